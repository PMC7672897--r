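# Mapping reads back onto the compacted graph by exact k-mer seeding.
# The read's first k-mer (falling back to its last) is looked up in an
# index of all node k-mers; the implied placement is verified base by
# base, following links across node boundaries where the read overhangs.
# Reads whose seed verifies in more than one place, or that can be
# extended across a junction in more than one way, are dropped as
# repeat-ambiguous; so are reads that exceed the mismatch budget.

# index of every k-mer window of every node sequence, keyed by canonical
node_kmer_index <- function(g) {
  k <- g$k
  nodes <- g$nodes[len >= k]
  if (nrow(nodes) == 0L) {
    return(data.table(kmer = character(0), node = integer(0),
                      pos = integer(0), strand = character(0),
                      key = "kmer"))
  }
  nw <- nodes$len - k + 1L
  ni <- rep.int(nodes$id, nw)
  starts <- sequence(nw)
  win <- substring(g$nodes$seq[ni], starts, starts + k - 1L)
  cn <- canonical_kmers(win)
  idx <- data.table(kmer = cn$canon, node = ni, pos = starts - 1L,
                    strand = cn$strand)
  setkey(idx, kmer)
  idx
}

# walk a read across the graph. The read runs left-to-right over node
# "views" (a view is the node sequence in orientation o). Starts inside
# node n0 viewed with orientation o0 at view offset xv (0-based position
# of the read's first base). Returns NULL (failed or ambiguous) or a
# data.table chain of visits: node, orient, outer (node-forward position
# of the segment's first read base), seg (bases of the read it covers).
walk_read <- function(read, g, vplus, vminus, n0, o0, xv, max_mm) {
  rl <- nchar(read)
  node <- n0; o <- o0; off <- xv
  len <- g$nodes$len[node]
  v <- if (o == "+") vplus[node] else vminus[node]
  seg <- min(rl, len - off)
  mm <- hamming_bounded(substr(read, 1L, seg),
                        substr(v, off + 1L, off + seg), max_mm)
  if (mm > max_mm) return(NULL)
  outer <- if (o == "+") off else len - 1L - off
  here <- data.table(node = node, orient = o, outer = outer, seg = seg)
  if (seg >= rl) return(here)
  # read continues past the view's right end: cross a link
  rs <- if (o == "+") "R" else "L"
  ep <- g$links[(a == node & from_side(oa) == rs) |
                (b == node & to_side(ob) == rs)]
  if (nrow(ep) == 0L) return(NULL)  # runs off a free end
  rest <- substr(read, seg + 1L, rl)
  ok <- NULL
  for (i in seq_len(nrow(ep))) {
    l <- ep[i]
    if (l$a == node && from_side(l$oa) == rs) {
      nn <- l$b; ns <- to_side(l$ob)
    } else {
      nn <- l$a; ns <- from_side(l$oa)
    }
    no <- if (ns == "L") "+" else "-"
    sub <- walk_read(rest, g, vplus, vminus, nn, no, l$ov, max_mm - mm)
    if (!is.null(sub)) {
      if (!is.null(ok)) return(NULL)  # ambiguous extension
      ok <- sub
    }
  }
  if (is.null(ok)) return(NULL)
  rbind(here, ok)
}

# re-express a chain computed for the reverse complement of a read in
# terms of the read itself: reverse the visit order, flip orientations,
# and move each segment's reference base to its other end
flip_chain <- function(ch) {
  n <- nrow(ch)
  out <- ch[n:1L]
  out[, outer := ifelse(orient == "+", outer + seg - 1L, outer - (seg - 1L))]
  out[, orient := flip_orient(orient)]
  out
}

#' Map reads onto a compacted assembly graph
#'
#' Places each read by exact k-mer seeding (first k-mer, falling back to
#' the last) and verifies the placement base by base, allowing at most
#' `(1 - min_identity) * read length` mismatches and following links where
#' the read crosses node boundaries. A read is kept only if exactly one
#' placement verifies.
#'
#' @param reads Read table (see [parse_library()]) or character vector.
#' @param g A compacted `assembly_graph`.
#' @param min_identity Minimum fraction of matching bases (default 0.95).
#' @return data.table of anchors: `read_row` (row index in `reads`),
#'   `chain_pos`, `node`, `orient` (direction of the read on the node's
#'   stored strand), `outer` (node-forward 0-based position of the first
#'   read base of that segment) and `seg` (segment length). Single-node
#'   placements have one row; junction-crossing reads have one row per
#'   node visited.
#' @export
map_reads <- function(reads, g, min_identity = 0.95) {
  if (is.character(reads)) reads <- data.table(seq = reads)
  k <- g$k
  idx <- node_kmer_index(g)
  out_empty <- data.table(read_row = integer(0), chain_pos = integer(0),
                          node = integer(0), orient = character(0),
                          outer = integer(0), seg = integer(0))
  if (nrow(idx) == 0L || nrow(reads) == 0L) return(out_empty)
  seqs <- reads$seq
  rls <- nchar(seqs)
  usable <- which(rls >= k & !grepl("[^ACGT]", seqs))
  if (!length(usable)) return(out_empty)

  vplus <- character(max(g$nodes$id)); vminus <- character(max(g$nodes$id))
  vplus[g$nodes$id] <- g$nodes$seq
  vminus[g$nodes$id] <- reverse_complement(g$nodes$seq)

  nlen <- integer(max(g$nodes$id)); nlen[g$nodes$id] <- g$nodes$len

  try_place <- function(rseq, rl, r0, node, pos, si, sr, max_mm) {
    # seed: read k-mer at offset r0 equals node window [pos, pos+k) when
    # oriented; o = read direction on node's stored strand
    o <- if (sr == si) "+" else "-"
    len <- nlen[node]
    xv <- if (o == "+") pos - r0 else len - pos - k - r0
    if (xv >= 0L) {
      ch <- walk_read(rseq, g, vplus, vminus, node, o, xv, max_mm)
      if (!is.null(ch)) return(ch)
      return(NULL)
    }
    # read start hangs off this view; walk the reverse complement instead
    rrc <- reverse_complement(rseq)
    r0f <- rl - k - r0
    of <- flip_orient(o)
    xvf <- if (of == "+") pos - r0f else len - pos - k - r0f
    if (xvf < 0L) return(NULL)  # seed interior to a multi-node span
    ch <- walk_read(rrc, g, vplus, vminus, node, of, xvf, max_mm)
    if (is.null(ch)) return(NULL)
    flip_chain(ch)
  }

  n_us <- length(usable)
  # bulk seed lookup: first k-mer, then last k-mer for reads with no hit
  fk <- substr(seqs[usable], 1L, k)
  cn1 <- canonical_kmers(fk)
  h1 <- idx[data.table(q = seq_len(n_us), kmer = cn1$canon),
            on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  seen1 <- unique(h1$q)
  need2 <- setdiff(seq_len(n_us), seen1)
  h2 <- NULL
  r0_2 <- integer(n_us); strand2 <- character(n_us)
  if (length(need2)) {
    r0v <- rls[usable[need2]] - k
    lk <- substr(seqs[usable[need2]], r0v + 1L, r0v + k)
    cn2 <- canonical_kmers(lk)
    r0_2[need2] <- r0v
    strand2[need2] <- cn2$strand
    h2 <- idx[data.table(q = need2, kmer = cn2$canon),
              on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  }

  results <- vector("list", n_us)
  process <- function(htab, strands, r0s) {
    if (is.null(htab) || nrow(htab) == 0L) return(invisible())
    qs <- split(seq_len(nrow(htab)), htab$q)
    for (qn in names(qs)) {
      rows <- qs[[qn]]
      q <- htab$q[rows[1L]]
      rseq <- seqs[usable[q]]
      rl <- rls[usable[q]]
      max_mm <- as.integer(floor((1 - min_identity) * rl))
      chains <- list()
      for (r in rows) {
        ch <- try_place(rseq, rl, r0s[q], htab$node[r], htab$pos[r],
                        htab$strand[r], strands[q], max_mm)
        if (!is.null(ch)) {
          chains[[length(chains) + 1L]] <- ch
          if (length(chains) > 1L) break
        }
      }
      if (length(chains) == 1L) {
        ch <- chains[[1L]]
        ch[, `:=`(read_row = usable[q], chain_pos = seq_len(.N))]
        results[[q]] <<- ch
      }
    }
    invisible()
  }
  process(h1, cn1$strand, rep.int(0L, n_us))
  process(h2, strand2, r0_2)

  anchors <- rbindlist(results[!vapply(results, is.null, TRUE)])
  if (nrow(anchors) == 0L) return(out_empty)
  setcolorder(anchors, c("read_row", "chain_pos", "node", "orient",
                         "outer", "seg"))
  anchors[]
}
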