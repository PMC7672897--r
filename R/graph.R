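# Bidirected assembly graph. Each node stores one strand of a
# double-stranded sequence; a link (a, oa, b, ob, ov) states that the
# ov-suffix of node a read in orientation oa equals the ov-prefix of node b
# read in orientation ob. The same physical junction read on the opposite
# strand is (b, flip(ob), a, flip(oa)); links are stored once, in the
# lexicographically smaller of the two forms.
#
# A link occupies one "side" of each node: the right (R) side of a when
# oa = "+", else the left (L); the left side of b when ob = "+", else the
# right. Side occupancy drives compaction, tip and bubble detection.

from_side <- function(o) ifelse(o == "+", "R", "L")
to_side   <- function(o) ifelse(o == "+", "L", "R")

new_graph <- function(k, nodes, links) {
  structure(list(k = as.integer(k), nodes = nodes, links = links),
            class = "assembly_graph")
}

empty_links <- function() {
  data.table(a = integer(0), oa = character(0), b = integer(0),
             ob = character(0), ov = integer(0), freq = integer(0))
}

#' @export
print.assembly_graph <- function(x, ...) {
  cat("assembly graph: k =", x$k, "|", nrow(x$nodes), "nodes |",
      nrow(x$links), "links |", sum(nchar(x$nodes$seq)), "bp\n")
  invisible(x)
}

# one row per (link row, node, side) endpoint occupancy
link_endpoints <- function(links) {
  if (nrow(links) == 0L) {
    return(data.table(lrow = integer(0), node = integer(0), side = character(0)))
  }
  rbind(
    data.table(lrow = seq_len(nrow(links)), node = links$a,
               side = from_side(links$oa)),
    data.table(lrow = seq_len(nrow(links)), node = links$b,
               side = to_side(links$ob))
  )
}

side_counts <- function(links) {
  ep <- link_endpoints(links)
  ep[, .(nlinks = .N), by = .(node, side)]
}

# count of links attached to the given (node, side) pairs (0 when free)
count_at <- function(sc, qnode, qside) {
  q <- data.table(node = qnode, side = qside)
  idx <- sc[q, on = c("node", "side"), which = TRUE]
  n <- sc$nlinks[idx]
  n[is.na(n)] <- 0L
  n
}

canonical_link_table <- function(links) {
  if (nrow(links) == 0L) return(links)
  links <- canonicalize_oriented_pairs(copy(links))
  links <- links[, .(freq = max(freq)), by = .(a, oa, b, ob, ov)]
  setorder(links, a, oa, b, ob, ov)
  setcolorder(links, c("a", "oa", "b", "ob", "ov", "freq"))
  links[]
}

#' Build the de Bruijn graph over a consensus k-mer set
#'
#' Nodes are the consensus k-mers; a link joins two nodes when a
#' (k-1)-suffix of one equals a (k-1)-prefix of the other in some
#' orientation pair (found by hashing all oriented flanks). Link frequency
#' is the number of read-adjacency instances (consecutive k-mer windows in
#' reads) whose two raw k-mers map to the two nodes; an overlap with no
#' read support gets frequency 0.
#'
#' @param consensus Result of [build_consensus_set()].
#' @param table The `kmer_table` the clusters came from (for adjacencies).
#' @return An `assembly_graph`.
#' @export
build_graph <- function(consensus, table) {
  stopifnot(inherits(table, "kmer_table"))
  k <- table$k
  nd <- consensus$nodes
  nodes <- data.table(id = nd$node_id, seq = nd$seq, cov = as.numeric(nd$count),
                      len = nchar(nd$seq))
  nodes[, nk := len - k + 1L]
  if (nrow(nodes) == 0L) return(new_graph(k, nodes, empty_links()))

  rc <- reverse_complement(nodes$seq)
  oriented <- rbind(
    data.table(id = nodes$id, o = "+", s = nodes$seq),
    data.table(id = nodes$id, o = "-", s = rc)
  )
  oriented[, `:=`(sfx = substr(s, 2L, k), pfx = substr(s, 1L, k - 1L))]
  ej <- merge(oriented[, .(a = id, oa = o, key = sfx)],
              oriented[, .(b = id, ob = o, key = pfx)],
              by = "key", allow.cartesian = TRUE)
  links <- if (nrow(ej)) {
    lk <- ej[, .(a, oa, b, ob)]
    lk[, `:=`(ov = k - 1L, freq = 0L)]
    lk <- canonical_link_table(lk)
    # drop hairpin fold-backs: a palindromic (k-1)-flank links a node's
    # end to itself on the opposite strand; a traversal cannot use them.
    # Genuine circular self-overlaps (same orientation) are kept.
    lk[!(a == b & oa != ob)]
  } else empty_links()

  # project read adjacencies through the member map onto node links
  adj <- table$adj
  if (nrow(adj) && nrow(links)) {
    mm <- consensus$members
    m1 <- match(adj$a, mm$kmer); m2 <- match(adj$b, mm$kmer)
    ok <- !is.na(m1) & !is.na(m2)
    if (any(ok)) {
      sgn <- function(o) ifelse(o == "+", 1L, -1L)
      q1 <- sgn(adj$oa[ok]) * sgn(mm$rel_orient[m1[ok]])
      q2 <- sgn(adj$ob[ok]) * sgn(mm$rel_orient[m2[ok]])
      proj <- data.table(a = mm$node_id[m1[ok]],
                         oa = ifelse(q1 > 0L, "+", "-"),
                         b = mm$node_id[m2[ok]],
                         ob = ifelse(q2 > 0L, "+", "-"),
                         count = adj$count[ok])
      proj <- canonicalize_oriented_pairs(proj)
      proj <- proj[, .(count = sum(count)), by = .(a, oa, b, ob)]
      links[proj, freq := freq + i.count, on = c("a", "oa", "b", "ob")]
    }
  }
  new_graph(k, nodes, links)
}

# renumber node ids 1..n in radix order of sequence (deterministic across
# construction paths), remapping links accordingly
renumber_graph <- function(g) {
  o <- order(g$nodes$seq, method = "radix")
  new_of_old <- integer(nrow(g$nodes))
  new_of_old[g$nodes$id[o]] <- seq_along(o)
  nodes <- g$nodes[o]
  nodes[, id := seq_len(.N)]
  links <- copy(g$links)
  if (nrow(links)) {
    links[, `:=`(a = new_of_old[a], b = new_of_old[b])]
    links <- canonical_link_table(links)
  }
  new_graph(g$k, nodes, links)
}

#' Compact unbranched paths into unitigs
#'
#' Merges every maximal chain of links whose two endpoint sides each carry
#' exactly one link. Merged sequences are overlap-collapsed concatenations,
#' canonicalized to the lexicographically smaller strand; coverage is the
#' k-mer-count-weighted mean of the parts. Idempotent.
#'
#' @param g An `assembly_graph`.
#' @return The compacted graph.
#' @export
compact_graph <- function(g) {
  links <- g$links
  nodes <- g$nodes
  if (nrow(links) == 0L) return(renumber_graph(g))
  sc <- side_counts(links)
  n_a <- count_at(sc, links$a, from_side(links$oa))
  n_b <- count_at(sc, links$b, to_side(links$ob))
  mergeable <- n_a == 1L & n_b == 1L & links$a != links$b
  if (!any(mergeable)) return(renumber_graph(g))

  ml <- links[mergeable]
  ml[, lid := .I]
  # break cycles: in a component where every vertex has both sides consumed
  # (edges == vertices), drop the largest link
  cg <- igraph::graph_from_edgelist(cbind(ml$a, ml$b), directed = FALSE)
  comp <- igraph::components(cg)$membership
  ml[, comp := comp[a]]
  drop <- ml[, {
    verts <- unique(c(a, b))
    if (.N == length(verts)) .(lid = max(lid)) else .(lid = integer(0))
  }, by = comp]$lid
  kept_cycle_links <- ml[lid %in% drop]
  ml <- ml[!lid %in% drop]
  if (nrow(ml) == 0L) return(renumber_graph(g))

  # adjacency: (node, side) -> row of ml, as plain indexed vectors
  nmax <- max(nodes$id)
  mla <- ml$a; mlb <- ml$b
  msa <- from_side(ml$oa); msb <- to_side(ml$ob)
  mlov <- ml$ov
  lrowL <- integer(nmax); lrowR <- integer(nmax)
  idx <- seq_len(nrow(ml))
  lrowR[mla[msa == "R"]] <- idx[msa == "R"]
  lrowL[mla[msa == "L"]] <- idx[msa == "L"]
  lrowR[mlb[msb == "R"]] <- idx[msb == "R"]
  lrowL[mlb[msb == "L"]] <- idx[msb == "L"]

  node_map <- data.table(old = nodes$id, new_seq = nodes$seq,
                         morient = "+", merged = FALSE)
  setkey(node_map, old)
  # endpoints of chains: nodes with exactly one side consumed by ml
  hasL <- lrowL > 0L; hasR <- lrowR > 0L
  ends <- which(xor(hasL, hasR))
  visited <- logical(nmax)
  chains <- list()
  for (start in ends) {
    if (visited[start]) next
    cur <- start
    cur_o <- if (lrowR[start] > 0L) "+" else "-"
    cn <- integer(256L); co <- character(256L); cv <- integer(256L)
    np <- 0L
    repeat {
      visited[cur] <- TRUE
      np <- np + 1L
      if (np > length(cn)) {
        length(cn) <- 2L * length(cn); length(co) <- 2L * length(co)
        length(cv) <- 2L * length(cv)
      }
      cn[np] <- cur; co[np] <- cur_o
      lrow <- if (cur_o == "+") lrowR[cur] else lrowL[cur]
      if (lrow == 0L) break
      if (mla[lrow] == cur &&
          msa[lrow] == (if (cur_o == "+") "R" else "L")) {
        nxt <- mlb[lrow]; nxt_side <- msb[lrow]
      } else {
        nxt <- mla[lrow]; nxt_side <- msa[lrow]
      }
      cv[np] <- mlov[lrow]
      if (visited[nxt]) break
      cur <- nxt
      cur_o <- if (nxt_side == "L") "+" else "-"
    }
    chains[[length(chains) + 1L]] <-
      list(nodes = cn[seq_len(np)], orient = co[seq_len(np)],
           ov = cv[seq_len(np - 1L)])
  }

  # assemble merged node rows
  new_rows <- vector("list", length(chains))
  seq_of <- nodes$seq; cov_of <- nodes$cov; nk_of <- nodes$nk
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    oseqs <- orient_seq(seq_of[ch$nodes], ch$orient)
    parts <- c(oseqs[1L],
               substring(oseqs[-1L], ch$ov + 1L, nchar(oseqs[-1L])))
    mseq <- paste(parts, collapse = "")
    crc <- reverse_complement(mseq)
    flipped <- crc < mseq
    if (flipped) mseq <- crc
    w <- nk_of[ch$nodes]
    new_rows[[ci]] <- data.table(
      seq = mseq, cov = sum(cov_of[ch$nodes] * w) / sum(w),
      len = nchar(mseq))
    mor <- ch$orient
    if (flipped) mor <- flip_orient(mor)
    node_map[.(ch$nodes), `:=`(new_seq = mseq, morient = mor, merged = TRUE,
                               chain = ci)]
  }

  untouched <- nodes[!node_map[.(nodes$id), merged]]
  merged_dt <- rbindlist(new_rows)
  merged_dt[, `:=`(id = nrow(untouched) + .I, nk = len - g$k + 1L)]
  new_nodes <- rbind(
    untouched[, .(id = seq_len(.N), seq, cov, len, nk)],
    merged_dt[, .(id, seq, cov, len, nk)]
  )
  # old id -> (new id, orientation within new node)
  old_ids <- nodes$id
  was_merged <- node_map[.(old_ids), merged]
  new_id_of_old <- integer(length(old_ids))
  new_id_of_old[!was_merged] <- seq_len(sum(!was_merged))
  chain_of_old <- node_map[.(old_ids), chain]
  new_id_of_old[was_merged] <- nrow(untouched) + chain_of_old[was_merged]
  or_of_old <- node_map[.(old_ids), morient]

  # remap surviving links (everything not consumed by the merge)
  surv <- links[!mergeable]
  surv <- rbind(surv, kept_cycle_links[, .(a, oa, b, ob, ov, freq)])
  if (nrow(surv)) {
    comp_or <- function(o, m) ifelse(o == m, "+", "-")  # sign product
    surv[, `:=`(oa = comp_or(oa, or_of_old[a]),
                ob = comp_or(ob, or_of_old[b]),
                a = new_id_of_old[a], b = new_id_of_old[b])]
    surv <- canonical_link_table(surv)
  } else {
    surv <- empty_links()
  }
  renumber_graph(new_graph(g$k, new_nodes, surv))
}

#' Write an assembly graph as GFA1
#'
#' Segments carry depth (`dp`) tags; links carry overlap CIGARs and read
#' support (`RC`) tags.
#'
#' @param g An `assembly_graph`.
#' @param path Output path.
#' @export
write_gfa <- function(g, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  if (nrow(g$nodes)) {
    writeLines(sprintf("S\t%d\t%s\tdp:f:%.2f", g$nodes$id, g$nodes$seq,
                       g$nodes$cov), con)
  }
  if (nrow(g$links)) {
    writeLines(sprintf("L\t%d\t%s\t%d\t%s\t%dM\tRC:i:%d",
                       g$links$a, g$links$oa, g$links$b, g$links$ob,
                       g$links$ov, g$links$freq), con)
  }
  invisible(path)
}
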