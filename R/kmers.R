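# k-mer extraction and error-tolerant clustering.
#
# All k-mers are stored in canonical form (lexicographic minimum of the
# k-mer and its reverse complement). Two k-mers are "the same up to p
# errors" when the Hamming distance between them, or between one and the
# reverse complement of the other, is <= p. The connected components of
# that Hamming graph are the clusters.

canonical_kmers <- function(kmers) {
  rc <- reverse_complement(kmers)
  fwd <- kmers <= rc
  list(canon = ifelse(fwd, kmers, rc), strand = ifelse(fwd, "+", "-"))
}

# Canonical form of an oriented adjacency (a,oa) -> (b,ob): the same
# physical junction read on the other strand is (b,flip(ob)) -> (a,flip(oa));
# keep the lexicographically smaller tuple so both readings aggregate.
canonicalize_oriented_pairs <- function(dt) {
  o_rank <- function(o) ifelse(o == "+", 0L, 1L)
  a2 <- dt$b; oa2 <- flip_orient(dt$ob)
  b2 <- dt$a; ob2 <- flip_orient(dt$oa)
  swap <- (a2 < dt$a) |
    (a2 == dt$a & (o_rank(oa2) < o_rank(dt$oa) |
      (oa2 == dt$oa & (b2 < dt$b |
        (b2 == dt$b & o_rank(ob2) < o_rank(dt$ob))))))
  if (any(swap)) {
    na <- ifelse(swap, a2, dt$a); noa <- ifelse(swap, oa2, dt$oa)
    nb <- ifelse(swap, b2, dt$b); nob <- ifelse(swap, ob2, dt$ob)
    dt[, `:=`(a = na, oa = noa, b = nb, ob = nob)]
  }
  dt
}

#' Extract all k-mers from reads
#'
#' Every length-k window of every N-free read fragment is counted under its
#' canonical form, and consecutive windows are recorded as oriented
#' adjacencies (the raw material for de Bruijn edge frequencies).
#'
#' @param reads Character vector of read sequences, or a read table with a
#'   `seq` column (see [parse_library()]).
#' @param k k-mer length (>= 2).
#' @return An object of class `kmer_table`: a list with `k`, `counts`
#'   (data.table `kmer`, `count`), `adj` (data.table `a`, `oa`, `b`, `ob`,
#'   `count` of canonical oriented adjacencies) and `n_occ`, the total
#'   number of k-mer occurrences.
#' @export
extract_kmers <- function(reads, k) {
  if (is.data.frame(reads)) reads <- reads$seq
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  frags <- split_fragments(toupper(reads))$frag
  frags <- frags[nchar(frags) >= k]
  empty <- function() {
    structure(list(
      k = k,
      counts = data.table(kmer = character(0), count = integer(0)),
      adj = data.table(a = character(0), oa = character(0),
                       b = character(0), ob = character(0),
                       count = integer(0)),
      n_occ = 0L), class = "kmer_table")
  }
  if (length(frags) == 0L) {
    warning("no fragment of length >= k = ", k, "; empty k-mer table")
    return(empty())
  }
  nw <- nchar(frags) - k + 1L
  fi <- rep.int(seq_along(frags), nw)
  starts <- sequence(nw)
  kmers <- substring(frags[fi], starts, starts + k - 1L)
  cn <- canonical_kmers(kmers)

  counts <- data.table(kmer = cn$canon)[, .(count = .N), by = kmer]
  setorder(counts, kmer)

  n <- length(kmers)
  adj <- data.table(a = character(0), oa = character(0),
                    b = character(0), ob = character(0), count = integer(0))
  if (n >= 2L) {
    i <- which(fi[-n] == fi[-1L])
    if (length(i)) {
      adj <- data.table(a = cn$canon[i], oa = cn$strand[i],
                        b = cn$canon[i + 1L], ob = cn$strand[i + 1L])
      adj <- canonicalize_oriented_pairs(adj)
      adj <- adj[, .(count = .N), by = .(a, oa, b, ob)]
      setorder(adj, a, oa, b, ob)
    }
  }
  structure(list(k = k, counts = counts, adj = adj, n_occ = n),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat("k-mer table: k =", x$k, "|", nrow(x$counts), "distinct canonical k-mers |",
      x$n_occ, "occurrences\n")
  invisible(x)
}

#' Pigeonhole partition of a k-mer into p + 1 spans
#'
#' Splits positions `[0, k)` into `p + 1` contiguous spans whose lengths
#' differ by at most one, longer spans first. If two k-mers are within
#' Hamming distance p, at most p spans can contain a mismatch, so at least
#' one span is identical in both - the pigeonhole argument behind the
#' candidate-pair index.
#'
#' @param k k-mer length.
#' @param p Error allowance (>= 0); requires `k >= p + 1`.
#' @return data.frame with 0-based `start` and `length` per span.
#' @examples
#' partition_spans(5, 1)  # spans (0,3) and (3,2)
#' @export
partition_spans <- function(k, p) {
  k <- as.integer(k); p <- as.integer(p)
  if (p < 0L) stop("p must be >= 0")
  if (k < p + 1L) stop("k must be >= p + 1 to partition into p + 1 spans")
  nsp <- p + 1L
  base <- k %/% nsp
  rem <- k %% nsp
  lens <- rep.int(base, nsp) + c(rep.int(1L, rem), rep.int(0L, nsp - rem))
  data.frame(start = cumsum(c(0L, lens[-nsp])), length = lens)
}

# all unordered within-group pairs of ids sharing a key; fully vectorised
# over groups of size 2 (the common case), lapply for larger groups
pairs_within_groups <- function(ids, keys) {
  o <- order(keys, method = "radix")
  keys <- keys[o]; ids <- ids[o]
  r <- rle(keys)
  n <- r$lengths
  multi <- which(n >= 2L)
  if (!length(multi)) return(matrix(integer(0), ncol = 2L))
  offs <- cumsum(c(0L, n))[multi]   # 0-based offset of each multi group
  ns <- n[multi]
  two <- ns == 2L
  res <- list()
  if (any(two)) {
    o2 <- offs[two]
    res[[1L]] <- cbind(ids[o2 + 1L], ids[o2 + 2L])
  }
  if (any(!two)) {
    big_off <- offs[!two]; big_n <- ns[!two]
    res[[length(res) + 1L]] <- do.call(rbind, lapply(seq_along(big_n), function(g) {
      m <- big_n[g]; off <- big_off[g]
      i <- rep.int(seq_len(m - 1L), (m - 1L):1L)
      j <- sequence((m - 1L):1L) + i
      cbind(ids[off + i], ids[off + j])
    }))
  }
  do.call(rbind, res)
}

#' Candidate k-mer pairs from the (p + 1)-substring index
#'
#' Indexes the i-th pigeonhole span of every canonical k-mer and of its
#' reverse complement in the i-th of p + 1 hash tables; any two k-mers that
#' share a span value become a candidate pair. By the pigeonhole principle
#' the candidate stream contains every pair at Hamming distance <= p in
#' either orientation (plus false positives, which verification removes).
#'
#' @param table A `kmer_table`, or a character vector of canonical k-mers.
#' @param p Error allowance (>= 1; at p = 0 clustering is skipped).
#' @return data.table with columns `a`, `b` (canonical k-mers, a < b),
#'   deduplicated.
#' @export
candidate_pairs <- function(table, p) {
  kmers <- if (inherits(table, "kmer_table")) table$counts$kmer else table
  p <- as.integer(p)
  if (p < 1L) stop("candidate_pairs requires p >= 1")
  n <- length(kmers)
  out <- data.table(a = character(0), b = character(0))
  if (n < 2L) return(out)
  k <- nchar(kmers[1L])
  rc <- reverse_complement(kmers)
  spans <- partition_spans(k, p)
  ids <- c(seq_len(n), seq_len(n))  # forward entries then rc entries
  pair_mat <- vector("list", nrow(spans))
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i] + 1L
    e <- spans$start[i] + spans$length[i]
    key <- c(substr(kmers, s, e), substr(rc, s, e))
    pm <- pairs_within_groups(ids, key)
    if (nrow(pm)) {
      pm <- pm[pm[, 1L] != pm[, 2L], , drop = FALSE]
      pair_mat[[i]] <- pm
    }
  }
  pm <- do.call(rbind, pair_mat)
  if (is.null(pm) || nrow(pm) == 0L) return(out)
  s1 <- kmers[pm[, 1L]]
  s2 <- kmers[pm[, 2L]]
  out <- unique(data.table(a = pmin(s1, s2), b = pmax(s1, s2)))
  setorder(out, a, b)
  out
}

#' Verified Hamming distance between two k-mers up to p
#'
#' Compares `a` against `b` and against the reverse complement of `b`
#' (early exit after p + 1 mismatches) and returns the smaller distance
#' with its orientation; forward wins ties.
#'
#' @param a,b Equal-length DNA strings (vectorised).
#' @param p Maximum distance of interest.
#' @return data.frame with `d` (NA when both orientations exceed p) and
#'   `orientation` (`"+"`, `"-"`, or NA).
#' @examples
#' kmer_distance("GGTCT", "GGTAT", 1)  # d = 1, forward
#' @export
kmer_distance <- function(a, b, p) {
  p <- as.integer(p)
  nmax <- max(length(a), length(b))
  a <- rep_len(a, nmax); b <- rep_len(b, nmax)
  df <- hamming_bounded(a, b, p)
  dr <- hamming_bounded(a, reverse_complement(b), p)
  use_f <- df <= p & df <= dr
  use_r <- !use_f & dr <= p
  d <- ifelse(use_f, df, ifelse(use_r, dr, NA_integer_))
  orientation <- ifelse(use_f, "+", ifelse(use_r, "-", NA_character_))
  data.frame(d = d, orientation = orientation, stringsAsFactors = FALSE)
}

#' Cluster k-mers by Hamming distance
#'
#' Builds the Hamming graph (edges between canonical k-mers whose verified
#' distance in either orientation is <= p) from the pigeonhole candidate
#' stream and returns its connected components, found by breadth-first
#' search from the lexicographically smallest member of each component.
#' Member orientations are propagated along the BFS forest (root =
#' forward). At p = 0 every distinct canonical k-mer is its own singleton
#' cluster and the graph is never built.
#'
#' @param table A `kmer_table`.
#' @param p Error allowance (>= 0).
#' @return data.table with columns `component` (1-based, numbered by
#'   smallest member), `kmer`, `orient`, `count`. The number of
#'   orientation conflicts observed on non-tree edges (palindromic cycles)
#'   is attached as attribute `orientation_conflicts`.
#' @export
cluster_kmers <- function(table, p) {
  stopifnot(inherits(table, "kmer_table"))
  p <- as.integer(p)
  counts <- table$counts
  kmers <- counts$kmer            # already sorted (radix) by extract_kmers
  n <- length(kmers)
  if (p == 0L || n <= 1L) {
    out <- data.table(component = seq_len(n), kmer = kmers, orient = "+",
                      count = counts$count)
    setattr(out, "orientation_conflicts", 0L)
    return(out[])
  }
  cand <- candidate_pairs(kmers, p)
  if (nrow(cand)) {
    ai <- match(cand$a, kmers); bi <- match(cand$b, kmers)
    vd <- kmer_distance(cand$a, cand$b, p)
    keep <- !is.na(vd$d)
    edges <- data.table(i = ai[keep], j = bi[keep],
                        flip = vd$orientation[keep] == "-")
  } else {
    edges <- data.table(i = integer(0), j = integer(0), flip = logical(0))
  }
  # dedupe parallel edges; an edge valid in both orientations is counted
  # as a potential orientation conflict below
  edges <- unique(edges)
  setorder(edges, i, j, flip)
  edges <- edges[!duplicated(paste(i, j))]

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$i, edges$j))
  }
  comp <- igraph::components(g)$membership
  comp <- match(comp, unique(comp))  # renumber in vertex (= lex) order

  orient <- rep.int(1L, n)
  conflicts <- 0L
  if (nrow(edges)) {
    bf <- igraph::bfs(g, root = 1, unreachable = TRUE, father = TRUE)
    ord <- as.integer(bf$order)
    father <- as.integer(bf$father)
    # per-vertex sign of the tree edge to the father
    keymax <- n + 1
    ekey <- edges$i * keymax + edges$j
    vkey <- pmin(ord, father[ord]) * keymax + pmax(ord, father[ord])
    esign <- ifelse(edges$flip, -1L, 1L)[match(vkey, ekey)]
    for (t in seq_along(ord)) {
      v <- ord[t]; f <- father[v]
      if (!is.na(f)) orient[v] <- orient[f] * esign[t]
    }
    bad <- orient[edges$i] * ifelse(edges$flip, -1L, 1L) != orient[edges$j]
    conflicts <- sum(bad)
  }
  out <- data.table(component = comp, kmer = kmers,
                    orient = ifelse(orient > 0L, "+", "-"),
                    count = counts$count)
  setorder(out, component, kmer)
  setattr(out, "orientation_conflicts", conflicts)
  out[]
}
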