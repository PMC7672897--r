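# Sub-k extension: after cleaning, unitig ends that overlap exactly by
# fewer than k bases are joined, longest overlap first, down to the
# minimum overlap m. Only mutually unique exact overlaps are joined;
# ambiguous many-to-one overlaps never are.

#' Default minimum overlap
#'
#' The extension stage joins unitig ends down to overlap length
#' `floor(k/2) + 1` by default.
#'
#' @param k k-mer length.
#' @return Integer minimum overlap.
#' @examples
#' default_min_overlap(46)  # 24
#' @export
default_min_overlap <- function(k) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  k %/% 2L + 1L
}

# outward-facing length-L flank of a free (node, side) end: read from the
# interior of the node toward (and ending at) that end
outward_flank <- function(seqs, sides, L) {
  n <- nchar(seqs)
  fl <- ifelse(sides == "R",
               substring(seqs, n - L + 1L, n),
               NA_character_)
  left <- sides == "L"
  if (any(left)) {
    fl[left] <- reverse_complement(substring(seqs[left], 1L, L))
  }
  fl
}

#' Extend the graph with sub-k overlaps
#'
#' For overlap length L from k-1 down to m, indexes all free unitig ends
#' by their length-L outward flanks and joins a pair of ends when each is
#' the other's only exact-match partner, re-compacting after each round.
#' Self-joins (both ends of the same node) are not made.
#'
#' @param g An `assembly_graph` (cleaned and compacted).
#' @param m Minimum overlap length; default `default_min_overlap(k)`.
#' @return The extended graph.
#' @export
extend_graph <- function(g, m = default_min_overlap(g$k)) {
  m <- as.integer(m)
  if (m > g$k - 1L) stop("m must be <= k - 1")
  g <- compact_graph(g)
  for (L in seq(g$k - 1L, m, by = -1L)) {
    sc <- side_counts(g$links)
    ends <- CJ(node = g$nodes$id, side = c("L", "R"))
    ends[, used := count_at(sc, node, side) > 0L]
    ends <- ends[used == FALSE & g$nodes$len[node] >= L]
    if (nrow(ends) < 2L) next
    ends[, flank := outward_flank(g$nodes$seq[node], side, L)]
    ends[, rcflank := reverse_complement(flank)]
    # e1 joins e2 when flank(e1) == rc(flank(e2)); symmetric
    hits <- merge(ends[, .(n1 = node, s1 = side, key = flank)],
                  ends[, .(n2 = node, s2 = side, key = rcflank)],
                  by = "key", allow.cartesian = TRUE)
    hits <- hits[n1 != n2]
    if (nrow(hits) == 0L) next
    # mutual uniqueness: each end may appear in exactly one pairing
    hits[, k1 := paste0(n1, s1)]
    hits[, k2 := paste0(n2, s2)]
    cnt <- table(c(hits$k1, hits$k2)) / 2  # each pairing listed twice
    uniq <- hits[cnt[k1] == 1 & cnt[k2] == 1]
    if (nrow(uniq) == 0L) next
    uniq <- uniq[n1 < n2 | (n1 == n2 & s1 < s2)]  # keep one listing per pair
    if (nrow(uniq) == 0L) next
    joins <- data.table(
      a = uniq$n1, oa = ifelse(uniq$s1 == "R", "+", "-"),
      b = uniq$n2, ob = ifelse(uniq$s2 == "L", "+", "-"),
      ov = L, freq = 0L)
    g$links <- canonical_link_table(rbind(g$links, joins))
    g <- compact_graph(g)
  }
  g
}
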