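# Consensus computation per cluster and recursive splitting of over-merged
# clusters. Over-merging shows up as a column of the member alignment where
# a minority nucleotide x is almost as frequent as the consensus nucleotide
# y; whenever occ(x) >= sp * occ(y) the members carrying x are pulled out
# into their own node and both halves are re-examined recursively.

BASES <- c("A", "C", "G", "T")

# sp as an exact fraction (numerator / 1e6) so the >= comparison below is
# integer arithmetic, with no float boundary effects for thresholds like 0.6
sp_fraction <- function(sp) {
  if (!is.numeric(sp) || length(sp) != 1L || sp <= 0 || sp > 1)
    stop("sp must be a single value in (0, 1]")
  c(num = round(sp * 1e6), den = 1e6)
}

# integer matrix (members x k) of A/C/G/T codes 1..4
seq_matrix <- function(seqs) {
  k <- nchar(seqs[1L])
  m <- match(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE), BASES)
  matrix(m, ncol = k, byrow = TRUE)
}

# occurrence-weighted per-column tallies: 4 x k
column_tallies <- function(M, w) {
  k <- ncol(M)
  T <- matrix(0, 4L, k)
  for (b in 1:4) {
    eq <- M == b
    T[b, ] <- if (nrow(M) == 1L) w * eq else colSums(w * eq)
  }
  T
}

#' Consensus sequence of oriented cluster members
#'
#' Column-wise majority over occurrence-weighted tallies; a tied column is
#' resolved to the lexicographically smallest nucleotide (A < C < G < T).
#'
#' @param seqs Character vector of equal-length oriented member k-mers.
#' @param counts Occurrence count per member (default 1 each).
#' @return The consensus string.
#' @examples
#' cluster_consensus(c("GGTCT", "GGTAT", "GCTCT", "TGTCT"))  # "GGTCT"
#' @export
cluster_consensus <- function(seqs, counts = rep.int(1L, length(seqs))) {
  if (length(seqs) == 0L) stop("empty member list has no consensus")
  if (length(unique(nchar(seqs))) != 1L) stop("members must have equal length")
  M <- seq_matrix(seqs)
  T <- column_tallies(M, counts)
  idx <- max.col(t(T), ties.method = "first")
  paste(BASES[idx], collapse = "")
}

# core recursive splitter on integer matrix rows; returns list of
# list(cons = integer consensus codes, rows = row indices into M)
split_rows <- function(M, w, rows, spf) {
  Msub <- M[rows, , drop = FALSE]
  T <- column_tallies(Msub, w[rows])
  cons <- max.col(t(T), ties.method = "first")
  qual <- T * spf[["den"]] >= rep(T[cbind(cons, seq_len(ncol(M)))],
                                  each = 4L) * spf[["num"]]
  qual[T == 0] <- FALSE
  qual[cbind(cons, seq_len(ncol(M)))] <- FALSE
  hit <- which(qual)  # column-major: scans columns left->right, bases A<C<G<T
  if (!length(hit)) {
    return(list(list(cons = cons, rows = rows)))
  }
  j <- ((hit[1L] - 1L) %/% 4L) + 1L
  x <- ((hit[1L] - 1L) %% 4L) + 1L
  in_v1 <- Msub[, j] == x
  c(split_rows(M, w, rows[in_v1], spf),
    split_rows(M, w, rows[!in_v1], spf))
}

#' Split an over-merged consensus node
#'
#' Scans alignment columns left to right (nucleotides A < C < G < T within
#' a column); at the first column whose minority nucleotide x satisfies
#' occ(x) >= sp * occ(y) against the consensus nucleotide y, members
#' carrying x become one node and the rest another, and both are split
#' recursively. Member multisets are partitioned, never duplicated.
#'
#' @param seqs Oriented member k-mers.
#' @param counts Occurrence count per member.
#' @param sp Splitting threshold in (0, 1].
#' @return List of nodes, each `list(consensus =, members = integer row
#'   indices into the input)`.
#' @export
split_node <- function(seqs, counts = rep.int(1L, length(seqs)), sp = 0.6) {
  if (length(seqs) == 0L) stop("empty member list")
  spf <- sp_fraction(sp)
  M <- seq_matrix(seqs)
  parts <- split_rows(M, counts, seq_along(seqs), spf)
  lapply(parts, function(pt) {
    list(consensus = paste(BASES[pt$cons], collapse = ""),
         members = pt$rows)
  })
}

#' Build the consensus k-mer set from clusters
#'
#' Applies consensus computation and recursive splitting to every cluster
#' and collects the resulting consensus sequences (canonicalized; duplicate
#' sequences merged with counts summed) as the node set for de Bruijn graph
#' construction. Every original k-mer occurrence is accounted to exactly
#' one final node.
#'
#' @param clusters Cluster table from [cluster_kmers()].
#' @param sp Splitting threshold.
#' @return List with `nodes` (data.table `node_id`, `seq`, `count`,
#'   `n_members`) and `members` (data.table `kmer`, `node_id`,
#'   `rel_orient`): the orientation that takes the canonical member k-mer
#'   onto the node sequence's strand.
#' @export
build_consensus_set <- function(clusters, sp = 0.6) {
  stopifnot(is.data.frame(clusters))
  cl <- as.data.table(clusters)
  if (nrow(cl) == 0L) {
    return(list(nodes = data.table(node_id = integer(0), seq = character(0),
                                   count = integer(0), n_members = integer(0)),
                members = data.table(kmer = character(0), node_id = integer(0),
                                     rel_orient = character(0))))
  }
  sizes <- cl[, .N, by = component]
  single_comp <- sizes[N == 1L, component]
  multi_comp <- sizes[N > 1L, component]

  seq_acc <- list(); count_acc <- list()
  mk_acc <- list(); mn_acc <- list(); mo_acc <- list()
  nid <- 0L

  if (length(single_comp)) {
    sing <- cl[component %in% single_comp]
    # singleton: consensus = the member itself; canonical k-mer is already
    # the canonical sequence, orientation "+"
    nid <- nrow(sing)
    seq_acc[[1L]] <- sing$kmer
    count_acc[[1L]] <- sing$count
    mk_acc[[1L]] <- sing$kmer
    mn_acc[[1L]] <- seq_len(nid)
    mo_acc[[1L]] <- rep.int("+", nid)
  }

  if (length(multi_comp)) {
    multi <- cl[component %in% multi_comp]
    oseq <- orient_seq(multi$kmer, multi$orient)
    idx_by_comp <- split(seq_len(nrow(multi)), multi$component)
    spf <- sp_fraction(sp)
    M <- seq_matrix(oseq)
    w <- multi$count
    # one entry per final (post-split) node
    cons_l <- list(); rows_l <- list()
    for (ix in idx_by_comp) {
      parts <- split_rows(M, w, ix, spf)
      for (pt in parts) {
        cons_l[[length(cons_l) + 1L]] <- pt$cons
        rows_l[[length(rows_l) + 1L]] <- pt$rows
      }
    }
    npart <- length(cons_l)
    cons_seq <- vapply(cons_l, function(ci) paste(BASES[ci], collapse = ""), "")
    ccons <- canonical_kmers(cons_seq)
    part_ids <- nid + seq_len(npart)
    nsz <- lengths(rows_l)
    rows_all <- unlist(rows_l, use.names = FALSE)
    node_all <- rep.int(part_ids, nsz)
    mo <- multi$orient[rows_all]
    flip_node <- rep.int(ccons$strand == "-", nsz)
    mo[flip_node] <- flip_orient(mo[flip_node])
    seq_acc[[length(seq_acc) + 1L]] <- ccons$canon
    count_acc[[length(count_acc) + 1L]] <-
      as.integer(rowsum(w[rows_all], node_all)[, 1L])
    mk_acc[[length(mk_acc) + 1L]] <- multi$kmer[rows_all]
    mn_acc[[length(mn_acc) + 1L]] <- node_all
    mo_acc[[length(mo_acc) + 1L]] <- mo
    nid <- nid + npart
  }

  nodes <- data.table(node_id = seq_len(nid),
                      seq = unlist(seq_acc, use.names = FALSE),
                      count = unlist(count_acc, use.names = FALSE))
  members <- data.table(kmer = unlist(mk_acc, use.names = FALSE),
                        node_id = unlist(mn_acc, use.names = FALSE),
                        rel_orient = unlist(mo_acc, use.names = FALSE))

  # merge duplicate canonical consensus sequences
  nodes[, final := .GRP, by = seq][]
  remap <- nodes$final
  merged <- nodes[, .(count = sum(count), n_members = .N), by = .(final, seq)]
  setorder(merged, seq)
  new_id <- seq_len(nrow(merged))
  id_of_final <- new_id[match(seq_len(max(remap)), merged$final)]
  members[, node_id := id_of_final[remap[node_id]]]
  out_nodes <- merged[, .(node_id = new_id, seq, count, n_members)]
  setorder(members, node_id, kmer)
  list(nodes = out_nodes, members = members[])
}
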