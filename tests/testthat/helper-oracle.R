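# Independent oracles and small fixture builders used across the suite.

library(data.table)

# Hamming distance of equal-length strings via adist with prohibitive
# indel costs (substitution-only alignment), in both orientations.
oracle_distance_matrix <- function(kmers) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  df <- utils::adist(kmers, kmers, costs = list(ins = 100, del = 100, sub = 1))
  dr <- utils::adist(kmers, rc, costs = list(ins = 100, del = 100, sub = 1))
  pmin(df, dr)
}

# brute-force connected components under distance <= p (union-find)
oracle_components <- function(kmers, p) {
  n <- length(kmers)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    d <- oracle_distance_matrix(kmers)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (d[i, j] <= p) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

# all brute-force pairs (i < j) at distance <= p in either orientation
oracle_pairs <- function(kmers, p) {
  if (length(kmers) < 2L) return(data.table(a = character(0), b = character(0)))
  d <- oracle_distance_matrix(kmers)
  idx <- which(upper.tri(d) & d <= p, arr.ind = TRUE)
  out <- data.table(a = kmers[idx[, 1L]], b = kmers[idx[, 2L]])
  out[, `:=`(lo = pmin(a, b), hi = pmax(a, b))]
  unique(out[, .(a = lo, b = hi)])
}

# a partition as a canonical string signature (order-independent)
partition_signature <- function(labels, items) {
  groups <- split(items, labels)
  groups <- vapply(groups, function(g) paste(sort(g), collapse = ","), "")
  paste(sort(groups), collapse = ";")
}

random_kmers <- function(n, k) {
  unique(vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
  }, ""))
}

# kmer_table from explicit canonical k-mers (counts 1), bypassing reads
table_from_kmers <- function(kmers) {
  k <- nchar(kmers[1L])
  canon <- unique(clustasm:::canonical_kmers(kmers)$canon)
  structure(list(
    k = k,
    counts = data.table(kmer = sort(canon), count = 1L),
    adj = data.table(a = character(0), oa = character(0),
                     b = character(0), ob = character(0), count = integer(0)),
    n_occ = length(canon)), class = "kmer_table")
}

# hand-built assembly graph for cleaning/extension unit tests
make_graph <- function(k, seqs, links = NULL, cov = 10) {
  nodes <- data.table(id = seq_along(seqs), seq = seqs,
                      cov = rep_len(as.numeric(cov), length(seqs)),
                      len = nchar(seqs))
  nodes[, nk := len - k + 1L]
  if (is.null(links)) {
    links <- data.table(a = integer(0), oa = character(0), b = integer(0),
                        ob = character(0), ov = integer(0), freq = integer(0))
  }
  clustasm:::new_graph(k, nodes, clustasm:::canonical_link_table(links))
}

link_row <- function(a, oa, b, ob, ov, freq) {
  data.table(a = as.integer(a), oa = oa, b = as.integer(b), ob = ob,
             ov = as.integer(ov), freq = as.integer(freq))
}

# is sequence (or its reverse complement) an exact substring of ref?
is_substring_either <- function(s, ref) {
  grepl(s, ref, fixed = TRUE) ||
    grepl(reverse_complement(s), ref, fixed = TRUE)
}

genome_kmers <- function(genome, k) {
  nw <- nchar(genome) - k + 1L
  win <- substring(genome, seq_len(nw), seq_len(nw) + k - 1L)
  unique(clustasm:::canonical_kmers(win)$canon)
}
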