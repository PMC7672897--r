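test_that("extract_kmers counts canonical windows and adjacencies", {
  tab <- extract_kmers("ACGTA", k = 5L)
  expect_equal(nrow(tab$counts), 1L)
  expect_equal(tab$counts$count, 1L)
  expect_equal(tab$n_occ, 1L)

  expect_warning(empty <- extract_kmers("AAAT", k = 5L))
  expect_equal(empty$n_occ, 0L)

  # occurrence conservation: n reads of length l give n * (l - k + 1)
  set.seed(1)
  reads <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = ""), "")
  tab <- extract_kmers(reads, k = 11L)
  expect_equal(tab$n_occ, 20L * (50L - 11L + 1L))
  expect_equal(sum(tab$counts$count), tab$n_occ)
  # adjacency conservation: one adjacency per consecutive window pair
  expect_equal(sum(tab$adj$count), 20L * (50L - 11L))
})

test_that("orientations are folded: a read and its reverse complement give
           the same table", {
  set.seed(2)
  reads <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = ""), "")
  t1 <- extract_kmers(reads, 9L)
  t2 <- extract_kmers(reverse_complement(reads), 9L)
  expect_equal(t1$counts, t2$counts)
})

test_that("partition spans are contiguous, balanced, longest first", {
  expect_equal(partition_spans(5, 0), data.frame(start = 0L, length = 5L))
  expect_equal(partition_spans(5, 1),
               data.frame(start = c(0L, 3L), length = c(3L, 2L)))
  sp <- partition_spans(80, 3)
  expect_equal(sp$length, rep(20L, 4))
  expect_equal(sp$start, c(0L, 20L, 40L, 60L))
  expect_error(partition_spans(3, 3), "p \\+ 1")
  # cover [0, k) exactly for a range of k, p
  for (k in 5:12) for (p in 0:3) {
    s <- partition_spans(k, p)
    expect_equal(rep(seq_len(nrow(s)), s$length) |> length(), k)
    expect_equal(s$start, cumsum(c(0L, s$length[-length(s$length)])))
    expect_lte(diff(range(s$length)), 1L)
  }
})

test_that("candidate index emits close pairs directly and via reverse
           complement", {
  cand <- candidate_pairs(c("AAAAA", "AAAAT"), p = 1)
  expect_true(nrow(cand) >= 1L)
  # TTTTC is canonical GAAAA; Hamming(AAAAA, GAAAA) = 1
  kms <- unique(clustasm:::canonical_kmers(c("AAAAA", "TTTTC"))$canon)
  cand2 <- candidate_pairs(sort(kms), p = 1)
  expect_true(nrow(cand2) >= 1L)
  expect_equal(kmer_distance("AAAAA", "GAAAA", 1)$d, 1L)
})

test_that("pigeonhole completeness: candidates are a superset of brute-force
           pairs", {
  set.seed(3)
  for (i in 1:25) {
    k <- sample(5:12, 1)
    kms <- unique(clustasm:::canonical_kmers(random_kmers(sample(10:120, 1), k))$canon)
    p <- sample(1:2, 1)
    want <- oracle_pairs(kms, p)
    got <- candidate_pairs(kms, p)
    if (nrow(want)) {
      missing <- want[!got, on = c("a", "b")]
      expect_equal(nrow(missing), 0L)
    } else {
      succeed()
    }
  }
})

test_that("verified distance picks the best orientation with early exit", {
  expect_equal(kmer_distance("GGTCT", "GGTAT", 1),
               data.frame(d = 1L, orientation = "+"))
  expect_equal(kmer_distance("ACGTA", "ACGTA", 0)$d, 0L)
  none <- kmer_distance("AAAAA", "GGGGG", 2)
  expect_true(is.na(none$d))
  expect_error(kmer_distance("AAAA", "AAAAA", 1), "length")
})

test_that("p = 0 gives one singleton cluster per distinct canonical k-mer", {
  tab <- extract_kmers(c("ACGTACGTAC", "ACGTACGTAC"), 5L)
  cl <- cluster_kmers(tab, 0)
  expect_equal(max(cl$component), nrow(tab$counts))
  expect_true(all(cl$orient == "+"))
})

test_that("the worked 4 k-mer component clusters together at p = 1", {
  tab <- table_from_kmers(c("GGTCT", "GGTAT", "GCTCT", "TGTCT"))
  cl <- cluster_kmers(tab, 1)
  expect_equal(max(cl$component), 1L)
  expect_equal(nrow(cl), 4L)
})

test_that("clusters equal brute-force components on random instances", {
  set.seed(4)
  for (i in 1:20) {
    k <- sample(5:12, 1)
    kms <- sort(unique(clustasm:::canonical_kmers(
      random_kmers(sample(10:150, 1), k))$canon))
    p <- sample(0:2, 1)
    cl <- cluster_kmers(table_from_kmers(kms), p)
    setorder(cl, kmer)
    expect_equal(partition_signature(cl$component, cl$kmer),
                 partition_signature(oracle_components(kms, p), kms))
  }
})

test_that("raising p never increases the cluster count", {
  set.seed(6)
  kms <- random_kmers(300, 6)
  tab <- table_from_kmers(kms)
  n0 <- max(cluster_kmers(tab, 0)$component)
  n1 <- max(cluster_kmers(tab, 1)$component)
  n2 <- max(cluster_kmers(tab, 2)$component)
  expect_lte(n1, n0)
  expect_lte(n2, n1)
})

test_that("propagated orientations keep cluster members mutually close", {
  # after BFS orientation propagation, every member's oriented sequence is
  # within plain (no reverse complement) Hamming distance p of at least
  # one other oriented member - its spanning-tree parent
  set.seed(8)
  p <- 1L
  for (i in 1:5) {
    kms <- sort(unique(clustasm:::canonical_kmers(random_kmers(400, 7))$canon))
    cl <- cluster_kmers(table_from_kmers(kms), p)
    for (comp in unique(cl[, .N, by = component][N >= 2L, component])) {
      os <- clustasm:::orient_seq(cl[component == comp, kmer],
                                  cl[component == comp, orient])
      for (j in seq_along(os)) {
        d <- clustasm:::hamming_bounded(rep(os[j], length(os) - 1L),
                                        os[-j], p)
        expect_lte(min(d), p)
      }
    }
  }
})
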