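build_p0_graph <- function(reads, k) {
  tab <- extract_kmers(reads, k)
  build_graph(build_consensus_set(cluster_kmers(tab, 0), 0.6), tab)
}

test_that("edges are exact (k-1)-overlaps with read-supported frequencies", {
  g <- build_p0_graph("GGTCTA", 5L)
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(nrow(g$links), 1L)
  expect_equal(g$links$ov, 4L)
  expect_equal(g$links$freq, 1L)

  # homopolymer: self-overlap loop allowed
  g2 <- build_p0_graph("AAAAAA", 5L)
  expect_equal(nrow(g2$nodes), 1L)
  expect_true(any(g2$links$a == g2$links$b))
})

test_that("error-free p = 0 graph matches the textbook de Bruijn graph", {
  set.seed(20)
  genome <- random_genome(800, seed = 20)
  pairs <- simulate_read_pairs(genome, read_length = 60, coverage = 25,
                               insert_mean = 150, seed = 21)
  k <- 15L
  g <- build_p0_graph(pairs$seq, k)
  # oracle: direct textbook construction from the reads - distinct
  # canonical windows as nodes, consecutive window pairs as edges
  wlist <- lapply(pairs$seq, function(rd) {
    nw <- nchar(rd) - k + 1L
    substring(rd, seq_len(nw), seq_len(nw) + k - 1L)
  })
  tk <- unique(clustasm:::canonical_kmers(unlist(wlist))$canon)
  expect_setequal(g$nodes$seq, tk)
  oracle_edges <- unique(rbindlist(lapply(wlist, function(w) {
    nw <- length(w)
    data.table(a = clustasm:::canonical_kmers(w[-nw])$canon,
               b = clustasm:::canonical_kmers(w[-1L])$canon)
  })))
  oracle_edges[, key := paste(pmin(a, b), pmax(a, b))]
  got <- data.table(a = g$nodes$seq[g$links$a], b = g$nodes$seq[g$links$b])
  got[, key := paste(pmin(a, b), pmax(a, b))]
  expect_setequal(got$key, unique(oracle_edges$key))
  expect_true(all(g$links$freq >= 1L))
})

test_that("compaction merges chains, respects branches, and is idempotent", {
  # a -> b -> c with no other edges collapses to one node of length k + 2
  g <- build_p0_graph("ACGTACC", 5L)  # 3 k-mers in a chain
  gc1 <- compact_graph(g)
  expect_equal(nrow(gc1$nodes), 1L)
  expect_equal(gc1$nodes$len, 7L)
  expect_true(gc1$nodes$seq %in% c("ACGTACC", reverse_complement("ACGTACC")))

  # branch: a -> b, a -> c keeps the junction
  gb <- build_p0_graph(c("AAACCC", "AACCCG", "AACCCT"), 4L)
  gbc <- compact_graph(gb)
  expect_equal(nrow(gbc$nodes), 3L)
  expect_true(any(gbc$nodes$len == 6L))  # AAACCC merged

  # idempotence
  gc2 <- compact_graph(gc1)
  expect_equal(gc2$nodes$seq, gc1$nodes$seq)
  gbc2 <- compact_graph(gbc)
  expect_setequal(gbc2$nodes$seq, gbc$nodes$seq)
  expect_equal(nrow(gbc2$links), nrow(gbc$links))
})

test_that("compaction weights coverage by k-mer count", {
  g <- make_graph(5L, c("AAACG", "AACGT"),
                  link_row(1, "+", 2, "+", 4, 3), cov = c(10, 20))
  gc <- compact_graph(g)
  expect_equal(nrow(gc$nodes), 1L)
  expect_equal(gc$nodes$cov, 15)  # equal weights: one k-mer each
})

test_that("low-frequency trimming uses a strict cutoff and spares cs = 0", {
  g <- make_graph(5L, c("AAACG", "AACGT", "ACGTT"),
                  rbind(link_row(1, "+", 2, "+", 4, 4),
                        link_row(2, "+", 3, "+", 4, 5)), cov = 10)
  expect_equal(nrow(trim_edges(g, 5L)$links), 1L)  # freq 4 < 5 removed
  expect_equal(nrow(trim_edges(g, 5L)$nodes), 3L)  # cov 10 nodes survive
  expect_equal(nrow(trim_edges(g, 0L)$links), 2L)
  # isolated nodes below the cutoff disappear with their links
  g2 <- make_graph(5L, c("AAACG", "CCCTT"), cov = c(10, 2))
  t2 <- trim_edges(g2, 5L)
  expect_equal(t2$nodes$seq, "AAACG")
})

test_that("tips are pruned only against stronger-or-equal alternatives,
           lowest frequency and then lexicographic first", {
  # through-path A - B - C plus a one-node spur T at the A|B junction
  s <- "ACGTACGTGGATCCATTACCGGTT"
  A <- substr(s, 1, 10); B <- substr(s, 7, 18); C <- substr(s, 15, 24)
  Tt <- paste0(substr(s, 7, 10), "AGCTAA")  # shares the 4-overlap into B
  k <- 5L
  g <- make_graph(k, c(A, B, C, Tt),
                  rbind(link_row(1, "+", 2, "+", 4, 30),
                        link_row(2, "+", 3, "+", 4, 30),
                        link_row(1, "+", 4, "+", 4, 1)), cov = 30)
  gp <- prune_tips(g, max_tip_len = 2L * k)
  expect_equal(nrow(gp$nodes), 1L)  # spur removed, chain compacted
  expect_equal(gp$nodes$len, 24L)

  # a linear chain is never treated as a tip
  g2 <- make_graph(k, c(A, B), link_row(1, "+", 2, "+", 4, 2), cov = 2)
  gp2 <- prune_tips(g2)
  expect_equal(sum(gp2$nodes$len), 18L)  # merged (10+12-4), nothing dropped

  # two equal-frequency tips competing at one junction: the
  # lexicographically smaller sequence is removed first, after which the
  # other is the sole continuation and survives
  T1 <- paste0(substr(s, 7, 10), "AGCTAA")
  T2 <- paste0(substr(s, 7, 10), "CGCTAA")
  g3 <- make_graph(k, c(A, T1, T2),
                   rbind(link_row(1, "+", 2, "+", 4, 2),
                         link_row(1, "+", 3, "+", 4, 2)), cov = 10)
  gp3 <- prune_tips(g3, max_tip_len = 2L * k)
  expect_equal(nrow(gp3$nodes), 1L)  # A merged with the survivor
  expect_true(is_substring_either("CGCTAA", gp3$nodes$seq))
  expect_false(is_substring_either("AGCTAA", gp3$nodes$seq))
})

test_that("single-variant bubbles pop onto the stronger path, transferring
           support", {
  # S branches into X and Y (one substitution apart), rejoining at E
  S <- "ACGGATCCAT"; X <- "CATTTACGGA"; Y <- "CATTTACGGA"
  substr(Y, 6, 6) <- "G"
  E <- "CGGATTGCAC"
  k <- 5L
  g <- make_graph(k, c(S, X, Y, E),
                  rbind(link_row(1, "+", 2, "+", 3, 20),
                        link_row(2, "+", 4, "+", 4, 20),
                        link_row(1, "+", 3, "+", 3, 2),
                        link_row(3, "+", 4, "+", 4, 2)), cov = 20)
  gb <- pop_bubbles(g, max_bubble_len = 3L * k, min_identity = 0.8)
  expect_equal(nrow(gb$nodes), 1L)  # popped and fully compacted
  expect_true(grepl("TTTAC", gb$nodes$seq) ||
                grepl(reverse_complement("TTTAC"), gb$nodes$seq))

  # identity below threshold: both branches stay
  Y2 <- "CATGGGCGGA"
  g2 <- make_graph(k, c(S, X, Y2, E),
                   rbind(link_row(1, "+", 2, "+", 3, 20),
                         link_row(2, "+", 4, "+", 4, 20),
                         link_row(1, "+", 3, "+", 3, 2),
                         link_row(3, "+", 4, "+", 4, 2)), cov = 20)
  gb2 <- pop_bubbles(g2, min_identity = 0.9)
  expect_equal(nrow(gb2$nodes), 4L)
})

test_that("chimeric connections between well-supported junctions are cut", {
  # U1 and U2 continue into V1/W1 and V2/W2; a freq-1 link joins U1 to U2
  k <- 5L
  seqs <- c("AAGGCTAGCA",              # U1, R side busy
            "TTCCGATTGG",              # U2
            paste0("TAGCA", "CCAGG"),  # V1 continues U1
            paste0("TAGCA", "GCTAA"),  # W1 continues U1
            paste0("ATTGG", "TACCC"),  # V2 continues U2
            paste0("ATTGG", "CATAA"))  # W2 continues U2
  links <- rbind(link_row(1, "+", 3, "+", 5, 30),
                 link_row(1, "+", 4, "+", 5, 28),
                 link_row(2, "+", 5, "+", 5, 30),
                 link_row(2, "+", 6, "+", 5, 28),
                 link_row(1, "+", 2, "-", 5, 1))  # chimera
  g <- make_graph(k, seqs, links, cov = 30)
  gc <- remove_chimeric_links(g, cs = 5L)
  got <- data.table(a = gc$nodes$seq[gc$links$a], b = gc$nodes$seq[gc$links$b])
  expect_equal(nrow(gc$links), 4L)
  # uniform-frequency graphs are untouched
  g2 <- make_graph(k, seqs, copy(links)[, freq := 30L], cov = 30)
  gc2 <- remove_chimeric_links(g2, cs = 5L)
  expect_equal(nrow(gc2$links), 5L)
})

test_that("cleaning is monotone and strand-symmetric end to end", {
  set.seed(22)
  genome <- random_genome(2000, seed = 22)
  pairs <- simulate_read_pairs(genome, read_length = 70, coverage = 30,
                               error_rate = 0.01, insert_mean = 200, seed = 23)
  tab <- extract_kmers(pairs$seq, 17L)
  g0 <- build_graph(build_consensus_set(cluster_kmers(tab, 0), 0.6), tab)
  g1 <- trim_edges(g0, 5L)
  expect_lte(nrow(g1$nodes), nrow(g0$nodes))
  expect_lte(nrow(g1$links), nrow(g0$links))
  g2 <- prune_tips(compact_graph(g1))
  expect_lte(sum(g2$nodes$len), sum(compact_graph(g1)$nodes$len))
  g3 <- pop_bubbles(g2)
  expect_lte(nrow(g3$nodes), nrow(g2$nodes))

  # strand symmetry: assembling reverse-complemented reads gives the same
  # unitig set
  res_f <- run_assembly(reads = data.table(seq = pairs$seq),
                        k = 17L, p = 0L, cs = 5L, out_prefix = NULL)
  res_r <- run_assembly(reads = data.table(seq = reverse_complement(pairs$seq)),
                        k = 17L, p = 0L, cs = 5L, out_prefix = NULL)
  expect_setequal(res_f$contigs$seq, res_r$contigs$seq)
})

test_that("a clean 5 kb genome assembles into one unitig equal to the
           genome up to orientation", {
  set.seed(24)
  genome <- random_genome(5000, seed = 24)
  pairs <- simulate_read_pairs(genome, read_length = 100, coverage = 30,
                               insert_mean = 300, seed = 25)
  res <- run_assembly(reads = pairs, k = 31L, p = 0L, cs = 0L,
                      out_prefix = NULL)
  expect_equal(nrow(res$contigs), 1L)
  expect_true(is_substring_either(res$contigs$seq[1L], genome))
  expect_gte(res$contigs$len[1L], 0.995 * nchar(genome))
})
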