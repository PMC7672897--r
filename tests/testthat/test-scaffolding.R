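two_node_graph <- function(k = 21L, len = 400L, seed = 40) {
  set.seed(seed)
  A <- random_genome(len, seed = seed)
  B <- random_genome(len, seed = seed + 1L)
  make_graph(k, c(A, B))
}

test_that("verbatim reads anchor at the correct offset and orientation", {
  g <- two_node_graph()
  A <- g$nodes$seq[g$nodes$id == 1L]
  rd <- substr(A, 51, 150)
  an <- map_reads(c(rd, reverse_complement(rd)), g)
  expect_equal(nrow(an), 2L)
  expect_equal(an[read_row == 1L, .(node, orient, outer)],
               data.table(node = 1L, orient = "+", outer = 50L))
  # the reverse-complement read reports its own first base: the segment
  # ends at offset 149 on the forward strand
  expect_equal(an[read_row == 2L, .(node, orient, outer)],
               data.table(node = 1L, orient = "-", outer = 149L))
})

test_that("reads hanging off a free end or matching two nodes are dropped", {
  g <- two_node_graph()
  A <- g$nodes$seq[1L]; B <- g$nodes$seq[2L]
  over <- paste0(substr(A, 351, 400), "ACGTACGTACGTACGTACGT")  # runs off
  an <- map_reads(over, g)
  expect_equal(nrow(an), 0L)
  # same 60-mer planted in both nodes -> ambiguous -> dropped
  core <- substr(A, 101, 160)
  B2 <- paste0(substr(B, 1, 100), core, substr(B, 161, 400))
  g2 <- make_graph(21L, c(A, B2))
  an2 <- map_reads(core, g2)
  expect_equal(nrow(an2), 0L)
})

test_that("reads crossing a link walk the chain with one anchor per node", {
  set.seed(41)
  s <- random_genome(300, seed = 41)
  k <- 21L
  A <- substr(s, 1, 150); B <- substr(s, 131, 300)
  g <- make_graph(k, c(A, B), link_row(1, "+", 2, "+", 20, 10))
  rd <- substr(s, 101, 200)  # spans the junction
  an <- map_reads(rd, g)
  expect_equal(nrow(an), 2L)
  expect_equal(an$chain_pos, 1:2)
})

test_that("links require ss supporting pairs and use the lower-median gap", {
  g <- two_node_graph(len = 1000L)
  mk_pair <- function(i, outer1, outer2) {
    rbind(
      data.table(read_row = 2L * i - 1L, chain_pos = 1L, node = 1L,
                 orient = "+", outer = outer1, seg = 50L),
      data.table(read_row = 2L * i, chain_pos = 1L, node = 2L,
                 orient = "-", outer = outer2, seg = 50L))
  }
  # mate1 forward near A's right end (d = 1000 - outer1); mate2 reverse
  # near B's left end (d = outer2 + 1); gap = 300 - dA - dB
  outs <- data.table(o1 = c(900, 902, 898, 901, 899, 900),
                     o2 = c(49, 49, 49, 49, 49, 49))
  anchors <- rbindlist(lapply(1:6, function(i)
    mk_pair(i, outs$o1[i], outs$o2[i])))
  reads <- data.table(pair_id = rep(sprintf("p%d", 1:6), each = 2L),
                      mate = rep(1:2, 6L), lib = 0L, insert = 300L)
  lk <- infer_links(anchors, reads, g, ss = 5L)
  expect_equal(nrow(lk), 1L)
  expect_equal(lk$support, 6L)
  # inferred gaps: 300 - (1000 - o1) - 50 = o1 - 750
  expect_equal(lk$gap, sort(outs$o1 - 750)[3L])  # lower median of 6
  expect_equal(lk[, .(a, sa, b, sb)],
               data.table(a = 1L, sa = "R", b = 2L, sb = "L"))
  # below the support threshold: no link
  lk4 <- infer_links(anchors[read_row <= 8L], reads[1:8], g, ss = 5L)
  expect_equal(nrow(lk4), 0L)
  # explicit median example
  expect_equal(sort(c(98, 100, 102))[2L], 100)
})

test_that("raising ss never increases the number of links", {
  set.seed(42)
  g <- two_node_graph(len = 800L, seed = 43)
  anchors <- rbindlist(lapply(1:12, function(i) rbind(
    data.table(read_row = 2L * i - 1L, chain_pos = 1L, node = 1L,
               orient = "+", outer = 700L + i, seg = 50L),
    data.table(read_row = 2L * i, chain_pos = 1L, node = 2L,
               orient = "-", outer = 40L + i, seg = 50L))))
  reads <- data.table(pair_id = rep(sprintf("p%d", 1:12), each = 2L),
                      mate = rep(1:2, 12L), lib = 0L, insert = 400L)
  n_prev <- Inf
  for (ss in c(1L, 5L, 10L, 13L)) {
    n <- nrow(infer_links(anchors, reads, g, ss = ss))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("scaffold rendering joins oriented contigs with N gaps, floors
           negative gaps at one N, and applies the length filter", {
  contigs <- data.table(id = 1:2, seq = c("ACGTACGTAC", "GGGTTTCCCA"))
  links <- data.table(a = 1L, sa = "R", b = 2L, sb = "L", support = 8L,
                      gap = 50, lib = 0L, insert = 300L)
  sc <- build_scaffolds(contigs, links)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$seq, paste0("ACGTACGTAC", strrep("N", 50), "GGGTTTCCCA"))

  links$gap <- -12
  sc2 <- build_scaffolds(contigs, links)
  expect_equal(sc2$seq, paste0("ACGTACGTAC", "N", "GGGTTTCCCA"))

  # (2, R) endpoint: second contig enters reverse complemented
  links2 <- data.table(a = 1L, sa = "R", b = 2L, sb = "R", support = 8L,
                       gap = 5, lib = 0L, insert = 300L)
  sc3 <- build_scaffolds(contigs, links2)
  expect_equal(sc3$seq, paste0("ACGTACGTAC", strrep("N", 5),
                               reverse_complement("GGGTTTCCCA")))

  # ml filters scaffolds and standalone contigs
  sc4 <- build_scaffolds(contigs, links, ml = 100L)
  expect_equal(nrow(sc4), 0L)
  sc5 <- build_scaffolds(contigs, NULL, ml = 0L)
  expect_equal(nrow(sc5), 2L)

  # every non-N stretch of a scaffold is a verbatim contig substring
  parts <- strsplit(sc3$seq, "N+")[[1L]]
  expect_true(all(vapply(parts, function(p)
    any(vapply(contigs$seq, function(cs)
      is_substring_either(p, cs), TRUE)), TRUE)))
})

test_that("read chains resolve a spanned repeat into a single contig", {
  set.seed(44)
  # genome with an exact 60 bp repeat, shorter than the reads: spanning
  # reads witness both in/out pairings and the junction is duplicated
  unit <- random_genome(60, seed = 45)
  a <- random_genome(900, seed = 46)
  b <- random_genome(900, seed = 47)
  c_ <- random_genome(900, seed = 48)
  genome <- paste0(a, unit, b, unit, c_)
  pairs <- simulate_read_pairs(genome, read_length = 100, coverage = 60,
                               insert_mean = 300, seed = 49)
  res <- run_assembly(reads = pairs, k = 31L, p = 0L, cs = 0L,
                      out_prefix = NULL)
  expect_equal(nrow(res$contigs), 1L)
  expect_true(is_substring_either(res$contigs$seq[1L], genome))
})
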