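# Full assembly pipeline: extract k-mers -> cluster (skipped at p = 0) ->
# consensus/split -> de Bruijn graph -> clean -> extend -> map pairs ->
# thread junctions -> scaffold -> write out_contig.fasta /
# out_scaffold.fasta.

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full assembly pipeline
#'
#' @param reads Read table (see [parse_library()] / [read_libraries()]),
#'   or `NULL` if `libraries` is given.
#' @param libraries Optional list of library specs passed to
#'   [read_libraries()].
#' @param k k-mer length.
#' @param p Error allowance on k-mers (maximum Hamming distance for
#'   clustering); `p = 0` skips clustering entirely.
#' @param sp Consensus splitting threshold in (0, 1] (default 0.6).
#' @param cs Low-frequency cutoff for graph cleaning (default 5).
#' @param ss Minimum anchor-pair support for scaffold links (default 5).
#' @param m Minimum overlap for sub-k extension; default
#'   `default_min_overlap(k)`.
#' @param ml Minimum contig/scaffold length written to output (default 0).
#' @param out_prefix Output directory/prefix; `out_contig.fasta` and
#'   `out_scaffold.fasta` are written under it. `NULL` skips writing.
#' @param max_tip_len,max_bubble_len,min_bubble_identity Structural
#'   cleaning parameters (defaults 2k, 3k, 0.9).
#' @param min_map_identity Read-mapping identity threshold (default 0.95).
#' @param genome_size Optional denominator for reported N50/E-size.
#' @param verbose Log stage-by-stage node/link counts and timings.
#' @return (invisibly) a list: `contigs`, `scaffolds` (tables with
#'   sequences), `graph`, `links`, `contig_stats`, `scaffold_stats`,
#'   `files`.
#' @export
run_assembly <- function(reads = NULL, libraries = NULL, k, p = 0L,
                         sp = 0.6, cs = 5L, ss = 5L,
                         m = default_min_overlap(k), ml = 0L,
                         out_prefix = "out",
                         max_tip_len = 2L * k, max_bubble_len = 3L * k,
                         min_bubble_identity = 0.9,
                         min_map_identity = 0.95,
                         genome_size = NULL, verbose = FALSE) {
  k <- as.integer(k); p <- as.integer(p)
  if (k < p + 1L) stop("k must be >= p + 1")
  if (sp <= 0 || sp > 1) stop("sp must be in (0, 1]")
  m <- as.integer(m)
  if (m > k - 1L) stop("m must be <= k - 1")
  if (is.null(reads)) {
    if (is.null(libraries)) stop("either 'reads' or 'libraries' is required")
    reads <- read_libraries(libraries)
  }
  if (!nrow(reads)) stop("no reads given")

  t0 <- proc.time()[3L]
  tick <- function(stage, extra = "") {
    t1 <- proc.time()[3L]
    log_stage(verbose, "[%6.1fs] %s%s", t1 - t0, stage, extra)
  }

  tab <- extract_kmers(reads, k)
  tick("k-mer extraction", sprintf(": %d distinct / %d occurrences",
                                   nrow(tab$counts), tab$n_occ))
  clusters <- cluster_kmers(tab, p)
  ncomp <- if (nrow(clusters)) max(clusters$component) else 0L
  tick("clustering", sprintf(": %d clusters (p = %d)", ncomp, p))
  consensus <- build_consensus_set(clusters, sp)
  tick("consensus/split", sprintf(": %d consensus k-mers",
                                  nrow(consensus$nodes)))
  g <- build_graph(consensus, tab)
  tick("graph construction", sprintf(": %d nodes, %d links",
                                     nrow(g$nodes), nrow(g$links)))
  g <- clean_graph(g, cs = cs, max_tip_len = max_tip_len,
                   max_bubble_len = max_bubble_len,
                   min_bubble_identity = min_bubble_identity)
  tick("cleaning", sprintf(": %d nodes, %d links",
                           nrow(g$nodes), nrow(g$links)))
  g <- extend_graph(g, m)
  tick("extension", sprintf(": %d nodes, %d links",
                            nrow(g$nodes), nrow(g$links)))

  anchors <- map_reads(reads, g, min_identity = min_map_identity)
  tick("read mapping", sprintf(": %d reads anchored",
                               length(unique(anchors$read_row))))
  # thread junctions; re-map while resolutions change the graph
  for (round in 1:5) {
    n_before <- nrow(g$nodes)
    g <- thread_junctions(g, anchors)
    if (nrow(g$nodes) == n_before) break
    anchors <- map_reads(reads, g, min_identity = min_map_identity)
  }
  tick("junction threading", sprintf(": %d nodes", nrow(g$nodes)))

  contigs <- assembly_contigs(g)
  links <- if (!is.null(reads$pair_id) && any(reads$mate %in% c(1L, 2L))) {
    infer_links(anchors, reads, g, ss = ss)
  } else NULL
  scaffolds <- build_scaffolds(g$nodes[, .(id, seq)], links, ml = ml)
  tick("scaffolding", sprintf(": %d links, %d scaffolds",
                              if (is.null(links)) 0L else nrow(links),
                              nrow(scaffolds)))

  contigs_out <- contigs[len >= ml]
  contig_stats <- assembly_stats(contigs_out$len, genome_size)
  scaffold_stats <- assembly_stats(nchar(scaffolds$seq), genome_size)

  files <- NULL
  if (!is.null(out_prefix)) {
    dir.create(dirname(file.path(out_prefix, ".")), recursive = TRUE,
               showWarnings = FALSE)
    f_contig <- file.path(out_prefix, "out_contig.fasta")
    f_scaf <- file.path(out_prefix, "out_scaffold.fasta")
    write_fasta(sprintf("contig_%d length=%d cov=%.1f",
                        seq_len(nrow(contigs_out)), contigs_out$len,
                        contigs_out$cov),
                contigs_out$seq, f_contig)
    write_fasta(scaffolds$name, scaffolds$seq, f_scaf)
    files <- c(contig = f_contig, scaffold = f_scaf)
  }
  if (verbose) {
    message("contigs:")
    print(contig_stats)
    message("scaffolds:")
    print(scaffold_stats)
  }
  invisible(list(contigs = contigs_out, scaffolds = scaffolds, graph = g,
                 links = links, contig_stats = contig_stats,
                 scaffold_stats = scaffold_stats, files = files))
}
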