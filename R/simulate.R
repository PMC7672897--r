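# Illumina-like data simulator: random genomes (optionally with planted
# repeats) and inward-facing paired reads with Gaussian insert sizes and
# substitution-only errors, matching the dominant error mode of the
# platform (no indels). Fully deterministic given a seed.

#' Random genome sequence
#'
#' I.i.d. bases at a given GC fraction. `repeat_spec = c(unit_len, copies)`
#' additionally samples one repeat unit and pastes it (replacing the
#' existing sequence, so genome length is unchanged) at `copies`
#' non-overlapping random positions.
#'
#' @param length Genome length in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @param repeat_spec Optional `c(unit_length, copies)`.
#' @param seed Optional RNG seed for reproducibility.
#' @return A DNA string.
#' @export
random_genome <- function(length, gc = 0.5, repeat_spec = NULL, seed = NULL) {
  if (length <= 0L) stop("length must be > 0")
  if (!is.null(seed)) set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(names(probs), length, replace = TRUE, prob = probs)
  gseq <- paste(bases, collapse = "")
  if (!is.null(repeat_spec)) {
    ul <- as.integer(repeat_spec[1L]); nc <- as.integer(repeat_spec[2L])
    if (nc * ul > length) stop("repeats do not fit in the genome")
    unit <- paste(sample(names(probs), ul, replace = TRUE, prob = probs),
                  collapse = "")
    # non-overlapping placement by rejection
    placed <- integer(0)
    tries <- 0L
    while (length(placed) < nc) {
      tries <- tries + 1L
      if (tries > 10000L) stop("could not place non-overlapping repeats")
      s <- sample.int(length - ul + 1L, 1L)
      if (!any(abs(placed - s) < ul)) placed <- c(placed, s)
    }
    for (s in placed) {
      substr(gseq, s, s + ul - 1L) <- unit
    }
  }
  gseq
}

#' Simulate inward-facing paired-end reads
#'
#' Fragments are drawn with normal(insert_mean, insert_sd) lengths clamped
#' to `[read_length, genome length]`, uniform start and uniform strand.
#' Mate 1 is the fragment prefix; mate 2 the reverse complement of the
#' fragment suffix. Each base is substituted with probability `error_rate`
#' to a uniformly chosen different base. The number of pairs is
#' `ceiling(coverage * genome length / (2 * read_length))`.
#'
#' @param genome DNA string.
#' @param read_length Read length in bp.
#' @param coverage Target fold coverage.
#' @param error_rate Per-base substitution probability.
#' @param insert_mean,insert_sd Fragment length distribution (bp).
#' @param orientation `"fr"` (inward, Illumina fragment libraries) or
#'   `"rf"` (outward); `"rf"` swaps the two mates.
#' @param lib Zero-based library index stored with the reads.
#' @param seed Optional RNG seed.
#' @return Read table as from [parse_library()], plus simulation truth
#'   columns `frag_start` (0-based), `frag_len` and `strand`.
#' @export
simulate_read_pairs <- function(genome, read_length = 100L, coverage = 30,
                                error_rate = 0, insert_mean = 300L,
                                insert_sd = 30, orientation = c("fr", "rf"),
                                lib = 0L, seed = NULL) {
  orientation <- match.arg(orientation)
  if (!is.null(seed)) set.seed(seed)
  G <- nchar(genome)
  rl <- as.integer(read_length)
  if (rl > G) stop("read_length exceeds genome length")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  np <- as.integer(ceiling(coverage * G / (2 * rl)))
  fl <- as.integer(pmin(pmax(round(rnorm(np, insert_mean, insert_sd)), rl), G))
  fs <- as.integer(floor(runif(np) * (G - fl + 1L)))  # 0-based
  strand <- ifelse(runif(np) < 0.5, "+", "-")
  frag <- substring(genome, fs + 1L, fs + fl)
  neg <- strand == "-"
  frag[neg] <- reverse_complement(frag[neg])
  r1 <- substr(frag, 1L, rl)
  r2 <- reverse_complement(substring(frag, fl - rl + 1L, fl))
  if (orientation == "rf") {
    tmp <- r1; r1 <- r2; r2 <- tmp
  }
  add_errors <- function(seqs) {
    ne <- rbinom(length(seqs), rl, error_rate)
    hit <- which(ne > 0L)
    for (i in hit) {
      pos <- sample.int(rl, ne[i])
      s <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
      for (p in pos) {
        s[p] <- sample(setdiff(BASES, s[p]), 1L)
      }
      seqs[i] <- paste(s, collapse = "")
    }
    seqs
  }
  if (error_rate > 0) {
    r1 <- add_errors(r1)
    r2 <- add_errors(r2)
  }
  pid <- paste0("L", lib, "P", seq_len(np))
  rbind(
    data.table(id = paste0(pid, "/1"), seq = r1, mate = 1L, pair_id = pid,
               lib = as.integer(lib), insert = as.integer(insert_mean),
               frag_start = fs, frag_len = fl, strand = strand),
    data.table(id = paste0(pid, "/2"), seq = r2, mate = 2L, pair_id = pid,
               lib = as.integer(lib), insert = as.integer(insert_mean),
               frag_start = fs, frag_len = fl, strand = strand)
  )
}

#' Write simulated pairs as two FASTQ files
#'
#' @param pairs Table from [simulate_read_pairs()].
#' @param path_1,path_2 Output FASTQ paths (`.gz` for gzip).
#' @export
write_pair_fastq <- function(pairs, path_1, path_2) {
  m1 <- pairs[mate == 1L]; m2 <- pairs[mate == 2L]
  setkey(m1, pair_id); setkey(m2, pair_id)
  write_fastq(m1$id, m1$seq, path_1)
  write_fastq(m2$id, m2$seq, path_2)
  invisible(c(path_1, path_2))
}
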