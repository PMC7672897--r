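# Assembly summary statistics. N50 here follows the assembly-total
# convention: the minimum length, taking sequences in descending order,
# needed to cover half the denominator (by default the total sequence
# produced; pass the genome size for reference-based reporting).

#' N50 of a set of sequence lengths
#'
#' Sorts lengths in descending order and returns the first length at which
#' the running total reaches half the denominator.
#'
#' @param lengths Positive sequence lengths (bp).
#' @param denominator Total to cover half of; defaults to `sum(lengths)`.
#' @return The N50 length.
#' @examples
#' n50(c(5, 4, 3, 2, 1))  # 4
#' @export
n50 <- function(lengths, denominator = sum(lengths)) {
  if (length(lengths) == 0L) stop("no lengths given")
  if (denominator <= 0) stop("denominator must be > 0")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= denominator / 2)[1L]]
}

#' E-size of a set of sequence lengths
#'
#' The expected length of the sequence containing a uniformly random base
#' of the denominator: sum(L^2) / denominator.
#'
#' @inheritParams n50
#' @return The E-size (a real number, bp).
#' @examples
#' e_size(c(3, 1), 4)  # 2.5
#' @export
e_size <- function(lengths, denominator = sum(lengths)) {
  if (length(lengths) == 0L) stop("no lengths given")
  if (denominator <= 0) stop("denominator must be > 0")
  sum(as.numeric(lengths)^2) / denominator
}

#' Summary statistics of an assembly
#'
#' @param lengths Sequence lengths in bp (scaffold lengths count their N
#'   gap characters).
#' @param genome_size Optional denominator for N50/E-size; default is the
#'   assembly total.
#' @return An `assembly_stats` object: `num`, `total`, `max`, `n50`,
#'   `e_size`.
#' @export
assembly_stats <- function(lengths, genome_size = NULL) {
  denom <- if (is.null(genome_size)) sum(lengths) else genome_size
  structure(list(num = length(lengths), total = sum(lengths),
                 max = if (length(lengths)) max(lengths) else 0L,
                 n50 = if (length(lengths)) n50(lengths, denom) else 0L,
                 e_size = if (length(lengths)) e_size(lengths, denom) else 0),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("%8s %12s %10s %10s %10s\n", "Num", "Total", "Max", "N50",
              "E-size"))
  cat(sprintf("%8d %12d %10d %10d %10.1f\n", x$num, x$total, x$max, x$n50,
              x$e_size))
  invisible(x)
}
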