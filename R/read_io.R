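# Read input: FASTQ/FASTA libraries, paired or single, normalised to a
# uniform in-memory table of reads.

#' Reverse complement of DNA strings
#'
#' Vectorised Watson-Crick reverse complement over the alphabet
#' `{A, C, G, T, N}`; `N` maps to `N`.
#'
#' @param x Character vector of uppercase DNA strings.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement(c("ACGT", "AAAC"))
#' @export
reverse_complement <- function(x) {
  if (length(x) == 0L) return(character(0))
  if (!is.character(x)) stop("'x' must be a character vector")
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         x[which(bad)[1L]])
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# orientation helpers: orientations are "+"/"-" characters
flip_orient <- function(o) ifelse(o == "+", "-", "+")

orient_seq <- function(s, o) {
  neg <- o == "-"
  if (any(neg)) s[neg] <- reverse_complement(s[neg])
  s
}

detect_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- ""
  while (!nzchar(first)) {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) return("empty")
    first <- trimws(line)
  }
  lead <- substr(first, 1L, 1L)
  if (lead == "@") "fastq" else if (lead == ">") "fasta"
  else stop("cannot detect format of '", path,
            "': first record starts with '", lead, "'")
}

read_seq_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- detect_format(path)
  if (fmt == "empty") {
    return(data.table(id = character(0), seq = character(0)))
  }
  ss <- tryCatch(
    Biostrings::readDNAStringSet(path, format = fmt),
    error = function(e) stop("unreadable record in '", path, "': ",
                             conditionMessage(e))
  )
  ids <- sub("\\s.*$", "", names(ss))
  data.table(id = ids, seq = toupper(as.character(ss)))
}

#' Parse one sequencing library
#'
#' Reads a single-end or paired-end library (FASTQ or FASTA, optionally
#' gzipped; format auto-detected from the first record). Paired files are
#' joined positionally: record i of file 1 is the mate of record i of
#' file 2. Sequences are uppercased; qualities are discarded (the assembly
#' method never uses them).
#'
#' @param path_1 Path to the first (or only) read file.
#' @param path_2 Optional path to the mate file.
#' @param insert_size Library insert size in bp (required when paired).
#' @param library_index Zero-based library number stored with each read.
#' @return A [data.table::data.table] with columns `id`, `seq`, `mate`
#'   (1 or 2, 0 for single-end), `pair_id` (shared by the two mates),
#'   `lib` and `insert`.
#' @export
parse_library <- function(path_1, path_2 = NULL, insert_size = NA_integer_,
                          library_index = 0L) {
  r1 <- read_seq_file(path_1)
  if (is.null(path_2)) {
    if (nrow(r1) == 0L) {
      return(data.table(id = character(0), seq = character(0),
                        mate = integer(0), pair_id = character(0),
                        lib = integer(0), insert = integer(0)))
    }
    return(data.table(id = r1$id, seq = r1$seq, mate = 0L,
                      pair_id = paste0("L", library_index, "S", seq_len(nrow(r1))),
                      lib = as.integer(library_index),
                      insert = as.integer(insert_size)))
  }
  if (is.na(insert_size) || insert_size <= 0L) {
    stop("a positive insert_size is required for the paired library ",
         path_1, " / ", path_2)
  }
  r2 <- read_seq_file(path_2)
  if (nrow(r1) != nrow(r2)) {
    stop("paired files have different record counts: ",
         path_1, " has ", nrow(r1), ", ", path_2, " has ", nrow(r2))
  }
  if (nrow(r1) == 0L) {
    return(data.table(id = character(0), seq = character(0),
                      mate = integer(0), pair_id = character(0),
                      lib = integer(0), insert = integer(0)))
  }
  pid <- paste0("L", library_index, "P", seq_len(nrow(r1)))
  rbind(
    data.table(id = r1$id, seq = r1$seq, mate = 1L, pair_id = pid,
               lib = as.integer(library_index),
               insert = as.integer(insert_size)),
    data.table(id = r2$id, seq = r2$seq, mate = 2L, pair_id = pid,
               lib = as.integer(library_index),
               insert = as.integer(insert_size))
  )
}

#' Read a set of libraries into one read table
#'
#' @param libraries A list of library specs, each a list with elements
#'   `path_1`, optional `path_2` and `insert_size`. Library order defines
#'   the zero-based `lib` index.
#' @return Combined read table (see [parse_library()]).
#' @export
read_libraries <- function(libraries) {
  out <- lapply(seq_along(libraries), function(i) {
    sp <- libraries[[i]]
    parse_library(sp$path_1, sp$path_2,
                  insert_size = if (is.null(sp$insert_size)) NA_integer_
                                else as.integer(sp$insert_size),
                  library_index = i - 1L)
  })
  rbindlist(out)
}

# Split sequences into N-free fragments over {A,C,G,T}. Any non-ACGT base
# breaks a read; fragments inherit the index of their source sequence.
split_fragments <- function(seqs) {
  has_bad <- grepl("[^ACGT]", seqs)
  if (!any(has_bad)) {
    return(data.table(origin = seq_along(seqs), frag = seqs))
  }
  clean <- data.table(origin = which(!has_bad), frag = seqs[!has_bad])
  parts <- regmatches(seqs[has_bad], gregexpr("[ACGT]+", seqs[has_bad]))
  nl <- lengths(parts)
  dirty <- data.table(origin = rep(which(has_bad), nl),
                      frag = unlist(parts, use.names = FALSE))
  out <- rbind(clean, dirty)
  setorder(out, origin)
  out[nzchar(frag)]
}

#' Write reads as FASTQ
#'
#' Writes standard 4-line FASTQ records with constant quality `I`.
#' A `.gz` suffix on `path` gives gzip output.
#'
#' @param ids,seqs Character vectors of read names and sequences.
#' @param path Output path.
#' @export
write_fastq <- function(ids, seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param ids,seqs Character vectors of names and sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(ids, seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path, format = "fasta", width = width)
  invisible(path)
}
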