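#' DNA sequence validation
#'
#' Upper-cases input and rejects any character outside `{A,C,G,T,N}`;
#' characters outside the alphabet signal data corruption and are never
#' silently coerced.
#'
#' @param x Character vector of DNA sequences.
#' @return The validated, upper-cased character vector.
#' @export
as_dna <- function(x) {
  if (!is.character(x)) stop("DNA sequences must be supplied as character strings")
  x <- toupper(x)
  bad <- regexpr("[^ACGTN]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid DNA character '%s' at position %d of sequence %d",
                 substr(x[i], bad[i], bad[i]), bad[i], i))
  }
  x
}

#' Reverse complement of DNA sequences
#'
#' `N` maps to `N`; applying twice returns the input.
#'
#' @param seq Character vector over `{A,C,G,T,N}` (lowercase accepted).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ACGTN") # "NACGT"
#' @export
reverse_complement <- function(seq) {
  seq <- as_dna(seq)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  names(out) <- names(seq)
  out
}

#' Construct a DNA double strand
#'
#' A read paired with its reverse complement: the unit of scoring, since a
#' binding site may lie on either strand.
#'
#' @param forward Forward-strand sequence (single string).
#' @param id Read identifier.
#' @return An object of class `dna_double_strand` with fields `forward`,
#'   `reverse` and `id`.
#' @export
double_strand <- function(forward, id = "") {
  forward <- as_dna(forward)
  stopifnot(length(forward) == 1L)
  structure(list(forward = forward,
                 reverse = reverse_complement(forward),
                 id = as.character(id)),
            class = "dna_double_strand")
}

#' @export
print.dna_double_strand <- function(x, ...) {
  cat("DNA double strand", if (nzchar(x$id)) paste0("'", x$id, "'"), "\n")
  cat("  5'-", x$forward, "-3'\n", sep = "")
  cat("  3'-", reverse_complement(x$reverse), "-5'\n", sep = "")
  invisible(x)
}

# Coerce a double strand or a plain string to a double strand.
as_double_strand <- function(x, id = "") {
  if (inherits(x, "dna_double_strand")) x else double_strand(x, id)
}

#' Extract a window from a double strand
#'
#' Coordinates are 0-based half-open and always expressed on the forward
#' strand's axis; `strand = "-"` returns the window as read from the
#' reverse-complement strand (i.e. the reverse complement of the forward
#' segment).
#'
#' @param ds A `dna_double_strand` (or a plain sequence string).
#' @param start 0-based offset on the forward axis.
#' @param length Window length.
#' @param strand `"+"` or `"-"`.
#' @return The window as a character string.
#' @export
window_at <- function(ds, start, length, strand = "+") {
  ds <- as_double_strand(ds)
  L <- nchar(ds$forward)
  strand <- match.arg(strand, c("+", "-"))
  if (start < 0L || length < 1L || start + length > L)
    stop(sprintf("window [%d, %d) out of range for read of length %d",
                 start, start + length, L))
  fwd <- substr(ds$forward, start + 1L, start + length)
  if (strand == "+") fwd else reverse_complement(fwd)
}

#' Read DNA sequences from a file
#'
#' FASTA and FASTQ are parsed with Biostrings (gzip-transparent); FASTQ
#' qualities are discarded because the models use sequence content only.
#' `plain` reads one sequence per line, for SELEX-style dumps.
#'
#' @param path File path.
#' @param format `"fasta"`, `"fastq"` or `"plain"`; `"auto"` guesses from
#'   the file extension (default plain).
#' @return Named character vector of sequences (names are record ids where
#'   the format carries them), in file order.
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq", "plain")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    base <- sub("\\.(gz|bz2)$", "", path)
    ext <- tolower(tools::file_ext(base))
    format <- if (ext %in% c("fa", "fasta", "fna")) "fasta"
      else if (ext %in% c("fq", "fastq")) "fastq"
      else "plain"
  }
  if (format %in% c("fasta", "fastq")) {
    set <- Biostrings::readDNAStringSet(path, format = format)
    out <- as.character(set)
    names(out) <- sub("\\s.*$", "", names(set))
  } else {
    con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
    lines <- readLines(con)
    close(con)
    lines <- trimws(lines)
    out <- lines[nzchar(lines)]
  }
  if (length(out)) as_dna(out) else character(0)
}

#' Write sequences to FASTA
#'
#' @param x Named (or unnamed) character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  ids <- names(x) %||% paste0("seq", seq_along(x))
  if (is.null(names(x))) names(x) <- ids
  empty <- !nzchar(ids)
  ids[empty] <- paste0("seq", which(empty))
  writeLines(paste0(">", ids, "\n", unname(x)), path)
  invisible(path)
}
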