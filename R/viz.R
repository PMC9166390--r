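# Binding specificity visualization: motif construction from forest
# out-of-bag behavior, and motif file writers.

#' Construct a PWM from positive out-of-bag predictions
#'
#' Takes the positive-labeled training windows whose out-of-bag class-1
#' probability exceeds `threshold`, counts bases per position and
#' column-normalizes. Intended for JointRF-style fixed-configuration
#' windows; ComBind forests can be exported per-orientation, but their
#' relaxed gap spacing and orientation mixing blur the motif.
#'
#' @param forest A `binding_forest` trained on `windows`.
#' @param windows The training windows (character vector) in training order.
#' @param labels The 0/1 training labels in the same order.
#' @param threshold OOB probability cut-off defining a positive OOB
#'   prediction (default 0.5).
#' @param name Motif name for the result.
#' @return A [pwm] of the forest's window length.
#' @export
oob_positive_pfm <- function(forest, windows, labels, threshold = 0.5,
                             name = "oob_positive") {
  stopifnot(inherits(forest, "binding_forest"))
  labels <- as.integer(labels)
  if (length(windows) != length(labels)) stop("windows and labels differ in length")
  oob <- oob_probabilities(forest)
  if (length(oob) != length(windows))
    stop("forest was not trained on these windows (row count mismatch)")
  keep <- labels == 1L & !is.na(oob) & oob > threshold
  if (!any(keep))
    stop("no positive windows with OOB probability above the threshold")
  enc <- encode_reads(windows[keep])
  counts <- vapply(seq_len(ncol(enc)), function(j)
    tabulate(enc[, j], nbins = 4L), integer(4))
  pwm(counts, name = name, normalize = TRUE)
}

#' Write a motif to a file
#'
#' Formats: `jaspar` (`>name` header and `A [ ... ]` rows), `meme` (MEME
#' minimal motif format, for downstream logo tools) and `matrix4rows`
#' (plain 4 whitespace-separated rows). Probabilities are written with 6
#' decimals and round-trip through [parse_pwm] at that precision.
#'
#' @param x A [pwm].
#' @param path Output path.
#' @param format `"jaspar"`, `"meme"` or `"matrix4rows"`.
#' @return `path`, invisibly.
#' @export
write_motif <- function(x, path, format = c("jaspar", "meme", "matrix4rows")) {
  stopifnot(inherits(x, "pwm"))
  format <- match.arg(format)
  p <- formatC(x$probs, digits = 6, format = "f")
  lines <- switch(format,
    jaspar = c(paste0(">", x$name),
               vapply(1:4, function(i)
                 sprintf("%s [ %s ]", BASES[i], paste(p[i, ], collapse = " ")),
                 character(1))),
    matrix4rows = vapply(1:4, function(i) paste(p[i, ], collapse = " "),
                         character(1)),
    meme = c("MEME version 4", "",
             "ALPHABET= ACGT", "",
             "strands: + -", "",
             "Background letter frequencies",
             "A 0.25 C 0.25 G 0.25 T 0.25", "",
             paste("MOTIF", x$name),
             sprintf("letter-probability matrix: alength= 4 w= %d", x$length),
             vapply(seq_len(x$length), function(j)
               paste(formatC(x$probs[, j], digits = 6, format = "f"),
                     collapse = " "), character(1))))
  writeLines(lines, path)
  invisible(path)
}
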