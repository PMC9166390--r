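#' Construct a position weight matrix
#'
#' @param probs 4 x L numeric matrix of per-position base probabilities,
#'   rows in order A, C, G, T. Columns must each sum to 1 (within 1e-9);
#'   a count matrix can be normalized with `normalize = TRUE`.
#' @param name Motif name.
#' @param normalize Divide each column by its total before validating.
#' @return An object of class `pwm`.
#' @export
pwm <- function(probs, name = "motif", normalize = FALSE) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("a PWM must have exactly 4 rows (A, C, G, T)")
  if (!is.numeric(probs) || anyNA(probs)) stop("PWM entries must be numeric and non-missing")
  if (any(probs < 0)) stop("PWM entries must be non-negative")
  if (normalize) {
    tot <- colSums(probs)
    if (any(tot <= 0)) stop("cannot normalize a PWM column with total <= 0")
    probs <- sweep(probs, 2, tot, "/")
  }
  if (any(abs(colSums(probs) - 1) > 1e-9))
    stop("every PWM column must sum to 1 (use normalize = TRUE for count matrices)")
  if (any(probs > 1 + 1e-12)) stop("PWM entries must lie in [0, 1]")
  dimnames(probs) <- list(BASES, NULL)
  structure(list(probs = probs, name = as.character(name), length = ncol(probs)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, digits = 3, ...) {
  cat(sprintf("PWM '%s' (%d columns)\n", x$name, x$length))
  print(round(x$probs, digits))
  invisible(x)
}

#' Parse a PWM from a file
#'
#' Two dialects: `matrix4rows` (4 whitespace-separated numeric rows in
#' A, C, G, T order, optional leading `>` or `#` header line) and `jaspar`
#' (`>id name` header, then rows like `A [ 10 5 ... ]`). Counts are
#' normalized to column probabilities.
#'
#' @param path File path.
#' @param dialect `"matrix4rows"` or `"jaspar"`.
#' @return A [pwm].
#' @export
parse_pwm <- function(path, dialect = c("matrix4rows", "jaspar")) {
  dialect <- match.arg(dialect)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  name <- tools::file_path_sans_ext(basename(path))
  if (dialect == "jaspar") {
    hdr <- grepl("^>", lines)
    if (any(hdr)) name <- sub("^>\\s*", "", lines[which(hdr)[1L]])
    lines <- lines[!hdr]
    rows <- lapply(lines, function(l) {
      base <- sub("^([ACGTacgt]).*$", "\\1", l)
      rest <- sub("^[ACGTacgt]?\\s*\\[?", "", l)
      nums <- regmatches(rest, gregexpr("[0-9][0-9.eE+-]*", rest))[[1]]
      list(base = toupper(base), values = as.numeric(nums))
    })
    if (length(rows) != 4L) stop("JASPAR record must have 4 base rows, got ", length(rows))
    m <- matrix(NA_real_, 4, length(rows[[1]]$values), dimnames = list(BASES, NULL))
    for (r in rows) {
      if (!r$base %in% BASES) stop("unrecognized base row: ", r$base)
      if (length(r$values) != ncol(m)) stop("ragged JASPAR matrix rows")
      m[r$base, ] <- r$values
    }
  } else {
    lines <- lines[!grepl("^[>#]", lines)]
    if (length(lines) != 4L)
      stop("matrix4rows PWM must have exactly 4 numeric rows, got ", length(lines))
    vals <- lapply(strsplit(lines, "\\s+"), as.numeric)
    if (anyNA(unlist(vals))) stop("non-numeric entry in PWM file")
    L <- unique(lengths(vals))
    if (length(L) != 1L) stop("ragged PWM rows (unequal column counts)")
    m <- do.call(rbind, vals)
  }
  if (anyNA(m)) stop("could not parse PWM from ", path)
  if (any(m < 0)) stop("negative entry in PWM file")
  pwm(m, name = name, normalize = TRUE)
}

#' Convert a PWM to a log-odds matrix
#'
#' Entries are `log((p + pseudocount * background_b) / (1 + pseudocount) /
#' background_b)`. With `pseudocount = 0`, zero probabilities yield `-Inf`,
#' which is permitted and handled downstream by [replace_neg_inf]. Uniform
#' columns map to exactly 0 under the uniform background, so an `N` position
#' (scored as probability 0.25) contributes zero.
#'
#' @param x A [pwm].
#' @param background Length-4 probability vector (A, C, G, T); default
#'   uniform.
#' @param pseudocount Non-negative pseudocount mass; default 0.
#' @param base Logarithm base: `"e"` (default) or `"2"`. AUROC evaluation is
#'   rank-based, so the base cannot affect it.
#' @return An object of class `log_odds_matrix` with fields `scores`,
#'   `background` and `name`.
#' @export
to_log_odds <- function(x, background = rep(0.25, 4), pseudocount = 0, base = c("e", "2")) {
  stopifnot(inherits(x, "pwm"))
  base <- match.arg(base)
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop("background must be a strictly positive length-4 probability vector")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  p <- sweep(x$probs, 1, pseudocount * background, "+") / (1 + pseudocount)
  s <- log(sweep(p, 1, background, "/"))
  if (base == "2") s <- s / log(2)
  structure(list(scores = s, background = background, name = x$name,
                 length = ncol(s), log_base = base),
            class = "log_odds_matrix")
}

#' Extend a PWM with uniform columns
#'
#' Appends `(0.25, 0.25, 0.25, 0.25)` columns on one side until the motif is
#' `target_len` columns long, covering the binding space of the partner TF
#' without specifying gap or overlap. Motifs longer than `target_len` are an
#' error (never truncated).
#'
#' @param x A [pwm].
#' @param side `"left"` or `"right"`: where the uniform columns are added.
#' @param target_len Target length (default 25).
#' @return A [pwm] of length `target_len`.
#' @export
extend_pwm <- function(x, side = c("right", "left"), target_len = 25L) {
  stopifnot(inherits(x, "pwm"))
  side <- match.arg(side)
  if (x$length > target_len)
    stop(sprintf("motif '%s' has %d columns, longer than target %d",
                 x$name, x$length, target_len))
  if (x$length == target_len) return(x)
  pad <- matrix(0.25, 4, target_len - x$length)
  m <- if (side == "right") cbind(x$probs, pad) else cbind(pad, x$probs)
  pwm(m, name = paste0(x$name, "_ext", substr(side, 1, 1), target_len))
}

#' Pad a sequence with N characters
#'
#' Prepends and appends `k` `N`s; scanning scores `N` as probability 0.25
#' (zero in log-odds), so padding lets a matrix overhang the read ends.
#'
#' @param seq Character vector of sequences.
#' @param k Number of `N`s on each side (default 5).
#' @return Padded sequences.
#' @export
pad_with_N <- function(seq, k = 5L) {
  seq <- as_dna(seq)
  if (k < 0) stop("k must be >= 0")
  if (k == 0) return(seq)
  pad <- strrep("N", k)
  out <- paste0(pad, seq, pad)
  names(out) <- names(seq)
  out
}

# 5-row score matrix (A,C,G,T,N) used by the scanning core. Probability
# matrices are scanned in log space (products compare identically); N scores
# probability 0.25, i.e. log(0.25) in log-probability space and 0 in
# log-odds space.
score_rows <- function(matrix) {
  if (inherits(matrix, "pwm")) {
    rbind(log(matrix$probs), N = log(0.25))
  } else if (inherits(matrix, "log_odds_matrix")) {
    rbind(matrix$scores, N = 0)
  } else stop("matrix must be a 'pwm' or a 'log_odds_matrix'")
}

# Window scores of one score matrix over encoded reads: n x (L - W + 1).
window_scores <- function(S, enc) {
  n <- nrow(enc); L <- ncol(enc); W <- ncol(S)
  P <- L - W + 1L
  out <- matrix(0, n, P)
  for (s in seq_len(P)) {
    acc <- S[enc[, s], 1L]
    if (W > 1L) for (j in 2:W) acc <- acc + S[enc[, s + j - 1L], j]
    out[, s] <- acc
  }
  out
}

# Best hit of one score matrix over both strands of encoded reads.
# Tie-break: "+" strand before "-", then smallest forward-axis start.
# A "-"-strand window at reverse offset r (0-based) occupies forward starts
# L - W - r, so within "-" ties the *last* maximum column wins.
scan_core <- function(S, enc_f, enc_r) {
  W <- ncol(S)
  L <- ncol(enc_f)
  Wf <- window_scores(S, enc_f)
  Wr <- window_scores(S, enc_r)
  bf <- do.call(pmax, c(as.data.frame(Wf), na.rm = FALSE))
  br <- do.call(pmax, c(as.data.frame(Wr), na.rm = FALSE))
  use_rev <- br > bf
  score <- ifelse(use_rev, br, bf)
  # max.col tolerates all--Inf rows (argmax defaults to an end column,
  # matching the tie-break). -Inf entries must not reach max.col as NaN.
  sf <- max.col(replace(Wf, !is.finite(Wf), -.Machine$double.xmax),
                ties.method = "first")
  sr <- max.col(replace(Wr, !is.finite(Wr), -.Machine$double.xmax),
                ties.method = "last")
  start <- ifelse(use_rev, L - W - (sr - 1L), sf - 1L)
  list(score = score,
       start = as.integer(start),
       strand = ifelse(use_rev, "-", "+"))
}

# Reverse-complement an encoded read matrix without string round-trips.
encode_revcomp <- function(enc) {
  comp <- c(4L, 3L, 2L, 1L, 5L)[enc]
  dim(comp) <- dim(enc)
  comp[, rev(seq_len(ncol(comp))), drop = FALSE]
}

# Vectorized best-hit scan for a list of matrices over many reads.
# Returns data.frame(score, start, strand, matrix) with ties resolved by
# matrix order (earlier wins), then strand, then start.
scan_reads <- function(matrices, reads, pad = FALSE, pad_k = 5L) {
  if (inherits(matrices, c("pwm", "log_odds_matrix"))) matrices <- list(matrices)
  if (!length(matrices)) stop("at least one matrix is required")
  reads <- as_dna(reads)
  if (pad) reads <- pad_with_N(reads, pad_k)
  L <- unique(nchar(reads))
  if (length(L) != 1L)
    stop("scan_reads requires equal-length reads; split by length first")
  enc_f <- encode_reads(reads)
  enc_r <- encode_revcomp(enc_f)
  best <- NULL
  for (k in seq_along(matrices)) {
    S <- score_rows(matrices[[k]])
    if (ncol(S) > L)
      stop(sprintf("matrix of length %d is longer than the (padded) read length %d",
                   ncol(S), L))
    hit <- scan_core(S, enc_f, enc_r)
    nm <- matrices[[k]]$name %||% paste0("matrix", k)
    if (is.null(best)) {
      best <- data.frame(score = hit$score, start = hit$start,
                         strand = hit$strand, matrix = nm,
                         stringsAsFactors = FALSE)
    } else {
      repl <- hit$score > best$score
      best$score[repl] <- hit$score[repl]
      best$start[repl] <- hit$start[repl]
      best$strand[repl] <- hit$strand[repl]
      best$matrix[repl] <- nm
    }
  }
  best
}

#' Best-scoring window of a matrix over a double strand
#'
#' Evaluates every window on both strands and returns the maximum. For a
#' [pwm] the window score is the product of per-position probabilities
#' (`N` contributes 0.25); for a log-odds matrix it is the sum of
#' per-position log-odds (`N` contributes 0). Ties are broken in favour of
#' the `+` strand, then the smallest forward-axis start.
#'
#' @param matrix A [pwm] or [to_log_odds] matrix.
#' @param ds A `dna_double_strand` or sequence string.
#' @param pad Pad the read with `pad_k` `N`s on both ends before scanning.
#' @param pad_k Padding width (default 5).
#' @return A `scan_hit`: list with `score`, `start` (0-based, on the
#'   (padded) forward axis), `strand` and `matrix_name`.
#' @export
scan_max <- function(matrix, ds, pad = FALSE, pad_k = 5L) {
  ds <- as_double_strand(ds)
  hit <- scan_reads(list(matrix), ds$forward, pad = pad, pad_k = pad_k)
  score <- hit$score[1L]
  if (inherits(matrix, "pwm")) score <- exp(score)
  structure(list(score = score, start = hit$start[1L], strand = hit$strand[1L],
                 matrix_name = hit$matrix[1L]),
            class = "scan_hit")
}

#' Maximum PWM-set score of a double strand
#'
#' Pads the read with `pad_k` `N`s, scans every matrix over both strands and
#' returns the highest maximum-per-position score. Used as the PWM-scoring
#' baseline when an experiment reports several motifs for a pair; `-Inf`
#' results are replaced at the dataset level with [replace_neg_inf].
#'
#' @param matrices A list of log-odds matrices (or [pwm]s, scanned as
#'   log-probabilities).
#' @param ds A `dna_double_strand` or sequence string.
#' @param pad,pad_k N-padding control (default: pad with five `N`s).
#' @return The maximum score (may be `-Inf`).
#' @export
score_with_pwm_set <- function(matrices, ds, pad = TRUE, pad_k = 5L) {
  ds <- as_double_strand(ds)
  pwm_scores(matrices, ds$forward, pad = pad, pad_k = pad_k)[1L]
}

#' Vectorized PWM-set scores for many reads
#'
#' @param matrices List of log-odds matrices (or [pwm]s).
#' @param reads Character vector of equal-length reads.
#' @param pad,pad_k N-padding control.
#' @return Numeric score vector, one per read (possibly `-Inf`).
#' @export
pwm_scores <- function(matrices, reads, pad = TRUE, pad_k = 5L) {
  scan_reads(matrices, reads, pad = pad, pad_k = pad_k)$score
}

#' Replace -Inf scores with the dataset minimum finite score
#'
#' Applied after maximum-per-position selection when log-odds matrices with
#' zero-probability entries leave `-Inf` scores.
#'
#' @param scores Numeric vector with at least one finite value.
#' @return `scores` with every `-Inf` replaced by `min(scores[finite])`.
#' @export
replace_neg_inf <- function(scores) {
  fin <- is.finite(scores)
  if (!any(fin)) stop("all scores are -Inf; nothing to impute from")
  scores[scores == -Inf] <- min(scores[fin])
  scores
}
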