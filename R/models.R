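# JointRF and ComBind: window selection with PWMs, forest training on
# positional nucleotide features, and maximum-per-position /
# orientation-averaged double-strand scoring.

# Extract the selected window strings given a scan hit table.
hits_to_windows <- function(reads, hits, W) {
  fwd <- substr(reads, hits$start + 1L, hits$start + W)
  flip <- hits$strand == "-"
  if (any(flip)) fwd[flip] <- reverse_complement(fwd[flip])
  fwd
}

#' Select training windows with a pairwise PWM (JointRF)
#'
#' For every read (positive and negative alike) the probability-score
#' maximizing window of the matrix's length is chosen over both strands,
#' without N-padding: training reads are pure `{A,C,G,T}` and the window
#' must stay inside the read.
#'
#' @param pwm A pairwise (composite) [pwm].
#' @param reads Character vector of equal-length reads.
#' @param labels Optional 0/1 labels carried through to the output.
#' @return A data.frame with columns `id`, `window`, `start`, `strand`,
#'   `matrix`, `score` and (if given) `label`.
#' @export
select_windows_jointrf <- function(pwm, reads, labels = NULL) {
  stopifnot(inherits(pwm, "pwm"))
  reads <- as_dna(reads)
  hits <- scan_reads(list(pwm), reads, pad = FALSE)
  out <- data.frame(id = names(reads) %||% as.character(seq_along(reads)),
                    window = hits_to_windows(reads, hits, pwm$length),
                    start = hits$start, strand = hits$strand,
                    matrix = hits$matrix, score = exp(hits$score),
                    stringsAsFactors = FALSE)
  if (!is.null(labels)) out$label <- as.integer(labels)
  out
}

#' Select training windows for one ComBind orientation
#'
#' In orientation `TF1-TF2` the candidate matrices are the TF1 motif
#' extended rightward and the TF2 motif extended leftward with uniform
#' `(0.25, 0.25, 0.25, 0.25)` columns to 25 nt; in `TF2-TF1` the sides swap.
#' Each read contributes the single 25-nt window maximizing the probability
#' score over both candidate matrices and both strands, so the chosen window
#' covers one TF's most probable site plus undetermined space for the
#' partner.
#'
#' @param pwm_tf1,pwm_tf2 Individual-TF [pwm]s (at most 25 columns each).
#' @param orientation `"TF1-TF2"` or `"TF2-TF1"`.
#' @param reads Character vector of equal-length reads (>= 25 nt).
#' @param labels Optional 0/1 labels carried through.
#' @param window_length Extension target (default 25).
#' @return As [select_windows_jointrf] (windows are `window_length` nt).
#' @export
select_windows_combind <- function(pwm_tf1, pwm_tf2,
                                   orientation = c("TF1-TF2", "TF2-TF1"),
                                   reads, labels = NULL, window_length = 25L) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(pwm_tf1, "pwm"), inherits(pwm_tf2, "pwm"))
  reads <- as_dna(reads)
  mats <- if (orientation == "TF1-TF2") {
    list(extend_pwm(pwm_tf1, "right", window_length),
         extend_pwm(pwm_tf2, "left", window_length))
  } else {
    list(extend_pwm(pwm_tf2, "right", window_length),
         extend_pwm(pwm_tf1, "left", window_length))
  }
  hits <- scan_reads(mats, reads, pad = FALSE)
  out <- data.frame(id = names(reads) %||% as.character(seq_along(reads)),
                    window = hits_to_windows(reads, hits, window_length),
                    start = hits$start, strand = hits$strand,
                    matrix = hits$matrix, score = exp(hits$score),
                    stringsAsFactors = FALSE)
  if (!is.null(labels)) out$label <- as.integer(labels)
  out
}

# All windows of length W over both strands of equal-length reads, as one
# character matrix n x 2P (forward starts 1..P, then reverse).
all_windows <- function(reads, W) {
  L <- unique(nchar(reads))
  stopifnot(length(L) == 1L)
  if (W > L) stop(sprintf("read length %d is shorter than window length %d", L, W))
  P <- L - W + 1L
  rev <- reverse_complement(reads)
  cols <- vector("list", 2L * P)
  for (s in seq_len(P)) {
    cols[[s]] <- substr(reads, s, s + W - 1L)
    cols[[P + s]] <- substr(rev, s, s + W - 1L)
  }
  do.call(cbind, cols)
}

# Maximum forest probability over all windows (both strands) of each read.
max_window_prob <- function(forest, reads) {
  wmat <- all_windows(reads, forest$window_length)
  n <- nrow(wmat)
  p <- predict(forest, as.vector(wmat))
  apply(matrix(p, nrow = n), 1L, max)
}

#' Train a JointRF model
#'
#' Selects, for each candidate pairwise PWM, the maximum-probability window
#' of every training read ([select_windows_jointrf]) and trains a forest on
#' the positional nucleotides. With several candidate PWMs, one model is
#' trained per PWM and the one with the highest AUROC on the held-out
#' evaluation set is returned (selection never touches the final test set).
#'
#' @param reads,labels Training reads and 0/1 labels.
#' @param pwms A [pwm] or list of pairwise [pwm]s.
#' @param config A [forest_config].
#' @param eval_reads,eval_labels Held-out evaluation set; required when more
#'   than one PWM is supplied.
#' @return A `jointrf_model`: `forest`, `pairwise_pwm`, `window_length`, and
#'   `pwm_aurocs` (one AUROC per candidate PWM, `NA` when no selection was
#'   needed).
#' @export
train_jointrf <- function(reads, labels, pwms, config = forest_config(),
                          eval_reads = NULL, eval_labels = NULL) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (!length(pwms)) stop("at least one pairwise PWM is required")
  if (length(pwms) > 1L && (is.null(eval_reads) || is.null(eval_labels)))
    stop("an evaluation split is required to select among multiple PWMs")
  seeds <- if (is.null(config$seed)) rep(list(NULL), length(pwms))
           else as.list(spawn_seeds(config$seed, length(pwms)))
  models <- vector("list", length(pwms))
  aurocs <- rep(NA_real_, length(pwms))
  for (k in seq_along(pwms)) {
    cfg <- config
    cfg$seed <- seeds[[k]]
    sel <- select_windows_jointrf(pwms[[k]], reads, labels)
    forest <- train_forest(sel$window, sel$label, cfg)
    models[[k]] <- structure(list(forest = forest, pairwise_pwm = pwms[[k]],
                                  window_length = pwms[[k]]$length),
                             class = "jointrf_model")
    if (length(pwms) > 1L)
      aurocs[k] <- auroc(score_jointrf(models[[k]], eval_reads), eval_labels)
  }
  best <- if (length(pwms) == 1L) 1L else which.max(aurocs)
  model <- models[[best]]
  model$pwm_aurocs <- stats::setNames(aurocs, vapply(pwms, `[[`, "", "name"))
  model$selected_pwm <- pwms[[best]]$name
  model
}

#' Train a ComBind model
#'
#' Trains two forests from the full training set, one per binding
#' orientation (`TF1-TF2` and `TF2-TF1`), on 25-nt windows selected with the
#' uniformly extended individual-TF PWMs ([select_windows_combind]).
#' Opposite-strand binding is covered because every scan considers both
#' strands.
#'
#' @param reads,labels Training reads and 0/1 labels.
#' @param pwm_tf1,pwm_tf2 Individual-TF [pwm]s.
#' @param config A [forest_config]; with a non-`NULL` seed, per-orientation
#'   forest seeds are derived from it deterministically.
#' @param window_length Window length (default 25).
#' @return A `combind_model` with fields `rf1`, `rf2`, `pwm_tf1`, `pwm_tf2`
#'   and `window_length`.
#' @export
train_combind <- function(reads, labels, pwm_tf1, pwm_tf2,
                          config = forest_config(), window_length = 25L) {
  seeds <- if (is.null(config$seed)) list(NULL, NULL)
           else as.list(spawn_seeds(config$seed, 2L))
  forests <- lapply(1:2, function(k) {
    ori <- c("TF1-TF2", "TF2-TF1")[k]
    cfg <- config
    cfg$seed <- seeds[[k]]
    sel <- select_windows_combind(pwm_tf1, pwm_tf2, ori, reads, labels,
                                  window_length = window_length)
    train_forest(sel$window, sel$label, cfg)
  })
  structure(list(rf1 = forests[[1]], rf2 = forests[[2]],
                 pwm_tf1 = pwm_tf1, pwm_tf2 = pwm_tf2,
                 window_length = as.integer(window_length)),
            class = "combind_model")
}

#' Score double strands with a JointRF model
#'
#' The sequence score is the maximum forest class-1 probability over all
#' windows of the model's length on both strands.
#'
#' @param model A `jointrf_model`.
#' @param reads A `dna_double_strand`, or a character vector of equal-length
#'   reads.
#' @return Numeric scores in `[0, 1]`, one per read.
#' @export
score_jointrf <- function(model, reads) {
  stopifnot(inherits(model, "jointrf_model"))
  if (inherits(reads, "dna_double_strand")) reads <- reads$forward
  reads <- as_dna(reads)
  max_window_prob(model$forest, reads)
}

#' Score double strands with a ComBind model
#'
#' Each orientation's forest yields a maximum-per-position probability; the
#' ComBind sequence score is the average of the two orientation scores.
#'
#' @param model A `combind_model`.
#' @param reads A `dna_double_strand`, or a character vector of equal-length
#'   reads.
#' @param detail Return a data.frame with the per-orientation scores.
#' @return Numeric scores in `[0, 1]` (or a data.frame when `detail`).
#' @export
score_combind <- function(model, reads, detail = FALSE) {
  stopifnot(inherits(model, "combind_model"))
  if (inherits(reads, "dna_double_strand")) reads <- reads$forward
  reads <- as_dna(reads)
  s1 <- max_window_prob(model$rf1, reads)
  s2 <- max_window_prob(model$rf2, reads)
  if (detail) data.frame(score = (s1 + s2) / 2, rf1 = s1, rf2 = s2)
  else (s1 + s2) / 2
}

#' @export
print.combind_model <- function(x, ...) {
  cat(sprintf("ComBind model: %d-nt windows, motifs '%s' + '%s'\n",
              x$window_length, x$pwm_tf1$name, x$pwm_tf2$name))
  print(x$rf1); print(x$rf2)
  invisible(x)
}

#' @export
print.jointrf_model <- function(x, ...) {
  cat(sprintf("JointRF model: pairwise motif '%s' (%d-nt windows)\n",
              x$pairwise_pwm$name, x$window_length))
  print(x$forest)
  invisible(x)
}
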