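#' Random forest hyperparameter configuration
#'
#' Defaults follow the training protocol: 200 classification trees, Gini
#' split criterion, and `mtry` expressed as a fraction of the number of
#' positional variables (the window length), rounded half-to-even (IEC
#' 60559, as `round()` in R) with a floor of 1.
#'
#' @param n_trees Number of trees (default 200).
#' @param min_node_size Minimum node size below which a node is not split;
#'   the grid-searched values are 1, 5, 10, 15.
#' @param mtry_fraction Fraction of positional variables sampled at each
#'   split; the grid-searched values are 0.1-0.5.
#' @param seed Integer seed for reproducible training; `NULL` draws one from
#'   the current RNG stream at training time.
#' @return A `forest_config` list.
#' @export
forest_config <- function(n_trees = 200L, min_node_size = 1L,
                          mtry_fraction = 0.2, seed = NULL) {
  stopifnot(n_trees >= 1L, min_node_size >= 1L,
            mtry_fraction > 0, mtry_fraction <= 1)
  structure(list(n_trees = as.integer(n_trees),
                 min_node_size = as.integer(min_node_size),
                 mtry_fraction = mtry_fraction,
                 seed = seed),
            class = "forest_config")
}

# Positional factor features (N_1, ..., N_n) from equal-length windows.
windows_to_features <- function(windows) {
  enc <- encode_reads(windows)
  if (any(enc == 5L))
    stop("windows containing N cannot be used as forest features")
  df <- as.data.frame(lapply(seq_len(ncol(enc)), function(j)
    factor(BASES[enc[, j]], levels = BASES)))
  names(df) <- paste0("p", seq_len(ncol(enc)))
  df
}

#' Train a classification forest on positional nucleotide features
#'
#' Each window position is one categorical variable over `{A,C,G,T}`; trees
#' are grown on bootstrap samples (leaving about one third of rows
#' out-of-bag) with Gini-impurity splits and `mtry = round(mtry_fraction *
#' window_length)` candidate positions per node. Backed by
#' \pkg{ranger} with response-ordered factor splitting.
#'
#' @param windows Character vector of equal-length `{A,C,G,T}` windows.
#' @param labels 0/1 vector, one per window; both classes must be present.
#' @param config A [forest_config].
#' @return A `binding_forest`: the fitted ensemble plus its configuration,
#'   window length and out-of-bag class-1 probabilities.
#' @export
train_forest <- function(windows, labels, config = forest_config()) {
  labels <- as.integer(labels)
  if (length(windows) != length(labels)) stop("windows and labels differ in length")
  if (length(unique(labels)) < 2L) stop("both classes must be present in training data")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  W <- unique(nchar(windows))
  if (length(W) != 1L) stop("all training windows must have the same length")
  df <- windows_to_features(windows)
  mtry <- max(1L, as.integer(round(config$mtry_fraction * W)))
  seed <- config$seed %||% sample.int(.Machine$integer.max - 1L, 1L)
  fit <- ranger::ranger(
    x = df, y = factor(labels, levels = c(0L, 1L)),
    num.trees = config$n_trees,
    mtry = mtry,
    min.node.size = config$min_node_size,
    probability = TRUE,
    respect.unordered.factors = "order",
    splitrule = "gini",
    seed = seed,
    num.threads = 1L,
    verbose = FALSE)
  structure(list(fit = fit,
                 config = config,
                 seed = seed,
                 mtry = mtry,
                 window_length = W,
                 n_pos = sum(labels == 1L),
                 n_neg = sum(labels == 0L)),
            class = "binding_forest")
}

#' @export
print.binding_forest <- function(x, ...) {
  cat(sprintf("binding_forest: %d trees, window %d nt, mtry %d, min node %d (%d pos / %d neg)\n",
              x$config$n_trees, x$window_length, x$mtry,
              x$config$min_node_size, x$n_pos, x$n_neg))
  invisible(x)
}

#' Class-1 probabilities for windows
#'
#' @param object A `binding_forest`.
#' @param windows Character vector of windows of the training length.
#' @param ... Unused.
#' @return Numeric vector of class-1 (bound) probabilities in `[0, 1]`.
#' @export
predict.binding_forest <- function(object, windows, ...) {
  W <- unique(nchar(windows))
  if (length(W) != 1L || W != object$window_length)
    stop("windows must match the forest's training window length (",
         object$window_length, ")")
  df <- windows_to_features(windows)
  p <- predict(object$fit, data = df, num.threads = 1L)$predictions
  unname(p[, "1"])
}

#' Out-of-bag class-1 probabilities for the training rows
#'
#' Aggregated predictions of the trees that did not sample each row into
#' their bootstrap; `NA` for rows that were in-bag for every tree.
#'
#' @param forest A `binding_forest`.
#' @return Numeric vector aligned with the training windows.
#' @export
oob_probabilities <- function(forest) {
  stopifnot(inherits(forest, "binding_forest"))
  unname(forest$fit$predictions[, "1"])
}
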