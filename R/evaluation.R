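# Data splitting, pre-training grid search, AUROC, and paired model
# comparison.

#' Class-balanced train/test/pre-training split
#'
#' Samples `train_fraction` of each class into the training set (floor rule,
#' remainder to the test side), then `pretrain_fraction` of each class's
#' training reads into the pre-training subset used for hyperparameter grid
#' search. Pre-training is a subset of training; training and test are
#' disjoint and cover the data.
#'
#' @param labels 0/1 label vector (both classes non-empty).
#' @param train_fraction Fraction per class for training (default 0.75; use
#'   0.50 for oversized libraries).
#' @param pretrain_fraction Fraction of the training reads (per class) for
#'   pre-training (default 0.25).
#' @param seed Optional integer seed.
#' @return List of integer index vectors `pretrain`, `train`, `test`.
#' @export
split_dataset <- function(labels, train_fraction = 0.75,
                          pretrain_fraction = 0.25, seed = NULL) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (train_fraction <= 0 || train_fraction >= 1 ||
      pretrain_fraction <= 0 || pretrain_fraction >= 1)
    stop("fractions must lie in (0, 1)")
  idx0 <- which(labels == 0L)
  idx1 <- which(labels == 1L)
  if (!length(idx0) || !length(idx1)) stop("both classes must be non-empty")
  local_seed(seed, {
    take <- function(idx, frac) {
      k <- floor(frac * length(idx))
      if (k < 1L) stop("fraction yields an empty subset")
      sample(idx, k)
    }
    tr0 <- take(idx0, train_fraction)
    tr1 <- take(idx1, train_fraction)
    train <- sort(c(tr0, tr1))
    pretrain <- sort(c(take(tr0, pretrain_fraction),
                       take(tr1, pretrain_fraction)))
    test <- sort(c(setdiff(idx0, tr0), setdiff(idx1, tr1)))
    if (!length(test)) stop("fraction yields an empty test set")
    list(pretrain = pretrain, train = train, test = test)
  })
}

#' The default hyperparameter grid
#'
#' Minimum node sizes 1, 5, 10, 15 crossed with mtry fractions 0.1-0.5:
#' 20 configurations.
#'
#' @return A data.frame with columns `min_node_size` and `mtry_fraction`,
#'   ordered so that grid-search ties resolve to the smaller node size, then
#'   the smaller fraction.
#' @export
default_forest_grid <- function() {
  g <- expand.grid(min_node_size = c(1L, 5L, 10L, 15L),
                   mtry_fraction = c(0.1, 0.2, 0.3, 0.4, 0.5),
                   KEEP.OUT.ATTRS = FALSE)
  g[order(g$min_node_size, g$mtry_fraction), , drop = FALSE]
}

#' Hyperparameter grid search on the pre-training subset
#'
#' Splits the pre-training reads into an internal class-balanced 75/25
#' train/hold-out split, trains one model per grid cell and scores the
#' hold-out; returns the configuration with the highest hold-out AUROC
#' (ties: smaller `min_node_size`, then smaller `mtry_fraction`). The full
#' cell table is attached as attribute `"cells"`. Failing cells are recorded
#' with `NA` AUROC; an all-failed grid is an error.
#'
#' @param reads,labels Pre-training reads and 0/1 labels.
#' @param trainer `function(reads, labels, config)` returning a scorer
#'   `function(reads) -> numeric`; e.g. wrap [train_combind] +
#'   [score_combind].
#' @param grid Data.frame of `min_node_size` / `mtry_fraction` cells
#'   (default [default_forest_grid]).
#' @param n_trees,base_seed Forest size and master seed for the per-cell
#'   configs (cell seeds derive from `base_seed` by cell parameters, so the
#'   result is invariant to grid enumeration order).
#' @param holdout_fraction Internal hold-out fraction (default 0.25).
#' @return The winning [forest_config] (with `seed = base_seed`), with the
#'   cell AUROC table as attribute `"cells"`.
#' @export
grid_search <- function(reads, labels, trainer, grid = default_forest_grid(),
                        n_trees = 200L, base_seed = NULL,
                        holdout_fraction = 0.25) {
  if (!nrow(grid)) stop("grid must be non-empty")
  labels <- as.integer(labels)
  split <- split_dataset(labels, train_fraction = 1 - holdout_fraction,
                         pretrain_fraction = 0.5, seed = base_seed)
  tr <- split$train
  ho <- split$test
  cells <- grid
  cells$auroc <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg <- forest_config(n_trees = n_trees,
                         min_node_size = grid$min_node_size[i],
                         mtry_fraction = grid$mtry_fraction[i],
                         seed = cell_seed(base_seed, grid$min_node_size[i],
                                          grid$mtry_fraction[i]))
    res <- tryCatch({
      scorer <- trainer(reads[tr], labels[tr], cfg)
      auroc(scorer(reads[ho]), labels[ho])
    }, error = function(e) {
      warning(sprintf("grid cell (node %d, mtry %.2f) failed: %s",
                      grid$min_node_size[i], grid$mtry_fraction[i],
                      conditionMessage(e)), call. = FALSE)
      NA_real_
    })
    cells$auroc[i] <- res
  }
  if (all(is.na(cells$auroc))) stop("every grid cell failed")
  ord <- order(-cells$auroc, cells$min_node_size, cells$mtry_fraction,
               na.last = TRUE)
  best <- cells[ord[1L], ]
  out <- forest_config(n_trees = n_trees,
                       min_node_size = best$min_node_size,
                       mtry_fraction = best$mtry_fraction,
                       seed = base_seed)
  attr(out, "cells") <- cells
  out
}

# Deterministic per-cell seed independent of grid enumeration order.
cell_seed <- function(base_seed, min_node_size, mtry_fraction) {
  if (is.null(base_seed)) return(NULL)
  as.integer((as.numeric(base_seed) * 7 + min_node_size * 101 +
                round(mtry_fraction * 100) * 13) %% 2147483629 + 1)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a random positive
#' outscores a random negative, with ties counted one half;
#' `U / (n1 * n0)`.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (both classes present).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must be non-missing")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired values. Zero differences are dropped; midranks
#' handle tied absolute differences. For n <= `exact_max` pairs the p-value
#' is exact (dynamic programming over all 2^n sign assignments of the
#' midranks); above that, a normal approximation with continuity and tie
#' correction is used.
#'
#' @param a,b Equal-length numeric vectors; at least 5 non-zero differences.
#' @param exact_max Largest n for the exact branch (default 25).
#' @return List with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n` (pairs used) and `method`.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 25L) {
  if (length(a) != length(b)) stop("a and b differ in length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n < 5L) stop("need at least 5 non-zero differences")
  r <- rank(abs(d), ties.method = "average")
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    # DP over doubled midranks (integers); distribution of V under random signs
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    f <- numeric(tot + 1L)
    f[1L] <- 1
    for (w in r2) {
      shifted <- c(numeric(w), f[seq_len(tot + 1L - w)])
      f <- f + shifted
    }
    f <- f / 2^n
    v2 <- as.integer(round(2 * V))
    p_ge <- sum(f[(v2 + 1L):(tot + 1L)])
    p_le <- sum(f[1L:(v2 + 1L)])
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = V, p_value = p, n = n, method = method)
}

#' Compare models across libraries
#'
#' Given a per-library AUROC table (one row per library, one numeric column
#' per model), reports each model's median AUROC and all pairwise Wilcoxon
#' signed-rank p-values. Identical columns are reported as "no difference"
#' rather than a test failure.
#'
#' @param results Data.frame with a `library` id column and >= 2 numeric
#'   model columns; library ids must be unique and non-missing.
#' @param path Optional TSV path for the summary.
#' @return List with `summary` (model, median_auroc, n) and `pairwise`
#'   (model_a, model_b, p_value, note), of class `model_comparison`.
#' @export
compare_models <- function(results, path = NULL) {
  if (!"library" %in% names(results)) stop("results must have a 'library' column")
  ids <- results$library
  if (anyNA(ids) || anyDuplicated(ids))
    stop("misaligned library ids: missing or duplicated entries")
  models <- setdiff(names(results), "library")
  models <- models[vapply(results[models], is.numeric, TRUE)]
  if (length(models) < 2L) stop("need at least two model columns")
  summary <- data.frame(model = models,
                        median_auroc = vapply(results[models], stats::median, 0),
                        n = nrow(results))
  pairs <- utils::combn(models, 2L)
  pw <- data.frame(model_a = pairs[1L, ], model_b = pairs[2L, ],
                   p_value = NA_real_, note = "", stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    test <- tryCatch(wilcoxon_signed_rank(results[[pairs[1L, k]]],
                                          results[[pairs[2L, k]]]),
                     error = function(e) NULL)
    if (is.null(test)) pw$note[k] <- "no difference"
    else pw$p_value[k] <- test$p_value
  }
  out <- structure(list(summary = summary, pairwise = pw),
                   class = "model_comparison")
  if (!is.null(path)) {
    utils::write.table(summary, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(pw, sub("(\\.tsv)?$", "_pairwise.tsv", path),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (median AUROC over", x$summary$n[1L], "libraries):\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-12s %.3f\n", x$summary$model[i], x$summary$median_auroc[i]))
  cat("Pairwise Wilcoxon signed-rank tests:\n")
  for (i in seq_len(nrow(x$pairwise)))
    cat(sprintf("  %s vs %s: %s\n", x$pairwise$model_a[i], x$pairwise$model_b[i],
                if (nzchar(x$pairwise$note[i])) x$pairwise$note[i]
                else format.pval(x$pairwise$p_value[i], digits = 3)))
  invisible(x)
}
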