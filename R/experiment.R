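# End-to-end experiment orchestration: shuffle -> split -> pre-training grid
# search -> train -> test scoring -> evaluation, with every seed and chosen
# hyperparameter logged.

#' Trainer factory for ComBind grid search
#'
#' @param pwm_tf1,pwm_tf2 Individual-TF [pwm]s.
#' @param window_length Window length (default 25).
#' @return `function(reads, labels, config)` returning a scorer, as required
#'   by [grid_search].
#' @export
combind_trainer <- function(pwm_tf1, pwm_tf2, window_length = 25L) {
  force(pwm_tf1); force(pwm_tf2); force(window_length)
  function(reads, labels, config) {
    model <- train_combind(reads, labels, pwm_tf1, pwm_tf2, config,
                           window_length = window_length)
    function(r) score_combind(model, r)
  }
}

#' Trainer factory for JointRF grid search
#'
#' @param pairwise_pwm A pairwise [pwm].
#' @return `function(reads, labels, config)` returning a scorer.
#' @export
jointrf_trainer <- function(pairwise_pwm) {
  force(pairwise_pwm)
  function(reads, labels, config) {
    model <- train_jointrf(reads, labels, pairwise_pwm, config)
    function(r) score_jointrf(model, r)
  }
}

#' Save a trained model
#'
#' Writes the model object (RDS) together with a JSON manifest describing
#' its type, window length, motifs and forest configuration.
#'
#' @param model A `combind_model` or `jointrf_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  type <- if (inherits(model, "combind_model")) "combind" else "jointrf"
  manifest <- list(
    format_version = 1L,
    type = type,
    window_length = model$window_length,
    motifs = if (type == "combind") c(model$pwm_tf1$name, model$pwm_tf2$name)
             else model$pairwise_pwm$name,
    config = if (type == "combind")
      unclass(model$rf1$config)[c("n_trees", "min_node_size", "mtry_fraction")]
    else unclass(model$forest$config)[c("n_trees", "min_node_size", "mtry_fraction")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' Load a saved model
#'
#' @param dir Directory written by [save_model].
#' @return The model object.
#' @export
load_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  if (is.null(manifest$format_version) || manifest$format_version != 1L)
    stop("unsupported model format version")
  readRDS(file.path(dir, "model.rds"))
}

load_pwm_input <- function(x) {
  if (inherits(x, "pwm")) return(x)
  dialect <- if (grepl("\\.(jaspar|jas)$", x)) "jaspar" else "matrix4rows"
  parse_pwm(x, dialect)
}

#' Run a full training and evaluation experiment
#'
#' Executes the complete protocol on one read library: negative construction
#' by dinucleotide-preserving shuffling, class-balanced 75/25 train/test
#' split with a 25% pre-training subset, hyperparameter grid search in
#' pre-training, final training on the full training set with the chosen
#' configuration, test-set scoring, and AUROC evaluation of ComBind, JointRF
#' and the N-padded maximum-log-odds PWM baseline.
#'
#' @param config A list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{seed}{master seed; all stage seeds derive from it.}
#'     \item{reads / simulate}{either `reads` (path, optional `format`) for
#'       positive reads, or `simulate` (`n`, plus [dimer_spec] arguments
#'       `read_length`, `spacing`, `orientation_probs`, `planted_fraction`).}
#'     \item{pwm_tf1, pwm_tf2}{individual-TF motifs ([pwm] or file path).}
#'     \item{pairwise_pwms}{list of pairwise motifs for JointRF and the PWM
#'       baseline ([pwm]s or paths).}
#'     \item{models}{subset of `c("combind", "jointrf", "pwm")`.}
#'     \item{train_fraction, pretrain_fraction}{split fractions (0.75 /
#'       0.25; use 0.5 train for oversized libraries).}
#'     \item{n_trees}{forest size (200).}
#'     \item{grid}{`TRUE` (default) to grid-search, `FALSE` to use default
#'       hyperparameters.}
#'     \item{out_dir}{optional output directory for score TSVs, the AUROC
#'       table, saved models and the run log.}
#'   }
#' @return A list with `auroc` (named vector), `models`, `configs`,
#'   `scores` (test-set score table) and `split` sizes, invisibly written to
#'   `out_dir` when given.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  models_wanted <- config$models %||% c("combind", "jointrf", "pwm")
  train_fraction <- config$train_fraction %||% 0.75
  pretrain_fraction <- config$pretrain_fraction %||% 0.25
  n_trees <- config$n_trees %||% 200L
  out_dir <- config$out_dir
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  seeds <- spawn_seeds(seed, 6L)
  say("master seed %d", seed)

  pwm_tf1 <- if (!is.null(config$pwm_tf1)) load_pwm_input(config$pwm_tf1)
  pwm_tf2 <- if (!is.null(config$pwm_tf2)) load_pwm_input(config$pwm_tf2)
  pairwise <- lapply(config$pairwise_pwms %||% list(), load_pwm_input)

  positives <- stage("input", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      spec <- dimer_spec(pwm_tf1, pwm_tf2,
                         spacing = unlist(sim$spacing %||% c("0" = 1)),
                         orientation_probs = unlist(sim$orientation_probs %||% rep(0.25, 4)),
                         read_length = sim$read_length %||% 40L,
                         planted_fraction = sim$planted_fraction %||% 1)
      generate_reads(spec, sim$n %||% 1000L, seed = seeds[1L])$reads
    } else if (!is.null(config$reads)) {
      read_reads(config$reads, config$format %||% "auto")
    } else stop("config must provide 'reads' or 'simulate'")
  })
  with_n <- grepl("N", positives)
  if (any(with_n)) {
    say("dropping %d reads containing N", sum(with_n))
    positives <- positives[!with_n]
  }
  if (is.null(names(positives)) || !all(nzchar(names(positives))))
    names(positives) <- paste0("pos", seq_along(positives))
  say("positive reads: %d", length(positives))

  negatives <- stage("shuffle", build_negative_set(positives, seed = seeds[2L]))
  reads <- c(positives, negatives)
  labels <- c(rep(1L, length(positives)), rep(0L, length(negatives)))

  split <- stage("split", split_dataset(labels, train_fraction,
                                        pretrain_fraction, seed = seeds[3L]))
  say("split: %d train (%d pre-training), %d test",
      length(split$train), length(split$pretrain), length(split$test))
  tr <- split$train; pt <- split$pretrain; te <- split$test

  aurocs <- c()
  fitted <- list()
  chosen <- list()
  scores <- data.frame(id = names(reads)[te], label = labels[te],
                       stringsAsFactors = FALSE)

  if ("combind" %in% models_wanted) {
    stopifnot(!is.null(pwm_tf1), !is.null(pwm_tf2))
    cfg <- stage("pretrain", {
      if (isFALSE(config$grid)) forest_config(n_trees, seed = seeds[4L])
      else grid_search(reads[pt], labels[pt], combind_trainer(pwm_tf1, pwm_tf2),
                       n_trees = n_trees, base_seed = seeds[4L])
    })
    say("combind config: min node %d, mtry fraction %.2f",
        cfg$min_node_size, cfg$mtry_fraction)
    model <- stage("train", train_combind(reads[tr], labels[tr],
                                          pwm_tf1, pwm_tf2, cfg))
    det <- stage("score", score_combind(model, reads[te], detail = TRUE))
    scores$combind <- det$score
    scores$combind_rf1 <- det$rf1
    scores$combind_rf2 <- det$rf2
    aurocs["combind"] <- auroc(det$score, labels[te])
    fitted$combind <- model
    chosen$combind <- cfg
  }

  if ("jointrf" %in% models_wanted) {
    if (!length(pairwise)) stop("jointrf requires pairwise_pwms")
    cfg <- stage("pretrain", {
      if (isFALSE(config$grid)) forest_config(n_trees, seed = seeds[5L])
      else grid_search(reads[pt], labels[pt], jointrf_trainer(pairwise[[1L]]),
                       n_trees = n_trees, base_seed = seeds[5L])
    })
    say("jointrf config: min node %d, mtry fraction %.2f",
        cfg$min_node_size, cfg$mtry_fraction)
    model <- stage("train", {
      if (length(pairwise) > 1L) {
        # candidate selection on the pre-training hold-out, never the test set
        cand_tr <- setdiff(tr, pt)
        sel <- train_jointrf(reads[cand_tr], labels[cand_tr], pairwise, cfg,
                             eval_reads = reads[pt], eval_labels = labels[pt])
        say("jointrf selected motif '%s' (hold-out AUROCs: %s)",
            sel$selected_pwm,
            paste(sprintf("%s=%.3f", names(sel$pwm_aurocs), sel$pwm_aurocs),
                  collapse = ", "))
        best <- Filter(function(p) p$name == sel$selected_pwm, pairwise)[[1L]]
        train_jointrf(reads[tr], labels[tr], best, cfg)
      } else train_jointrf(reads[tr], labels[tr], pairwise[[1L]], cfg)
    })
    scores$jointrf <- stage("score", score_jointrf(model, reads[te]))
    aurocs["jointrf"] <- auroc(scores$jointrf, labels[te])
    fitted$jointrf <- model
    chosen$jointrf <- cfg
  }

  if ("pwm" %in% models_wanted) {
    if (!length(pairwise)) stop("the PWM baseline requires pairwise_pwms")
    lom <- lapply(pairwise, to_log_odds)
    scores$pwm <- stage("score",
                        replace_neg_inf(pwm_scores(lom, reads[te], pad = TRUE)))
    aurocs["pwm"] <- auroc(scores$pwm, labels[te])
  }

  for (m in names(aurocs)) say("%s test AUROC: %.4f", m, aurocs[m])

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(scores, file.path(out_dir, "scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(model = names(aurocs), auroc = unname(aurocs),
                 n_pos = sum(labels[te] == 1L), n_neg = sum(labels[te] == 0L)),
      file.path(out_dir, "auroc_table.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    for (m in names(fitted)) save_model(fitted[[m]], file.path(out_dir, m))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }

  invisible(list(auroc = aurocs, models = fitted, configs = chosen,
                 scores = scores,
                 split = vapply(split, length, 0L)))
}
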