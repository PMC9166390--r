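# Small labeled benchmark shared by the model tests (built once per file).
pair <- toy_pair()
bench_fixed <- make_benchmark(
  dimer_spec(pair$tf1, pair$tf2, spacing = c("5" = 1)), 250, seed = 301)
comp5 <- composite_pwm(pair$tf1, pair$tf2, 5, "pair_gap5")

test_that("forest configuration computes mtry by round-half-to-even", {
  cfg <- forest_config(n_trees = 200, mtry_fraction = 0.1)
  expect_identical(cfg$n_trees, 200L)
  # 0.1 * 25 = 2.5 rounds to 2 under IEC 60559; 0.3 * 25 = 7.5 rounds to 8
  f1 <- train_forest(c("AAAA", "AAAT", "TTTT", "TTTA"), c(1, 1, 0, 0),
                     forest_config(n_trees = 5, mtry_fraction = 0.5, seed = 1))
  expect_identical(f1$mtry, 2L)
  expect_error(forest_config(mtry_fraction = 0), "mtry_fraction")
})

test_that("forests separate trivially separable windows and are seeded", {
  set.seed(41)
  wins <- c(replicate(40, paste0("AAAA", random_read(4))),
            replicate(40, paste0("TTTT", random_read(4))))
  labs <- rep(c(1, 0), each = 40)
  cfg <- forest_config(n_trees = 200, seed = 7)
  f <- train_forest(wins, labs, cfg)
  p <- predict(f, wins)
  expect_true(all(p[labs == 1] > 0.8))
  expect_true(all(p[labs == 0] < 0.2))
  f2 <- train_forest(wins, labs, cfg)
  expect_identical(predict(f2, wins), p)
  expect_error(train_forest(wins, rep(1, 80), cfg), "both classes")
  expect_error(train_forest(c("AAAA", "AAAAA"), c(0, 1), cfg), "same length")
  expect_error(train_forest(c("AANA", "TTTT"), c(1, 0), cfg), "N")
  oob <- oob_probabilities(f)
  expect_length(oob, 80)
  expect_true(all(oob >= 0 & oob <= 1, na.rm = TRUE))
})

test_that("JointRF window selection picks maximum-probability windows", {
  p <- consensus_pwm("TTGACGTCAA", "site", p = 0.97)
  read <- paste0(strrep("C", 10), "TTGACGTCAA", strrep("G", 10))
  sel <- select_windows_jointrf(p, c(a = read), labels = 1)
  expect_identical(sel$window, "TTGACGTCAA")
  expect_identical(sel$start, 10L)
  expect_identical(sel$label, 1L)
  # uniform matrix: tie-break start 0, + strand
  uni <- pwm(matrix(0.25, 4, 6))
  selu <- select_windows_jointrf(uni, c(a = read))
  expect_identical(selu$start, 0L)
  expect_identical(selu$strand, "+")
  # n in, n out, labels preserved
  sel_all <- select_windows_jointrf(p, bench_fixed$reads, bench_fixed$labels)
  expect_identical(nrow(sel_all), length(bench_fixed$reads))
  expect_identical(sel_all$label, bench_fixed$labels)
  expect_true(all(nchar(sel_all$window) == 10))
})

test_that("ComBind window selection uses the orientation's extended matrices", {
  tf1 <- consensus_pwm("TTGACGTCAA", "tf1", p = 0.97)
  tf2 <- consensus_pwm("CCCGGG", "tf2", p = 0.97)
  read <- paste0("TTGACGTCAA", strrep("A", 30))  # TF1 consensus at left edge
  sel <- select_windows_combind(tf1, tf2, "TF1-TF2", c(r = read))
  expect_identical(sel$start, 0L)
  expect_identical(sel$strand, "+")
  expect_identical(nchar(sel$window), 25L)
  expect_match(sel$matrix, "tf1")
  # fully uniform matrices: tie-break start 0, + strand
  u <- pwm(matrix(0.25, 4, 10), name = "u")
  selu <- select_windows_combind(u, u, "TF1-TF2", c(r = random_read(40)))
  expect_identical(selu$start, 0L)
  expect_identical(selu$strand, "+")
  long <- pwm(matrix(0.25, 4, 26))
  expect_error(select_windows_combind(long, u, "TF1-TF2", read), "longer")
})

test_that("model scores match brute-force per-window forest loops", {
  split <- split_dataset(bench_fixed$labels, seed = 5)
  cfg <- forest_config(n_trees = 60, seed = 9)
  jm <- train_jointrf(bench_fixed$reads[split$train],
                      bench_fixed$labels[split$train], comp5, cfg)
  cm <- train_combind(bench_fixed$reads[split$train],
                      bench_fixed$labels[split$train],
                      pair$tf1, pair$tf2, cfg)
  test_reads <- bench_fixed$reads[split$test][1:12]

  brute_max <- function(forest, read) {
    W <- forest$window_length
    L <- nchar(read)
    wins <- unlist(lapply(c("+", "-"), function(st)
      vapply(0:(L - W), function(s) window_at(double_strand(read), s, W, st),
             character(1))))
    max(predict(forest, wins))
  }
  sj <- score_jointrf(jm, test_reads)
  sc <- score_combind(cm, test_reads, detail = TRUE)
  for (i in seq_along(test_reads)) {
    expect_equal(sj[i], brute_max(jm$forest, test_reads[[i]]))
    expect_equal(sc$rf1[i], brute_max(cm$rf1, test_reads[[i]]))
    expect_equal(sc$rf2[i], brute_max(cm$rf2, test_reads[[i]]))
  }
  # ComBind score is the exact mean of its orientation scores, in [0, 1]
  expect_equal(sc$score, (sc$rf1 + sc$rf2) / 2)
  expect_true(all(sj >= 0 & sj <= 1 & sc$score >= 0 & sc$score <= 1))
})

test_that("model scores are invariant to reverse-complementing the read", {
  split <- split_dataset(bench_fixed$labels, seed = 5)
  cfg <- forest_config(n_trees = 40, seed = 13)
  jm <- train_jointrf(bench_fixed$reads[split$train],
                      bench_fixed$labels[split$train], comp5, cfg)
  cm <- train_combind(bench_fixed$reads[split$train],
                      bench_fixed$labels[split$train], pair$tf1, pair$tf2, cfg)
  r <- bench_fixed$reads[split$test][1:25]
  rc <- reverse_complement(r)
  expect_equal(score_jointrf(jm, rc), score_jointrf(jm, r))
  expect_equal(score_combind(cm, rc), score_combind(cm, r))
})

test_that("JointRF selects the pairwise PWM matching the planted site", {
  split <- split_dataset(bench_fixed$labels, seed = 6)
  decoy <- composite_pwm(consensus_pwm("GGGGGGGG", "d1", 0.97),
                         consensus_pwm("AAAAAAAA", "d2", 0.97), 5, "decoy")
  m <- train_jointrf(bench_fixed$reads[split$train],
                     bench_fixed$labels[split$train],
                     list(decoy, comp5),
                     forest_config(n_trees = 60, seed = 3),
                     eval_reads = bench_fixed$reads[split$test],
                     eval_labels = bench_fixed$labels[split$test])
  expect_identical(m$selected_pwm, "pair_gap5")
  expect_length(m$pwm_aurocs, 2)
  expect_gt(m$pwm_aurocs["pair_gap5"], m$pwm_aurocs["decoy"])
  expect_error(train_jointrf(bench_fixed$reads, bench_fixed$labels,
                             list(decoy, comp5)), "evaluation split")
})

test_that("trained models are seed-reproducible and discriminate held-out reads", {
  split <- split_dataset(bench_fixed$labels, seed = 8)
  cfg <- forest_config(n_trees = 80, seed = 21)
  m1 <- train_combind(bench_fixed$reads[split$train],
                      bench_fixed$labels[split$train], pair$tf1, pair$tf2, cfg)
  m2 <- train_combind(bench_fixed$reads[split$train],
                      bench_fixed$labels[split$train], pair$tf1, pair$tf2, cfg)
  s1 <- score_combind(m1, bench_fixed$reads[split$test])
  expect_identical(s1, score_combind(m2, bench_fixed$reads[split$test]))
  expect_gt(auroc(s1, bench_fixed$labels[split$test]), 0.5)
  expect_identical(m1$rf1$window_length, 25L)
  expect_identical(m1$rf2$window_length, 25L)
})
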