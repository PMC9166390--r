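test_that("pwm construction validates stochastic columns", {
  expect_error(pwm(matrix(1, 3, 4)), "4 rows")
  expect_error(pwm(matrix(c(0.5, 0.5, 0.5, 0.5), 4, 2)), "sum to 1")
  expect_error(pwm(matrix(-1, 4, 2)), "non-negative")
  p <- pwm(matrix(10, 4, 3), normalize = TRUE)
  expect_equal(p$probs, matrix(0.25, 4, 3, dimnames = list(c("A","C","G","T"), NULL)))
})

test_that("PWM files parse in both dialects and errors are caught", {
  tmp <- withr::local_tempdir()
  m4 <- file.path(tmp, "m.pwm")
  writeLines(c("10 0 0", "10 20 0", "10 0 0", "10 0 20"), m4)
  p <- parse_pwm(m4, "matrix4rows")
  expect_equal(p$probs[, 1], c(A = .25, C = .25, G = .25, T = .25))
  expect_equal(p$probs[, 2], c(A = 0, C = 1, G = 0, T = 0))
  expect_identical(p$length, 3L)

  jas <- file.path(tmp, "m.jaspar")
  writeLines(c(">MA0001 testmotif",
               "A [ 1 0 ]", "C [ 1 4 ]", "G [ 1 0 ]", "T [ 1 0 ]"), jas)
  pj <- parse_pwm(jas, "jaspar")
  expect_identical(pj$name, "MA0001 testmotif")
  expect_equal(pj$probs[, 2], c(A = 0, C = 1, G = 0, T = 0))

  bad <- file.path(tmp, "bad.pwm")
  writeLines(c("1 1", "1 1", "1 1"), bad)
  expect_error(parse_pwm(bad, "matrix4rows"), "4 numeric rows")
  ragged <- file.path(tmp, "ragged.pwm")
  writeLines(c("1 1", "1 1 1", "1 1", "1 1"), ragged)
  expect_error(parse_pwm(ragged, "matrix4rows"), "ragged")
})

test_that("log-odds conversion matches the closed form", {
  uni <- pwm(matrix(0.25, 4, 3))
  lo <- to_log_odds(uni)
  expect_equal(lo$scores, matrix(0, 4, 3, dimnames = list(c("A","C","G","T"), NULL)))
  onehot <- pwm(matrix(c(1, 0, 0, 0), 4, 1))
  lo1 <- to_log_odds(onehot, pseudocount = 0)
  expect_equal(unname(lo1$scores["A", 1]), log(4))
  expect_identical(unname(lo1$scores["C", 1]), -Inf)
  # pseudocount policy: (p + pc*bg) / (1 + pc) / bg
  lo2 <- to_log_odds(onehot, pseudocount = 0.1)
  expect_equal(unname(lo2$scores["A", 1]), log((1 + 0.1 * 0.25) / 1.1 / 0.25))
  expect_error(to_log_odds(onehot, background = c(1, 1, 1, 1)), "background")
})

test_that("uniform extension adds inert columns on the stated side", {
  p <- consensus_pwm("ACGTACGTACG", "m")  # 11 columns
  er <- extend_pwm(p, "right", 25)
  expect_identical(er$length, 25L)
  expect_equal(er$probs[, 1:11], p$probs)
  expect_true(all(er$probs[, 12:25] == 0.25))
  el <- extend_pwm(consensus_pwm("ACGTACG", "m7"), "left", 25)
  expect_true(all(el$probs[, 1:18] == 0.25))
  expect_equal(el$probs[, 19:25], consensus_pwm("ACGTACG", "m7")$probs)
  p25 <- pwm(matrix(0.25, 4, 25))
  expect_identical(extend_pwm(p25, "right", 25)$probs, p25$probs)
  expect_error(extend_pwm(pwm(matrix(0.25, 4, 26)), "right", 25), "longer")
  # uniform flanks contribute exactly zero log-odds under uniform background
  lo <- to_log_odds(er)
  expect_true(all(lo$scores[, 12:25] == 0))
})

test_that("N padding has the stated geometry", {
  expect_identical(pad_with_N("ACGT", 5), "NNNNNACGTNNNNN")
  expect_identical(pad_with_N("ACGT", 0), "ACGT")
  expect_identical(nchar(pad_with_N(random_read(40), 5)), 50L)
})

test_that("scan_max matches the brute-force all-windows oracle", {
  uni <- to_log_odds(pwm(matrix(0.25, 4, 3)))
  hit <- scan_max(uni, random_read(20))
  expect_equal(hit$score, 0)
  expect_identical(hit$start, 0L)
  expect_identical(hit$strand, "+")

  set.seed(23)
  for (i in 1:60) {
    W <- sample(4:20, 1)
    L <- sample(25:60, 1)
    mat <- random_pwm(W)
    if (i %% 2 == 0) mat <- to_log_odds(mat)
    read <- random_read(L)
    pad <- i %% 3 == 0
    hit <- scan_max(mat, read, pad = pad)
    ref <- naive_scan(mat, read, pad = pad)
    got <- if (inherits(mat, "pwm")) log(hit$score) else hit$score
    expect_equal(got, ref$score, tolerance = 1e-9)
    expect_identical(hit$start, as.integer(ref$start))
    expect_identical(hit$strand, ref$strand)
  }
})

test_that("a matrix matching a planted site reports the planted coordinates", {
  p <- consensus_pwm("ACCGGTAAAT", "site", p = 0.97)  # not palindromic
  read <- paste0(strrep("C", 12), "ACCGGTAAAT", strrep("C", 12))
  hit <- scan_max(p, read)
  expect_identical(hit$start, 12L)
  expect_identical(hit$strand, "+")
  hitm <- scan_max(p, naive_revcomp(read))
  expect_identical(hitm$strand, "-")
  expect_identical(hitm$start, 12L)
  expect_equal(hitm$score, hit$score)
})

test_that("PWM-set scoring takes the maximum over matrices after padding", {
  p1 <- to_log_odds(consensus_pwm("ACGTACGT", "a"))
  p2 <- to_log_odds(pwm(matrix(0.25, 4, 5), name = "uni"))
  ds <- double_strand(random_read(40))
  expect_equal(score_with_pwm_set(list(p1), ds), scan_max(p1, ds, pad = TRUE)$score)
  both <- score_with_pwm_set(list(p1, p2), ds)
  expect_gte(both, 0)  # the uniform matrix lower-bounds the set score at 0
  expect_equal(both, max(scan_max(p1, ds, pad = TRUE)$score,
                         scan_max(p2, ds, pad = TRUE)$score))
  expect_error(score_with_pwm_set(list(), ds), "at least one")
})

test_that("-Inf replacement uses the dataset minimum finite score", {
  expect_equal(replace_neg_inf(c(1, -Inf, 3)), c(1, 1, 3))
  expect_equal(replace_neg_inf(c(-Inf, -2.5)), c(-2.5, -2.5))
  expect_equal(replace_neg_inf(c(1, 2)), c(1, 2))
  expect_error(replace_neg_inf(c(-Inf, -Inf)), "all scores")
})

test_that("scan scores are invariant under strand replacement", {
  set.seed(31)
  mats <- list(to_log_odds(random_pwm(7)), to_log_odds(random_pwm(11)))
  for (i in 1:40) {
    r <- random_read(40)
    expect_equal(score_with_pwm_set(mats, r),
                 score_with_pwm_set(mats, reverse_complement(r)))
  }
})

test_that("motifs round-trip through all writer formats", {
  p <- random_pwm(9, "round_trip")
  tmp <- withr::local_tempdir()
  for (fmt in c("jaspar", "matrix4rows")) {
    f <- file.path(tmp, paste0("m.", fmt))
    write_motif(p, f, fmt)
    back <- parse_pwm(f, if (fmt == "jaspar") "jaspar" else "matrix4rows")
    expect_equal(back$probs, p$probs, tolerance = 1e-5)
  }
  write_motif(p, file.path(tmp, "m.meme"), "meme")
  meme <- readLines(file.path(tmp, "m.meme"))
  expect_true(any(grepl("^MEME version", meme)))
  expect_true(any(grepl("letter-probability matrix: alength= 4 w= 9", meme)))
})
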