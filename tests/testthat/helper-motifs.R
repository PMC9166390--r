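# Shared fixtures and independent brute-force oracles. Everything is built
# in code; no binary fixtures.

# A near-consensus PWM: probability `p` on the consensus base per column.
consensus_pwm <- function(consensus, name = "motif", p = 0.91) {
  v <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - p) / 3, 4, length(v), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(v)) m[v[j], j] <- p
  pwm(m, name = name)
}

random_pwm <- function(len, name = "rand") {
  m <- matrix(stats::rexp(4 * len), 4, len)
  pwm(sweep(m, 2, colSums(m), "/"), name = name)
}

random_read <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Fixed-gap composite of two motifs: [left | gap uniform columns | right].
composite_pwm <- function(pwm1, pwm2, gap, name = "composite") {
  stopifnot(gap >= 0)
  mid <- matrix(0.25, 4, gap)
  pwm(cbind(pwm1$probs, mid, pwm2$probs), name = name)
}

# Brute-force per-position complement/reversal, independent of the package.
naive_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# Brute-force best window over all starts and both strands. Scores in log
# space (log probabilities for a pwm, log-odds sums otherwise); N scores
# probability 0.25 / log-odds 0. Tie-break: + strand first, then smallest
# forward-axis start, matching the documented scanning convention.
naive_scan <- function(matrix, read, pad = FALSE, pad_k = 5L) {
  S <- if (inherits(matrix, "pwm")) rbind(log(matrix$probs), N = log(0.25))
       else rbind(matrix$scores, N = 0)
  if (pad) read <- paste0(strrep("N", pad_k), read, strrep("N", pad_k))
  W <- ncol(S)
  L <- nchar(read)
  lookup <- stats::setNames(1:5, c("A", "C", "G", "T", "N"))
  score_window <- function(w) {
    idx <- lookup[strsplit(w, "")[[1]]]
    sum(S[cbind(idx, seq_len(W))])
  }
  best <- list(score = -Inf, start = 0L, strand = "+")
  for (strand in c("+", "-")) {
    for (s in 0:(L - W)) {
      w <- substr(read, s + 1L, s + W)
      if (strand == "-") w <- naive_revcomp(w)
      sc <- score_window(w)
      if (sc > best$score) best <- list(score = sc, start = s, strand = strand)
    }
  }
  best
}

# Brute-force 16-bin dinucleotide counter.
naive_dinuc_counts <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  keys <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                          function(a, b) paste0(a, b)))
  out <- stats::setNames(integer(16), sort(keys))
  di <- paste0(v[-length(v)], v[-1])
  for (d in di) out[d] <- out[d] + 1L
  out
}

# Brute-force AUROC by positive-negative pair counting, ties = 1/2.
naive_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Exact signed-rank statistic and two-sided p by enumerating all sign
# assignments (small n only).
naive_signed_rank <- function(a, b) {
  d <- (a - b)[a != b]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  Vs <- as.matrix(signs) %*% r
  p_ge <- mean(Vs >= V)
  p_le <- mean(Vs <= V)
  list(statistic = V, p_value = min(1, 2 * min(p_ge, p_le)))
}

# Small standard synthetic benchmark used across model tests.
toy_pair <- function() {
  list(tf1 = consensus_pwm("TGACGTCA", "tf1"),
       tf2 = consensus_pwm("CACGTGAC", "tf2"))
}
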