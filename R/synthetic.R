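# Synthetic CAP-SELEX-like read generator: fixed-length reads carrying one
# planted two-motif (dimer) site with configurable orientation mix and
# inter-motif spacing/overlap, on either strand, in a first-order Markov
# background with specified dinucleotide composition.

ORIENTATIONS <- c("TF1-TF2", "TF2-TF1")

#' Specify a synthetic dimer-motif read distribution
#'
#' @param pwm_tf1,pwm_tf2 Individual-TF [pwm]s for the pair.
#' @param spacing Named numeric vector mapping the gap (in nt; negative =
#'   overlap) between the two motifs to its probability, e.g.
#'   `c("0" = .5, "2" = .5)`. Normalized to sum 1.
#' @param orientation_probs Length-4 probability vector over
#'   `TF1-TF2+`, `TF2-TF1+`, `TF1-TF2-`, `TF2-TF1-` (the last two are the
#'   opposite-strand reflections). Normalized.
#' @param read_length Read length in nt (default 40, as in CAP-SELEX).
#' @param background_dinucleotide_probs Named length-16 vector of
#'   dinucleotide probabilities (AA ... TT) for the background Markov chain;
#'   default uniform.
#' @param planted_fraction Fraction of positive reads that actually carry a
#'   site (default 1); 0 gives pure background, the null control.
#' @return A `dimer_spec` list.
#' @export
dimer_spec <- function(pwm_tf1, pwm_tf2, spacing = c("0" = 1),
                       orientation_probs = rep(0.25, 4),
                       read_length = 40L,
                       background_dinucleotide_probs = rep(1 / 16, 16),
                       planted_fraction = 1) {
  stopifnot(inherits(pwm_tf1, "pwm"), inherits(pwm_tf2, "pwm"))
  gaps <- as.integer(names(spacing))
  if (anyNA(gaps)) stop("spacing must be named by integer gaps")
  if (any(spacing < 0) || sum(spacing) <= 0) stop("invalid spacing probabilities")
  spacing <- spacing / sum(spacing)
  if (length(orientation_probs) != 4L || any(orientation_probs < 0) ||
      sum(orientation_probs) <= 0)
    stop("orientation_probs must be 4 non-negative values")
  orientation_probs <- orientation_probs / sum(orientation_probs)
  names(orientation_probs) <- c("TF1-TF2+", "TF2-TF1+", "TF1-TF2-", "TF2-TF1-")
  if (length(background_dinucleotide_probs) != 16L ||
      any(background_dinucleotide_probs < 0) ||
      sum(background_dinucleotide_probs) <= 0)
    stop("background_dinucleotide_probs must be 16 non-negative values")
  bg <- background_dinucleotide_probs / sum(background_dinucleotide_probs)
  l1 <- pwm_tf1$length; l2 <- pwm_tf2$length
  if (any(gaps < -min(l1, l2)))
    stop("overlap cannot exceed the shorter motif's length")
  if (read_length < l1 + l2 + max(gaps))
    stop(sprintf("read length %d cannot hold the two motifs with gap %d",
                 read_length, max(gaps)))
  if (planted_fraction < 0 || planted_fraction > 1)
    stop("planted_fraction must lie in [0, 1]")
  structure(list(pwm_tf1 = pwm_tf1, pwm_tf2 = pwm_tf2,
                 spacing = stats::setNames(as.numeric(spacing), gaps),
                 orientation_probs = orientation_probs,
                 read_length = as.integer(read_length),
                 background_dinucleotide_probs = bg,
                 planted_fraction = planted_fraction),
            class = "dimer_spec")
}

# Composite site column probabilities for one core orientation and gap.
# Gap columns are NA (left as background); overlapped columns average the
# two motifs' column probabilities, keeping columns stochastic.
composite_columns <- function(p_left, p_right, gap) {
  l1 <- ncol(p_left); l2 <- ncol(p_right)
  len <- l1 + l2 + gap
  cols <- matrix(NA_real_, 4L, len)
  cols[, seq_len(l1)] <- p_left
  right_at <- l1 + gap  # 0-based start of the right motif
  for (j in seq_len(l2)) {
    pos <- right_at + j
    cols[, pos] <- if (is.na(cols[1L, pos])) p_right[, j]
                   else (cols[, pos] + p_right[, j]) / 2
  }
  cols
}

# Reverse complement of a composite column matrix (NA gap columns mirror).
revcomp_columns <- function(cols) {
  cols[4:1, rev(seq_len(ncol(cols))), drop = FALSE]
}

# First-order Markov background reads as an integer matrix n x L.
markov_background <- function(n, L, dinuc) {
  D <- matrix(dinuc, 4L, 4L, byrow = TRUE, dimnames = list(BASES, BASES))
  init <- rowSums(D)
  init <- if (sum(init) > 0) init / sum(init) else rep(0.25, 4)
  P <- D / ifelse(rowSums(D) > 0, rowSums(D), 1)
  P[rowSums(D) == 0, ] <- 0.25
  m <- matrix(0L, n, L)
  m[, 1L] <- sample.int(4L, n, replace = TRUE, prob = init)
  for (j in 2:L) {
    for (b in 1:4) {
      idx <- which(m[, j - 1L] == b)
      if (length(idx))
        m[idx, j] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
    }
  }
  m
}

decode_reads <- function(m) {
  ch <- BASES[m]
  dim(ch) <- dim(m)
  do.call(paste0, as.data.frame(ch, stringsAsFactors = FALSE))
}

#' Generate positive reads with planted dimer sites
#'
#' Each read is first-order Markov background text; with probability
#' `planted_fraction` one composite site is planted: letters sampled
#' per-column from the two PWMs, gap positions left as background,
#' orientation and strand drawn from the spec, start uniform among feasible
#' positions.
#'
#' @param spec A [dimer_spec].
#' @param n Number of reads (>= 1).
#' @param seed Optional integer seed.
#' @return List with `reads` (named character vector) and `truth`
#'   (data.frame: `id`, `planted`, `start` 0-based, `gap`, `orientation`,
#'   `strand`).
#' @export
generate_reads <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "dimer_spec"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  local_seed(seed, {
    L <- spec$read_length
    m <- markov_background(n, L, spec$background_dinucleotide_probs)
    planted <- stats::runif(n) < spec$planted_fraction
    gaps <- as.integer(names(spec$spacing))
    truth <- data.frame(id = paste0("pos", seq_len(n)), planted = planted,
                        start = NA_integer_, gap = NA_integer_,
                        orientation = NA_character_, strand = NA_character_,
                        stringsAsFactors = FALSE)
    if (any(planted)) {
      np <- sum(planted)
      widx <- which(planted)
      gap_draw <- gaps[sample.int(length(gaps), np, replace = TRUE,
                                  prob = spec$spacing)]
      ori_draw <- sample.int(4L, np, replace = TRUE,
                             prob = spec$orientation_probs)
      core <- ORIENTATIONS[ifelse(ori_draw %in% c(1L, 3L), 1L, 2L)]
      strand <- ifelse(ori_draw <= 2L, "+", "-")
      truth$gap[widx] <- gap_draw
      truth$orientation[widx] <- core
      truth$strand[widx] <- strand
      for (g in unique(gap_draw)) {
        for (co in unique(core)) {
          for (st in c("+", "-")) {
            sel <- widx[gap_draw == g & core == co & strand == st]
            if (!length(sel)) next
            cols <- if (co == "TF1-TF2")
              composite_columns(spec$pwm_tf1$probs, spec$pwm_tf2$probs, g)
            else
              composite_columns(spec$pwm_tf2$probs, spec$pwm_tf1$probs, g)
            if (st == "-") cols <- revcomp_columns(cols)
            len <- ncol(cols)
            starts <- sample.int(L - len + 1L, length(sel), replace = TRUE) - 1L
            truth$start[sel] <- starts
            for (j in seq_len(len)) {
              if (is.na(cols[1L, j])) next
              m[cbind(sel, starts + j)] <-
                sample.int(4L, length(sel), replace = TRUE, prob = cols[, j])
            }
          }
        }
      }
    }
    reads <- stats::setNames(decode_reads(m), truth$id)
    list(reads = reads, truth = truth)
  })
}

#' Build a labeled synthetic benchmark
#'
#' `n` positives from [generate_reads] plus `n` dinucleotide-preserving
#' shuffled negatives ([build_negative_set]), combined in shuffled order.
#' Byte-identical for a given seed.
#'
#' @param spec A [dimer_spec].
#' @param n Number of positive reads.
#' @param seed Optional integer seed.
#' @return A `selex_benchmark`: list with `reads` (named character vector),
#'   `labels` (0/1 integer vector, same order) and `truth`.
#' @export
make_benchmark <- function(spec, n, seed = NULL) {
  local_seed(seed, {
    pos <- generate_reads(spec, n)
    neg <- build_negative_set(pos$reads)
    reads <- c(pos$reads, neg)
    labels <- c(rep(1L, n), rep(0L, n))
    ord <- sample.int(2L * n)
    structure(list(reads = reads[ord], labels = labels[ord],
                   truth = pos$truth),
              class = "selex_benchmark")
  })
}

#' @export
print.selex_benchmark <- function(x, ...) {
  cat(sprintf("Synthetic SELEX benchmark: %d reads (%d positive, %d negative), %d nt\n",
              length(x$reads), sum(x$labels == 1L), sum(x$labels == 0L),
              nchar(x$reads[[1L]])))
  invisible(x)
}
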