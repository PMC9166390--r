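---
title: "Random forest models for TF-pair binding sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random forest models for TF-pair binding sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combind)
```

## The problem

Transcription factors (TFs) frequently bind DNA as pairs, on a shared
composite site whose geometry is flexible: the two motifs can appear in
either order along the strand (orientation), on either strand, and with a
variable number of background nucleotides between them — or even overlapping.
In-vitro selection libraries for pairwise binding (CAP-SELEX-style) deliver
large sets of short reads, typically 40 nt, each known to contain one joint
binding site somewhere on the read or its reverse complement, but at an
unknown position and configuration.

A single position weight matrix (PWM) fixes orientation and spacing, so a
composite PWM describes only one configuration. This package models joint
binding with random forests in two ways:

* **JointRF** assumes a known composite PWM. For every read it selects the
  maximum-probability window of the PWM's length over both strands and
  trains a forest on the window's nucleotides, one categorical variable per
  position. It adds non-linear, position-dependent structure on top of a
  fixed configuration.
* **ComBind** assumes only the two individual-TF PWMs. Each motif is
  extended with uniform $(0.25, 0.25, 0.25, 0.25)^\top$ columns to 25
  columns — rightward when that TF is expected to sit on the left of the
  pair, leftward otherwise — so the extended matrix pins down one TF's site
  while reserving undetermined space for the partner. Two forests are
  trained, one per orientation (TF1–TF2 and TF2–TF1); the remaining two of
  the four conceivable configurations are reflections onto the opposite
  strand and are covered because every scan considers both strands.

At prediction time a model scores all windows of its length on both strands
of the read and takes the maximum forest probability (the
maximum-per-position score). ComBind averages its two orientation scores;
averaging is preferred over the maximum because both orientations carry
evidence for at least one of the TFs and averaging stabilizes the score.
All scores are class-1 probabilities in $[0, 1]$.

## Negative class

Positives are the library reads. Negatives are built by shuffling each
positive once while preserving its exact multiset of overlapping
dinucleotides (a random Euler path on the base-transition multigraph,
constructed with the Altschul–Erickson arborescence method). The classes
are therefore equally sized and matched read-by-read in length, base and
dinucleotide composition: the discrimination left to learn is motif
content, not bulk composition. The shuffle conserves the first and last
base by construction — a consequence of the Euler-path formulation, not a
design choice.

Reads containing `N` are dropped from both classes before shuffling (with a
logged count); the shuffle is defined over pure `{A,C,G,T}` text.

## Training protocol

1. Split reads 75/25 into training and test, sampling within each class so
   balance is preserved (`floor(fraction * n)` per class; the remainder
   goes to the test side). For unusually large libraries a 50/50 split is
   used instead (`train_fraction = 0.5`).
2. Sample 25% of the training reads per class into a *pre-training* subset.
3. Grid-search forest hyperparameters on the pre-training subset: minimum
   node size $\{1, 5, 10, 15\}$ crossed with the fraction of positional
   variables tried at each split $\{0.1, 0.2, 0.3, 0.4, 0.5\}$ — 20 cells.
   Each cell is evaluated by AUROC on an internal class-balanced 75/25
   hold-out within pre-training. Ties go to the smaller node size, then
   the smaller fraction.
4. Retrain on the full training set with the winning configuration. The
   pre-training subset is used for selection only; the final model always
   sees all training reads.
5. Score the held-out test set and evaluate by AUROC (rank-based
   Mann–Whitney form, ties counted one half). Model differences across
   libraries are assessed with a two-sided Wilcoxon signed-rank test on the
   paired per-library AUROCs.

### Forest contract

Forests contain 200 Gini-impurity classification trees grown on bootstrap
samples (about one third of rows out-of-bag per tree), with
`mtry = round(mtry_fraction * window_length)` candidate positions per
split, rounded half-to-even (IEC 60559, R's `round()`) with a floor of 1.
The positional variables are 4-level factors; the backend is \pkg{ranger}
with response-ordered factor splitting (`respect.unordered.factors =
"order"`), the standard exact shortcut for binary outcomes that avoids
enumerating level partitions. `mtry` is always computed on the number of
positions (the window length), never on any expanded encoding, preserving
the "percentage of total variables" meaning of the grid. All training is
single-threaded and seeded; a master seed deterministically spawns
per-forest and per-grid-cell seeds, so whole experiments replay exactly.

200 trees is the default because forest AUROC is flat well before that
size on these data; it is kept as an explicit `forest_config()` parameter.

## PWM scoring conventions

* **Two score spaces.** Window selection during training uses probability
  products (position probability matrices); the PWM *baseline* uses
  log-odds sums under a uniform background. Rankings agree wherever all
  entries are positive; the two spaces are both exposed because zero
  probabilities behave differently (`0` vs `-Inf`).
* **Background** defaults to uniform (0.25 per base). This makes an `N`
  position — scored as probability 0.25 — contribute exactly zero log-odds,
  and makes the uniform extension columns score-inert.
* **Pseudocount** defaults to 0; `-Inf` log-odds scores that survive
  maximum-per-position selection are replaced by the dataset's minimum
  finite score (`replace_neg_inf()`), never silently clipped.
* **N padding.** For baseline scoring, reads are padded with five `N`s on
  each end so a matrix can overhang the read; windows then exist at every
  overhang position. Training-window selection does not pad: training
  windows must be pure `{A,C,G,T}` because they become forest features
  (this is asserted, not assumed).
* **Tie-breaks.** Among equal-scoring windows the `+` strand wins, then the
  smallest forward-axis start; among equal-scoring matrices in a set, the
  earlier matrix. Coordinates are 0-based half-open on the forward strand
  throughout the package; file writers that report positions document any
  1-based conversion.
* **Extension cap.** Motifs longer than the 25-column window are an error;
  truncating a motif would silently change the model.

## Synthetic benchmark generator

`dimer_spec()` + `make_benchmark()` emulate a pairwise-selection library at
desk scale: fixed-length reads (default 40 nt) of first-order Markov
background text with a specified dinucleotide distribution (default
uniform), each carrying — with probability `planted_fraction`, default 1 —
one composite site. Site letters are sampled per column from the two PWMs;
the gap is left as background; orientation and strand follow a 4-way
probability vector (default uniform over TF1–TF2/TF2–TF1 × strand); the gap
is drawn from an explicit spacing distribution, with negative gaps realized
by averaging the overlapped PWM columns (keeping columns stochastic); the
site start is uniform over feasible positions. The planted truth (start,
gap, orientation, strand) is returned for every read.

A first-order Markov background is chosen deliberately: dinucleotide
-preserving shuffles of such positives yield negatives that differ from
positives only in motif content, exactly the contrast the models target.

The benchmark used in the package's end-to-end checks plants two
informative 8-column motifs (consensus probability 0.91 per column, about
1.4 bits) with gap uniform on $\{0, \dots, 10\}$ in 20,000 reads (10,000
positives plus their shuffled negatives) — large enough for stable AUROCs
and small enough to train in minutes on one core. Under those conditions
ComBind's held-out AUROC exceeds 0.9 and clearly beats a single
fixed-spacing composite PWM, and with `planted_fraction = 0` every model
sits at chance.

What the generator does **not** emulate: selection-cycle enrichment
dynamics, PCR amplification bias, sequencing error, position-dependent
motif correlations, or multiple sites per read. Passing the synthetic
checks therefore demonstrates that the implementation recovers plantable
signal under the stated geometry — not that real libraries will reach the
same accuracies.

## Other design decisions

* **JointRF motif selection.** When several composite PWMs are available
  for a pair, one JointRF model is trained per PWM and the best is chosen
  by AUROC on a held-out split — the pre-training subset, with candidates
  trained on the remainder of the training set — never on the test set;
  the winner is then retrained on the full training set. Choosing on test
  data would bias the comparison optimistically.
* **Wilcoxon policy.** Zero differences are dropped before ranking
  (so identical score vectors are reported as "no difference" rather than
  a test result); tied absolute differences take midranks. For $n \le 25$
  the two-sided p-value is exact, computed by dynamic programming over the
  $2^n$ sign assignments of the (doubled, integer) midranks; larger $n$
  uses the normal approximation with continuity and tie corrections. The
  exact branch is required for constant-shift data, where every $|d|$ ties.
* **Split rounding** uses `floor` per class with the remainder on the test
  side, so the training fraction is never exceeded.
* **Degenerate inputs** error early and loudly: non-`{A,C,G,T,N}`
  characters name the offending position; single-class training sets,
  empty grids, all-`-Inf` score vectors and infeasible simulator geometry
  are all rejected rather than patched.

## Limitations

Trained forests are large objects; scoring enumerates every window on both
strands, so cost grows linearly in read length. ComBind deliberately folds
all orientations and spacings into one score and cannot report *which*
configuration was matched; for configuration-level inspection use JointRF
with a configuration-specific composite PWM, and `oob_positive_pfm()` to
visualize what its forest considers a positive site (out-of-bag
probabilities above 0.5, by default, of positive-labeled training windows,
column-normalized into a motif). The models are sequence-only: DNA shape,
methylation and chromatin context are out of scope.
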