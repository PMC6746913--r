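---
title: "Methods and design notes for sixmApred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for sixmApred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

DNA N6-methyladenine (6mA) prediction is cast as binary classification of
fixed 41-nt windows whose central base (position 21, 1-based) is an adenine:
the positive class contains windows whose central adenine is methylated, the
negative class windows where it is known not to be. The window length, the
central-adenine convention, the three feature maps, the 100-tree random
forest, and the evaluation protocols implemented here follow the design that
established this benchmark setup for the rice genome; everything is
parameterised so the same machinery runs at desk scale on synthetic data.

The classifier sees nothing but the window sequence. Its features are:

* **KNFC** — for each `k` in a configurable set (default 2, 3, 4), the
  vector of all `4^k` overlapping k-mer frequencies in lexicographic order
  over `(A, C, G, T)`. We normalise counts by the number of k-mer slots
  `L - k + 1`, so each block sums to exactly 1; the original description
  says only "frequency", and per-slot normalisation is the standard reading
  that makes blocks comparable across `k`. Raw counts are available with
  `normalize = FALSE`.
* **MNBE** — position-wise one-hot encoding, `4L` binary features. This is
  the only encoding that preserves *where* each base sits, which is why it
  dominates when the class signal is positional.
* **NV** — the natural vector: per base, its count `n_R`, mean position
  `mu_R`, and second-order normalised central moment `D2_R`. The printed
  denominator of `D2_R` is typographically ambiguous ("nn_R"); we read it
  as `n * n_R` with `n = L`, the convention of the natural-vector
  literature, and expose `denominator = "count"` for the alternative
  `n_R * n_R` reading rather than deciding silently. A base that never
  occurs gets `mu_R = D2_R = 0`: the mean is undefined at `n_R = 0`, and
  zero is the least-informative imputation that keeps the vector length
  fixed at 12.

# Benchmark construction

**Motif strata.** The published positive set is enriched for `GAGG`, `AGG`
and `AG` contexts at the methylated adenine (17.08%, 15.76% and 14.42% of
positives). The source states the motifs but neither their anchoring nor
their precedence; we anchor all three at the central adenine (`GAGG` =
positions 20–23, `AGG` = 21–23, `AG` = 21–22) and classify
most-specific-first, which makes the four strata disjoint. Disjointness is
the reading consistent with the published proportions summing below 100%.

**Matched negatives.** `sample_matched_negatives()` draws a stratified
uniform sample whose stratum counts are the largest-remainder apportionment
of `n * p` — floor every quota, then give the remaining units to the largest
fractional remainders — so counts are integers summing exactly to `n` for
any `n`. At `n = 10,000` with the default ratios this gives
1,708 / 1,576 / 1,442 / 5,274.

**Redundancy filter.** `greedy_identity_filter()` is an order-dependent
greedy clustering on ungapped identity (matching positions / L). It stands
in for CD-HIT, which performs word-filtered global-alignment clustering; the
two do not produce identical sets, and rebuilding the full published
benchmark should use CD-HIT itself. One boundary decision: a window is
dropped if its identity with a kept window exceeds the threshold *or* if it
is an exact duplicate, so `threshold = 1` deduplicates and `threshold = 0.8`
matches the published "similarity above 80% excluded" rule.

**Edge adenines.** When windows are cut from a longer sequence, adenines
closer than `flank` to either end are silently skipped. How the original
benchmark treated contig edges is not documented; skipping is this package's
choice, and it is symmetric (reversal never changes the eligible count).

**Alphabet.** Characters outside `A/C/G/T` (including `N`) are rejected,
never coerced or skipped: the benchmark contains only unambiguous bases, and
silently dropping a base would shift every downstream position-indexed
feature.

# The random forest

No random-forest package could be assumed in the execution environment, so
the package bundles one (C++ via Rcpp): bagged CART trees, Gini impurity
splits with midpoint thresholds, `mtry` features drawn uniformly without
replacement at every node, grown until purity, node size < 2, or a depth cap
of 30. Defaults are 100 trees and seed 1 — the published configuration — with
`mtry = floor(sqrt(p))`, the standard classification default; all growth
controls are stored in the model object.

Two details matter for reproducibility:

* The forest consumes its own Mersenne-Twister stream seeded from
  `rf_config(seed = )`, independent of R's RNG, so fits are bit-identical
  across sessions and platforms and never perturb the caller's RNG state.
* Scores are mean leaf class-1 probabilities across trees by default; the
  hard-vote fraction (each tree votes its leaf majority) is available with
  `vote = TRUE`. Both are consistent with "aggregation by voting";
  probability averaging yields smoother ROC curves and is the default.

Exact replication of WEKA's random forest (the implementation behind the
published numbers) is not attainable — bootstrap and split details differ —
and is not claimed; this is why the acceptance checks are property-based
rather than equality with the published headline AUCs.

Hard labels use threshold 0.5 with `>=` tie-breaking. No threshold is stated
in the source; 0.5 matches the balanced-class design, and the threshold is a
parameter everywhere it is used.

# Metrics and protocols

`Sn`, `Sp`, `Acc` are computed from the four confusion counts as
`1 - fn/N+`, `1 - fp/N-`, `1 - (fn + fp)/(N+ + N-)`. MCC is computed in the
standard `(TP, TN, FP, FN)` form; the rearranged ratio form printed beside
these definitions in the source is algebraically identical wherever defined,
and the test suite verifies agreement to 1e-12 on random tables. Two
conventions: MCC of a table with a zero margin is reported as 0 with a
warning (the ratio form divides by zero there), and MCC's range is
`[-1, 1]` — the bound "0 <= MCC <= 1" printed in the source contradicts its
own worked example of total disagreement (`MCC = -1`) and is treated as a
typo.

ROC curves sweep thresholds over the unique score values in descending
order; tied scores collapse to one point, and the trapezoidal AUC equals the
Mann-Whitney statistic `P(s+ > s-) + P(tie)/2` (verified against an
exhaustive pairwise oracle).

Protocol decisions where the source is silent:

* **Pooled out-of-fold scoring.** k-fold CV reports one ROC/AUC from all
  held-out scores pooled, and one confusion table from pooled hard calls —
  not per-fold averages — because a single curve per protocol is what the
  published tables report.
* **Stratified folds and splits.** Class-ratio-preserving partitions are
  used throughout (fold class counts differ by at most 1). Stratification is
  unstated in the source but reduces variance and cannot bias balanced
  data.
* **"Training" columns of ratio-split experiments.** Reported as internal
  fivefold CV on the training part. Plain resubstitution accuracy of a
  random forest is ~1.0, which contradicts the ~0.91 training values in the
  published table, so resubstitution cannot be what was reported.
* **Jackknife** is literal leave-one-out, capped at 2,000 samples unless
  overridden, because it costs `n` fits.

# The synthetic generator

`generate_windows()` produces the stated world the tests run in:

* Both classes receive exactly the same central-motif stratum counts
  (largest-remainder apportionment of the same ratios), reproducing the
  matched-negative design — the centre carries no class information.
* Positives are tilted towards an A-enriched profile
  `(0.55, 0.15, 0.15, 0.15)` at the biased offsets; negatives are uniform.
  `bias_strength` in `[0, 1]` linearly interpolates between uniform and the
  profile, so `0` is an exact null (identical class distributions) and the
  dial is a continuous difficulty control. The default 0.8 gives fivefold
  MNBE + RF AUC ≈ 0.95 at 1,000 + 1,000 — hard enough that metrics are not
  saturated, easy enough that the pipeline's recovery is unambiguous.
* The biased offsets default to −8…+10 and +15…+18 — the flanking regions
  where the real classes differ compositionally — plus −12…−9 standing in
  for the upstream AAAA consensus. The source localises that consensus only
  as "upstream", so its placement here is a documented package choice. The
  signal is compositional bias, not a planted deterministic motif, because
  that is what the real class difference looks like.

What the generator does **not** emulate: rice genomic base composition and
dinucleotide structure, the real benchmark's redundancy structure, any
linkage between the central motif and the flanking bias, and the unknown
true effect size of the real positional preferences. A green parameter
recovery test therefore establishes that the pipeline recovers a planted
positional signal of plausible strength and stays at chance on a true null —
it does not establish the published accuracies on real rice data, which
require the published benchmark and are out of scope here.

# Numerical and degenerate-input conventions

* KNFC block sums equal 1 to within 1e-12 (they are exact rational counts
  divided by a common denominator).
* Encoders are pure functions: identical input gives bit-identical output.
* Every stochastic operation takes one explicit integer seed and restores
  the caller's RNG state; no hidden global state.
* `sample_matched_negatives` fails loudly, naming the stratum and the
  shortfall, rather than silently relaxing ratios.
* Single-class test sets in `independent_eval()` return the defined point
  metrics with `NA`/absent for Sp-or-Sn, MCC and AUC, with a warning,
  rather than erroring — scoring a positives-only validation set is a
  legitimate use.

# Known limitations

* The identity filter is order-dependent and not CD-HIT; published-set
  reconstruction needs the real tool.
* The bundled forest is not WEKA's; per-sample score equality with the
  published model is impossible in principle.
* The independent-test negatives of the published comparison (CDS windows
  with GAGG motifs from the rice genome) require genome and annotation
  downloads and are not reproduced; `independent_eval()` evaluates whatever
  labelled set the caller supplies.
* Jackknife beyond a few thousand samples is computationally impractical by
  design; use k-fold CV there.
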