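# sixmApred

Sequence-based prediction of DNA N6-methyladenine (6mA) sites.

6mA is a DNA modification in which a methyl group is attached to the sixth
nitrogen of an adenine. In plant genomes (rice in particular) it is abundant
enough to matter for gene regulation but expensive to map experimentally, so
supervised classifiers are trained to recognise methylated adenines from
their local sequence context. `sixmApred` implements that pipeline for R
users working on desk-scale experiments: benchmark construction, feature
encoding, a deterministic random-forest classifier, and the standard
evaluation protocols.

## What the package computes

A sample is a 41-nt window `D = R1 R2 ... R41` over `{A, C, G, T}` with the
candidate 6mA site — an adenine — at position 21. Three feature maps are
provided:

* **KNFC** (k-tuple nucleotide frequency component): for each
  `k ∈ {2, 3, 4}`, the frequencies of all `4^k` overlapping k-mers in
  lexicographic order, 16 + 64 + 256 = 336 features. Each k-block is a
  probability vector (counts divided by `L − k + 1` slots).
* **MNBE** (mono-nucleotide binary encoding): the per-position one-hot code
  `A → (1,0,0,0)`, `C → (0,1,0,0)`, `G → (0,0,1,0)`, `T → (0,0,0,1)`,
  giving `4 × L = 164` features.
* **NV** (natural vector): the 12-vector
  `(n_R, μ_R, D2_R)` for `R ∈ {A, C, G, T}`, where `n_R` is the count of
  `R`, `μ_R` its mean 1-based position, and
  `D2_R = Σ_i (s_i − μ_R)² / (L · n_R)` the second-order normalized central
  moment of its positions.

Windows are classified by a bagged random forest (default: 100 Gini-split
CART trees, seed 1, `mtry = ⌊√p⌋`), implemented inside the package with its
own seeded RNG so fits are bit-reproducible. Evaluation reports

```
Sn  = 1 − N⁻₊/N⁺        Sp  = 1 − N₊⁻/N⁻
Acc = 1 − (N⁻₊ + N₊⁻)/(N⁺ + N⁻)        MCC ∈ [−1, 1]
```

(`N⁺`/`N⁻` the class sizes, `N⁻₊` false negatives, `N₊⁻` false positives)
plus the ROC curve and its trapezoidal AUC, under fivefold (or k-fold)
cross-validation with pooled out-of-fold scoring, ratio splits, jackknife
(leave-one-out), and independent-test protocols.

Benchmark construction utilities mirror the published design: negatives are
sampled so that the strata of the motif at the central adenine
(`GAGG` : `AGG` : `AG` : other = 17.08 : 15.76 : 14.42 : 52.74 by default)
match the positive set exactly, a greedy identity filter removes redundant
windows (a documented stand-in for CD-HIT), and classes are balanced by
seeded subsampling.

Because the real 154,000 + 154,000 rice benchmark requires an external
download, the package ships a synthetic generator that reproduces the two
statistical structures that make the problem learnable: matched central-motif
strata in both classes and a tunable positional A-enrichment in the positive
flanks (offsets −8…+10 and +15…+18, plus an upstream A-rich block). At
`bias_strength = 0` the two classes are identically distributed (a true
null).

## Worked example

```r
library(sixmApred)

## a 1,000 + 1,000 synthetic benchmark with strong positional bias
w <- generate_windows(synthetic_spec(n_pos = 1000, n_neg = 1000,
                                     bias_strength = 0.8, seed = 1))

## fivefold CV of the one-hot encoding with the default forest
report <- kfold_cv(w, schemes = "MNBE", classifier = rf_classifier(rf_config()),
                   k = 5, seed = 1)
print(report)
#> <m6a_metrics> [protocol=kfold, k=5, seed=1, classifier=random_forest, scheme=MNBE]
#>   Sn = 0.89  Sp = 0.874  Acc = 0.882  MCC = 0.7641  AUC = 0.9486

## train on everything, score a fresh held-out set
m <- train_model(encode_windows(w), w$label, rf_config())
test_w <- generate_windows(synthetic_spec(n_pos = 300, n_neg = 300,
                                          bias_strength = 0.8, seed = 2))
print(independent_eval(m, test_w))
#> <m6a_metrics> [protocol=independent, n=600, scheme=MNBE]
#>   Sn = 0.85  Sp = 0.8533  Acc = 0.8517  MCC = 0.7033  AUC = 0.9238
```

`Sn`/`Sp` say how many true 6mA / non-6mA windows were called correctly at
the 0.5 score threshold; `AUC ≈ 0.95` means a random positive outscores a
random negative about 95% of the time. On the null fixture
(`bias_strength = 0`) the same pipeline gives `AUC ≈ 0.5`, confirming that
the signal the forest finds is the planted positional bias and nothing else.

## Command line

A launcher is installed at `inst/exec/sixmapred` (run it with `Rscript` or
call `sixmApred::m6a_cli()`):

```sh
Rscript inst/exec/sixmapred synth   --out bench --n-pos 1000 --n-neg 1000 --seed 1
Rscript inst/exec/sixmapred encode  --in bench.tsv --out feat.csv --schemes mnbe
Rscript inst/exec/sixmapred train   --in feat.csv --out model.rds --trees 100 --seed 1
Rscript inst/exec/sixmapred predict --model model.rds --in bench.fasta --out scores.tsv
Rscript inst/exec/sixmapred cv      --in bench.tsv --out cv.json
Rscript inst/exec/sixmapred make-data --pos pos.fa --neg candidates.fa --out bench.tsv
```

All stochastic steps take explicit `--seed` flags and echo them into their
outputs, so every run is reproducible from its own provenance header.

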