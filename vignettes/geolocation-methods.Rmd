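---
title: "Methods: city geolocation from OTU count tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: city geolocation from OTU count tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical procedure it
implements, the choices that were genuinely open, and what its synthetic
benchmark does and does not demonstrate.

## The problem and the unit of classification

Samples are swabs from public urban surfaces, summarized as OTU counts
aggregated independently at the order, family and species ranks (rank-tagged
column names `o__`, `f__`, `s__`; a species resolved only to genus is named
`Genus.spp`). The classification unit is the **city-year group** (`CITY_YY`):
samples collected from the same city in different years are treated as
distinct classes, because year-to-year technical batch effects can be as
large as geographic differences and would otherwise contaminate a city
label. The same-city-different-year confusion count (`year_confusion()`)
quantifies exactly that risk after the fact.

## Preprocessing

**Depth filter.** Within each group, a sample is removed when its total
order-level count falls strictly below `fraction = 0.2` times the group
median of those totals. Order counts proxy overall sequencing depth; an
extremely shallow sample carries almost no compositional information. The
boundary is deliberately strict-below: a sample exactly at the cutoff stays.

**Ubiquity screen.** A taxon is kept when it is present (count > 0) in
strictly more than `threshold = 0.6` of the retained samples. This is a
relaxed "common feature" screen: taxa shared across cities are the ones on
which a cross-city model can generalize. The screen is computed after the
depth filter, on the filtered samples.

**Normalization.** `log2_cpm()` uses the voom convention
`log2((count + 0.5) / (library + 1) * 1e6)`, with the library size summed
over the taxa present in the matrix being normalized. The offsets bound
values away from minus infinity, so the matrix is finite everywhere; the
closed form is exact (tested to 1e-12). Only the normalization is used —
no precision weights. Normalization happens *before* feature selection
(numerically safer for the penalized fits); the offsets and a whole-table
library-size option are exposed as arguments.

## Feature selection by retention counting

For each group, `fit_one_vs_rest()` fits a binomial-deviance elastic net
(via glmnet) of "this group vs everything else". The mixing parameter is
fixed at `alpha = 0.4` for all fits — a compromise between lasso sparsity
and ridge stability chosen once for the whole panel — and the penalty
strength is the cross-validated deviance minimizer (`lambda.min`; the
1-SE rule is available and is the automatic fallback for degenerate fits).
Folds are stratified by class and seeded, so fits are reproducible. Class
imbalance is left unweighted by default.

A taxon's **retention count** is the number of one-vs-rest models giving it
a nonzero coefficient; `select_by_cutoff(profile, c)` keeps taxa with count
≥ c ("at least c models"), so feature sets nest monotonically in the cutoff.
`cutoff_sweep()` reproduces the cutoff-by-method error table from which a
working cutoff is chosen by balancing error against feature-set size.

## The repeated-split voting protocol

`make_split_plan()` fixes, per group, `round(0.2 · n)` samples (minimum 1,
round-half-up) as a test set used by *every* repetition, then re-splits the
remainder per repetition into 80% training / 20% validation. Each
repetition refits the learner and casts one vote per test sample; over
`n_reps` repetitions a vote tally accumulates. Errors are reported as:

- **top-1**: correct iff the true class is in the argmax vote set. The tie
  rule is generous by default (a tie that includes the truth is correct)
  because ties between the first and second vote rank are exactly what
  motivates the top-2 metric; a strict rule is available
  (`topk_error(..., ties = "strict")`).
- **top-2**: correct iff the true class holds one of the two highest
  *distinct* vote ranks (all classes tied at those ranks are eligible).
  Top-2 error therefore never exceeds top-1 error.

Back-ends: random forest (1,000 trees, `floor(sqrt(p))` variables per
split), RBF SVM (gamma over 10⁻³…10¹, cost over 10⁻¹…10³ by decades,
selected on validation accuracy), and a multilayer perceptron. No
deep-learning framework is a dependency: the MLP is implemented in the
package in plain matrix code — ReLU hidden layers (default widths 64 and
32), softmax output, inverted dropout (default rate 0.3), Adam (learning
rate 10⁻³), minibatches of 32, early stopping on validation loss with
patience 15 and best-weight restoration. Inputs are standardized inside the
model. The architecture beyond "ReLU + softmax + dropout" was an open
choice; two modest hidden layers with early stopping is a deliberately
conservative default for feature panels of tens to low hundreds of taxa.

## City traits

Monthly climate series (`month-stat` values) are remapped to meteorological
seasons with the hemisphere mirrored (southern summer is Dec–Feb), then the
seasonal mean of the monthly means feeds `kmeans_discretize()`: k-means with
25 restarts, labels re-ordered by ascending cluster mean so a higher level
always means a warmer/wetter city. When k equals the number of distinct
values the exact optimum (each value its own cluster) is returned directly.
The number of clusters is either forced per trait (the default trait
cardinalities are 3/4/3/2 for summer temperature, winter temperature,
summer humidity, winter humidity) or chosen by maximizing the mean
silhouette width over a k range — a compact stand-in for running a battery
of cluster-number indices plus visual inspection, and overridable per trait.
The urbanization score sums the anthrome ladder (wildlands 0, forested 1,
rangelands 2, croplands 3, villages 4, dense settlements 5) over the three
neighboring biomes and binarizes at the median with the ≥ convention (ties
go to 1; the tie convention was an open choice, and ≥ makes the all-equal
case well defined). With cardinalities (3, 4, 3, 2, 2, 2) the trait space
allows 288 distinct profiles.

## Mystery samples and candidate narrowing

`run_mystery_protocol()` holds out 20% of the unknown-origin samples per
repetition and trains the MLP on the full main dataset plus the remaining
mystery samples under one extra class label `"mystery"`. Votes accumulate
only in repetitions where a sample is held out, so a sample's vote total is
the number of times it was tested (roughly 20% of repetitions); rates are
vote-share based. The detection rate of truly-unseen-city samples is the
fraction whose top-voted class is `"mystery"`.

`fit_multioutput_traits()` trains one shared-trunk network with six softmax
heads (per-head cross-entropies summed unweighted) mapping a sample's
microbial profile to its city's six trait levels; years are merged since
climate is stable across adjacent years. Per-trait misclassification is
reported on a stratified 20% holdout. For an unseen city,
`average_profiles()` takes the arithmetic mean of the per-sample predicted
levels (fractional means flag within-city disagreement) and
`match_pattern()` rounds the means and ranks known cities by L1 distance on
the ordinal levels — the simplest metric faithful to "similar pattern"
reasoning; on binary traits the distance is exactly the number of
mismatched traits, and ties are reported together.

## The synthetic benchmark

`simulate_metasub()` generates the structure the analysis assumes, with
ground truth for every planted effect:

- per-rank baseline log-abundances ~ N(0, 2.5²), a wide spread so rare taxa
  drop out of samples and the ubiquity screen has work to do;
- per-city signature taxa (default 8) shifted by `signature_effect`
  (default 2 natural-log units) in their city. Signatures are drawn from
  the mid-abundance band (baselines clamped to the 40th–80th percentile):
  informative city fingerprints are common taxa, and the clamp prevents a
  dominant taxon from compositionally diluting its fellow signatures below
  their rest-of-world share — the planted-signal contract is verified
  empirically at generation time;
- per-city-year batch shifts ~ N(0, `batch_effect_sd`²) (default 0.3)
  applied to every taxon, the mechanism that makes city-year groups the
  honest classification unit;
- log-normal library sizes (mean 20,000 counts, log-SD 0.6) with a planted
  minority (default 5%) of low-depth outliers scaled by a factor strictly
  below 0.2, so they fall below the depth cutoff by construction — outliers
  are depth-only, never compositional, matching the purely depth-based
  filter;
- multinomial counts per rank given the softmax proportions and the
  library size (each rank gets its own multinomial with the same library
  size, mimicking independent aggregation at three ranks); a
  Dirichlet-multinomial overdispersion layer was considered and left out —
  the multinomial is the simplest model satisfying the planted-signal
  contract;
- city traits planted as ordinal levels with all levels represented, and
  monthly climate emitted around well-separated level centers (e.g. summer
  temperature centers 14/22/30 °C, monthly noise SD 0.8 °C) so the
  discretization recovers the planted levels exactly; hemispheres are
  mixed, and biome triples are drawn from the low or high anthrome range to
  match the planted urbanization level;
- optional mystery data: resampled cities reuse main-city signatures with a
  fresh batch shift (a new collection year), unseen cities get fresh
  disjoint signatures.

Defaults emulate a desk-scale version of a 23-city/28-group survey: 6
cities, two sampled in two years (8 groups), 20 samples per group, and
40/60/120 taxa at order/family/species — about one fifth of the published
per-rank feature counts. Per-city sample sizes in the real survey ranged
roughly 15–50 and are config-exposed rather than fixed.

What passing tests on this generator do **not** show about real data: no
phylogenetic or co-occurrence correlation among taxa, no overdispersion
beyond multinomial sampling, batch shifts that are i.i.d. across taxa
rather than structured, and climate traits that are exactly
city-deterministic. Real headline error rates (tens of percent) are
therefore not reproduced here — the synthetic conditions are designed so
that *calibration* (chance-level error on null data, near-zero error under
strong signal, detection above the 1/(G+1) chance level) is testable, not
so that the published error magnitudes reappear.

## Numerical and protocol choices

- One top-level seed derives per-stage sub-seeds; simulation, fold
  assignment, k-means restarts, split plans, learner initialization and
  dropout are all seeded, so a run is reproducible end to end.
- Round-half-up with a minimum of one test sample per group for stratified
  split sizes; a group too small for a validation slice trains without one.
- A failed learner repetition is retried with a fresh sub-seed; more than
  five failures abort the protocol.
- Degenerate inputs error loudly with the offending cell/sample named
  (negative counts, zero library sizes, missing metadata, mismatched
  feature sets between main and mystery tables).
- Test-suite problem sizes: 3–6 cities, 6–25 samples per group, 2–25
  repetitions, and 60–220 taxa; the acceptance checks use 20 simulated
  datasets for the retention property and 25 repetitions for the
  calibration runs.

## Known limitations

- No batch-effect correction or alternative normalizations (CSS/TMM,
  rarefaction); the city-year grouping absorbs batch effects rather than
  removing them.
- The mystery mechanism is the explicit extra-label scheme, not an open-set
  recognition method; it cannot say *where* an unseen sample is from, only
  that it is none of the known classes, which is why the trait-profile
  matching step exists.
- The multi-output trait model can only map unseen cities onto trait
  combinations seen in training.
- Hyperparameter search is limited to the stated SVM grids and MLP early
  stopping; there is no broader tuning, by design.
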