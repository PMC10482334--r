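---
title: "Methods: OPLS-DA, time-course fold changes and annotation tiers in longomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OPLS-DA, time-course fold changes and annotation tiers in longomix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longomix)
```

# The problem

Longitudinal two-condition omics experiments — the motivating case is a
fed-batch CHO culture run under two feed media and profiled over two to three
weeks by untargeted LC-MS metabolomics and TMT proteomics — produce
feature-by-sample abundance tables whose variance is dominated by the culture
*time* trajectory. The biological question, however, is the *condition*
contrast, which typically drives only a few percent of the total variance.
longomix implements the standard chemometrics answer to this structure:

1. curate features by retention time and abundance floor;
2. pareto-scale (metabolites, raw abundances) or mean-center (protein
   ratios) the table;
3. fit a two-class OPLS-DA that separates a predictive component (condition)
   from orthogonal components (time), and validate it by stratified
   cross-validation and a label-permutation test;
4. flag features whose predictive loadings are large relative to the loading
   spread;
5. summarize each feature's trajectory per condition by the area under the
   curve (AUC) over culture days and call regulation by a signed fold-change
   threshold *and* the loading flag jointly;
6. grade metabolite identifications into confidence tiers from retention
   time, mass accuracy, isotope fit and MS/MS evidence.

A synthetic-data generator with planted ground truth makes the whole chain
testable end to end.

# The OPLS-DA model

With `X` (n observations × p scaled variables) and class response
`y ∈ {+1, −1}` (centered), one orthogonal component is extracted per
iteration of the O-PLS recursion:

```
w   = X'y / ||X'y||           predictive weight (unit norm)
t   = X w                     predictive score
p   = X't / (t't)             predictive loading
w_o ∝ p − (w'p) w             orthogonal weight (unit norm)
t_o = X w_o ;  p_o = X't_o / (t_o't_o)
X  ←  X − t_o p_o'            deflation
```

and the final predictive component is a 1-component PLS on the filtered `X`.
Because `X'y` is invariant under the deflation (each `t_o` is exactly
uncorrelated with `y`), the predictive weight is stable across iterations;
with zero orthogonal components the model *is* a 1-component PLS1-DA, which
the test suite asserts to machine precision.

Variance bookkeeping is done against the total sum of squares of the input
matrix: `R2X_pred + Σ R2X_ortho + R2X_resid = 1` holds exactly because all
score vectors are mutually orthogonal by construction (asserted to 1e−8 on
random matrices). `R2Y = 1 − ||y − b·t||² / ||y||²`.

**Class encoding.** `test = +1`, `control = −1` (or `positive_class=`),
fixed so score-plot orientation is reproducible. Flipping the encoding flips
the signs of scores and loadings but changes no magnitude, R², Q² or
significance call — a tested invariance.

## Cross-validated Q2

`Q2 = 1 − PRESS / SS(y)` with strictly out-of-fold prediction. Folds are
stratified by class with a deterministic round-robin assignment in order of
appearance (which also spreads time points across folds), so repeated calls
are reproducible without consuming random numbers — important inside the
permutation loop. The default of 7 folds is the long-standing chemometrics
convention; it is a package default, not a fact about any particular study.
When `scale = "pareto"`/`"center"` is requested the scaling is refit inside
every training fold and applied frozen to the held-out fold, avoiding
leakage. A training fold that loses an entire class is an error; a fold
whose fit degenerates (zero class covariance, possible under permuted
labels) falls back to predicting the training class mean.

**Choosing orthogonal components.** `n_ortho = "auto"` adds components while
Q2 improves by more than 0.01, capped at 5. On strongly separable data this
legitimately selects *zero* orthogonal components: the time structure is
orthogonal to `y`, so it inflates neither PRESS nor the inner relation, and
removing it does not improve prediction. The orthogonal split is still
scientifically informative (it is how the time share of variance is read
off), so analyses that want the split should pass `n_ortho = 1` explicitly.

## Permutation validity test

Class labels are permuted `n_perm = 200` times; R2Y and Q2 are recomputed
per permutation and

```
p = (1 + #{permuted Q2 ≥ observed Q2}) / (n_perm + 1).
```

Permutations identical to the observed labeling, or to its full class swap,
are redrawn: both reproduce the observed model exactly (the swap only mirrors
it), so they carry no information about the null and would put a hard floor
of `2/(n_perm+1)` on the attainable p-value. For a balanced 12-observation
design the redraw excludes 2 of 924 arrangements — a ~0.2% perturbation of
the null, far inside the binomial acceptance band the calibration test uses.
Calibration is verified empirically: over 100 noise-only simulations the
fraction of runs with p ≤ 0.05 must fall in the exact binomial 95% region
around 0.05, and on perfectly separable data every run must give
p = 1/201.

## The loading-significance rule

A feature is significant when `|p_pred[j]| > sd(p_pred)` — the sample
standard deviation of the predictive-loading vector itself, with strict
inequality. This is the literal "loading greater than the standard
deviation" rule used with SIMCA-style workflows; whether that software
actually uses jack-knifed loading confidence intervals is unknowable from
the outside, so the sentence is implemented as written. Degenerate edges are
defined, not accidental: an all-equal nonzero loading vector has `sd = 0`
and flags everything; an all-zero vector flags nothing. Roughly: with `m`
planted features among `p` at a common loading scale `L` and near-zero null
loadings, `sd ≈ L·sqrt(m/p)`, so the rule adapts its own threshold to the
fraction of structured features — at 50/2000 the cutoff sits near `0.16·L`,
which is what makes the end-to-end false-discovery rate small on the
standard synthetic design.

# Time-course statistics

**AUC.** Replicate values are averaged per day (missing replicates skipped;
a fully missing day is an error naming the day) and the means are integrated
by the trapezoid rule on the observed day grid. The trapezoid of per-day
means equals the mean of per-replicate trapezoids on a complete design, so
the aggregation order is immaterial; an independent oracle (midpoint rule on
the linear interpolant) agrees to 1e−10 relative on random trajectories.

**Signed fold change.** `r = AUC_test / AUC_control`, reported as `r` when
`r ≥ 1` and `−control/test` otherwise, so values live in
`(−∞,−1] ∪ [+1,∞)` and thresholds read "± k-fold". The down branch is
computed as `−(control/test)` — not `−1/r` — so antisymmetry under condition
swap is exact in floating point. When the control AUC sits at or below the
detection floor while the test AUC is above it, the result is the `+Inf`
sentinel ("infinite increase", the behaviour expected for a feature present
in only one condition); both below the floor is undefined (`NA`) and can
never be called regulated.

**The floor on the AUC scale.** The retention floor of 5,000 abundance
units translates to `5000 × (day span)` on the AUC scale: a trajectory
pinned at the abundance floor integrates to exactly that, so comparing the
raw AUC against 5,000 would make the sentinel unreachable.
`differential_analysis()` applies this translation; `fold_change()` itself
takes whatever floor the caller supplies.

**Max fold change.** For protein-style data an alternative statistic takes
the per-day signed fold changes and returns the one with the largest
magnitude (sign kept, infinite sentinels dominate, earliest day wins ties),
with the day recorded.

**Regulation call.** `regulated ⇔ |signed_fc| ≥ threshold (boundary
inclusive; Inf passes) AND loading-significant`. Default thresholds: 1.5
(metabolite mode) and 1.1 (protein mode). Direction follows the sign for
regulated features and is `"none"` otherwise. If the two conditions were
sampled on different day grids the intersection is used with a warning.

# Annotation confidence tiers

Tier cascade (first rule fires), with RT and ppm windows inclusive and the
isotope-fit bound strict:

| tier | requires |
|------|----------|
| 1    | in-house standard: RT ± 0.3 min, mass ± 3.0 ppm, MS/MS match |
| 1\*  | same standard match, feature lacks MS/MS data |
| 2    | spectral library: mass ± 3.0 ppm and MS/MS pattern match |
| 3    | tentative structure: mass ± 3.0 ppm, MS/MS annotated manually |
| 4    | mass ± 3.0 ppm, isotope fit mSigma < 100, sum-formula match |
| 5    | mass and retention time only |

A missing mSigma skips the tier-4 rule (it is not an error). Among several
in-window references the smallest `|ppm|` wins, ties broken by `|ΔRT|`, then
lexicographic name — tie-breaking is a package convention, since no external
rule exists. Tier 2 deliberately has no RT requirement: spectral libraries
are not instrument-specific. The engine is total and deterministic, and
clearing any match flag can only worsen (raise) the tier — a tested
monotonicity property. `summarize_tiers()` cross-tabulates tiers against
abundance bins (default edges 5,000 / 10,000 / 50,000 / 100,000 / ∞; only
the outer bins are conventional, the interior edges are configurable).

# The synthetic world

`study_design()` defaults *are* the stated world of the analysis, chosen
once:

| parameter | default | why |
|-----------|---------|-----|
| days | 3, 5, 7, 10, 12, 14, 17 | fed-batch sampling grid of the motivating study |
| replicates | 3 | bioreactor replicates per condition |
| n_features | 2000 | "thousands of features" at desk-test scale |
| n_discriminative | 50 | a few percent of features carry the condition |
| effect_log2fc | 1 | true 2× ratio, random sign per feature |
| time_variance_fraction | 0.6 | time drives ~50–65% of variance in such data |
| noise_cv | 0.2 | 20% replicate CV, typical untargeted LC-MS precision |
| n_exclusive | 20 | features present in only one condition |

Each feature's log-abundance is
`baseline + a_i · h(day) + δ_i · 1[test] + ε`, where `h` is **one shared**
cubic trajectory standardized to unit variance across samples (population
sd over the day grid, since every day carries equal samples), `a_i` is a
per-feature signed amplitude solving
`a_i² = f/(1−f) · (σ² + δ_i²/4)` so each feature's time share equals the
target `f`, `δ_i = ±effect·ln 2`, and `ε` is Gaussian with
`σ = sqrt(log(1+cv²))` (i.e. multiplicative log-normal noise — abundances
are positive and right-skewed). A *shared* trajectory (rather than
independent per-feature trends) is a deliberate choice: it makes culture
time a rank-1 direction in feature space, which is what lets a *single*
orthogonal component absorb the time share, as observed in real
time-dominated models. Baselines are log-normal around 1e5; planted
features are kept above the detection floor and inside the retention window
so curation cannot silently delete ground truth. Exclusive features are
recorded as missing (`NA`, below the 5,000 floor) in the control condition.

`realized_time_variance()` reports the share actually achieved by regressing
the pooled pareto-scaled data on the trajectory. It lands ~0.01 below the
target at the defaults — the residual convexity bias of exponentiating the
log-scale construction — comfortably inside the ±0.05 contract at
n ≥ 1000 features.

**What the generator does not emulate** (so what a green test does *not*
establish): batch and injection-order drift, correlated feature blocks
beyond the single time direction (adducts, isotopologues, pathway
co-regulation), intensity-dependent (heteroscedastic) noise, missingness at
low abundance rather than by condition, retention-time drift, and any
chromatographic or spectral raw data. Conclusions about those failure modes
need real data.

`generate_annotation_evidence()` plants an intended tier per feature and
constructs evidence realizing exactly that tier: reference masses sit on a
jittered grid separated by far more than the ppm window, so a feature can
match at most one record and cannot accidentally qualify for a better tier;
the rule engine reproduces the intended tiers for 100% of features — the
generator and the cascade are written independently and cross-checked.

# Numerical and policy choices

- Metabolite tables are pareto-scaled on **raw** (not log) abundances,
  following the dominant software convention for this workflow; protein
  ratio tables are centered only. Missing values are imputed at
  detection-floor/2 before scaling (configurable).
- Scaling may be applied once globally (as interactive analyses typically
  do) or refit per CV fold (leakage-free); both modes are exposed and the
  cross-validation default inside the pipeline scales once globally,
  matching what the fitted model sees.
- Orthogonal extraction stops early when the orthogonal weight norm falls
  below 1e−10 of the loading scale (no orthogonal variation left); the
  pure rank-1 class-aligned limit therefore yields R2X_pred = 1 with zero
  orthogonal components.
- Ties at the `|loading| = sd` boundary are excluded (strict inequality,
  "greater than"); ties at the fold threshold are included ("minimum fold
  change of ±k").
- Fold ties in `max_fold_change` resolve to the earliest day.
- All randomness in a pipeline run derives from one integer seed; the run
  manifest (config + seed + versions) suffices to reproduce any run, and
  identical seeds give byte-identical output tables.

# Known limitations

- Two classes only; no multi-class OPLS-DA, O2PLS, S-plots or VIP scores.
- The loading-significance rule is the literal sd rule; no jack-knifed
  loading confidence intervals.
- The permutation test permutes labels freely (subject to the identity/swap
  redraw); it does not restrict permutations within days, so its null
  ignores the repeated-measures structure — as does the convention it
  reproduces.
- AUC fold changes inherit the day grid; no smoothing or unequal-variance
  weighting is applied.
- Annotation evidence is tabular and boolean for MS/MS matches; no spectral
  similarity scoring.
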