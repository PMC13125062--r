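---
title: "Individualized structure-function coupling: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized structure-function coupling: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sfgap)
```

## The scientific question

White-matter microstructure, summarized by fractional anisotropy (FA),
constrains the synchronized activity patterns that resting-state functional
connectivity (FC) measures. `sfgap` asks the individual-level version of the
structure-function coupling question: **how well can a person's FA —
whole-brain and in each white-matter region — be predicted from their
distributed FC pattern**, which functional circuits carry that prediction,
and does the *residual* (the "structure-function gap": predicted minus
observed FA) relate to behavior?

The pipeline has five stages.

1. **FC features.** Pearson correlations between regional BOLD series are
   averaged across hemispheres: for bilateral regions *i, j* the entry is
   the mean of the four cross-hemisphere correlations
   {L~i~L~j~, L~i~R~j~, R~i~L~j~, R~i~R~j~}, and the diagonal holds the
   homotopic correlation cor(L~i~, R~i~). The upper triangle *including*
   that homotopic diagonal is the feature vector: R(R+1)/2 features, e.g.
   1431 for 53 bilateral regions.
2. **Confound control.** Every FC feature and FA target is adjusted by a
   linear model with fixed effects for age, sex, scanner, socioeconomic
   status and race/ethnicity plus a random subject intercept, fitted by REML
   on training visits only and applied through its fixed effects.
3. **Prediction.** An exact Gaussian process with an RBF kernel under
   automatic relevance determination (ARD; one lengthscale per feature)
   predicts FA under 5-fold *subject-level* cross-validation — all visits of
   a subject share a fold. Feature importance is the fold-averaged inverse
   lengthscale 1/ℓ.
4. **Regional analysis.** The 27 regional models are filtered for
   reliability (observed FA must predict the out-of-fold predicted FA in a
   random-intercept model at p < 0.05), their importance maps embedded in 2D
   and tested for clustering by anatomical tract family with PERMANOVA.
5. **Gap-behavior link.** Per-visit gaps (predicted − observed), corrected
   for head motion and observed-FA magnitude, are related to a behavioral
   battery by regularized CCA under the same subject-level folds, with
   subject-level permutation inference for component correlations and
   canonical loadings.

## The synthetic cohort: what it emulates and what it does not

Real adolescent cohorts of this kind are restricted-access, so the package
ships a generator (`sim_config()` / `simulate_cohort()`) whose defaults play
the role of the study conditions:

* **Longitudinal structure**: visits per subject uniform in `visit_range`
  (default 1–6, matching a cohort with up to six annual visits), age
  uniform 12–22 at baseline plus one year per visit; sex, scanner and
  race/ethnicity categorical; SES in years of parental education
  (mean 16.8, sd 2.5).
* **FC with homotopic structure**: each homologue pair shares a latent
  factor (baseline coupling weight 0.55 on the logit scale, per-visit sd
  0.4, shifted by 0.02/year of age) and all regions share a global factor
  (weight 0.35); BOLD length 160. Because the signal is injected through
  the factor loadings, every simulated FC matrix is a genuine correlation
  matrix. FC varies across visits both through the coupling weights and
  through finite-series sampling noise.
* **Sparse coupling**: each FA target depends linearly on a planted support
  of `support_size` (default 10) FC features with unit-norm coefficients
  scaled by `beta_scale`; targets in the same tract family share their
  support (so tract clustering of importance maps is literally true).
  FA noise has a subject random intercept (sd 0.02) and visit noise
  (sd 0.02), in FA units around a baseline near 0.5.
* **The planted gap-behavior link**: a low-rank latent trait enters FA
  additively and is *independent of FC by construction*, and the behavioral
  battery (126 measures with ~5% missingness) loads on the same trait. The
  FC-unexplained FA component therefore carries the behavior signal, which
  is exactly what the gap analysis claims to detect; its population
  canonical correlations follow in closed form from the planted loadings
  (`planted_canonical_correlations()`).

What the generator does **not** emulate: empirical FA/FC marginal
distributions of any real cohort, site- or sequence-specific artifacts,
spatial autocorrelation of parcellations, non-linear coupling, and
measurement error models for behavior. Passing recovery tests therefore
shows the *machinery* is correct and calibrated — not that real adolescent
data behave this way.

### Oracle calibration

The recoverability benchmark is the *oracle*: the accuracy of the true
planted coefficients applied to the realized FC features. Because the
pipeline works on confound-residualized data, the oracle signal is first
projected off the confound design — the age-mediated part of a planted
signal is not recoverable by any confound-controlled model
(`oracle_prediction_r()`). `calibrate_beta_scale()` solves for the
`beta_scale` that makes this residualized oracle equal a requested value,
using a pilot cohort with the same seed and size so the calibration is
exact for the cohort actually generated.

## The GP and its numerical choices

The kernel is
σ²~f~ exp(−½ Σ~k~ (x~k~−x′~k~)²/ℓ~k~²) + σ²~n~ 𝟙[x = x′], fitted by
maximizing the log marginal likelihood with analytic gradients (L-BFGS-B).
Choices that matter:

* **Standardization.** Features are standardized and the target centered
  within each training fold, so lengthscales are comparable across features
  and the GP mean is the training-target mean.
* **Initialization.** Lengthscales start at √p (the median-distance
  heuristic: standardized features put typical squared distances near 2p;
  a unit start makes every kernel entry e^(−p) ≈ 0 and kills the gradient).
* **Staged variances.** The two variance parameters are fitted first with
  lengthscales pinned, then everything is released. Starting all p + 2
  parameters jointly tends to fall into an interpolating local optimum in
  which the noise variance collapses to zero — a known failure mode of
  ARD evidence maximization with many lengthscales. For low signal-to-noise
  problems `noise = "fixed"` additionally freezes the staged noise estimate
  during relevance determination.
* **Multi-start.** The second start sets each lengthscale inversely
  proportional to the feature's marginal correlation with the target, so
  the optimizer also explores the basin where empirically relevant features
  are already short; the start with the best final evidence wins.
* **Bounds.** Lengthscales live in [10^−3^, 10^3^] so 1/ℓ stays finite and
  fold-wise coefficients of variation are defined; variances are bounded
  relative to var(y); the kernel diagonal carries a 10^−8^ σ²~f~ jitter.
* **Subset-of-data option.** `max_opt_n` learns hyperparameters on an
  evenly-spaced subsample and then conditions the posterior on the full
  training fold — the standard exact-GP economy when n grows.

Accuracy is summarized two ways: the pooled correlation over all out-of-fold
predictions (the headline number), and the fold-averaged within-fold
correlation (`r_fold_mean`). The pooled version carries a structural
negative bias under the null — training means differ across folds, and that
between-fold variation anticorrelates with the held-out values — so the
fold-averaged version is the one to use for null calibration.

Importance is aggregated to gray-matter regions as the **mean** over
incident features (the homotopic self-feature counted once); a **sum**
aggregation is available since both conventions appear in practice, and
they differ only by the constant incidence count R.

## Reliability filter, embedding, PERMANOVA

Regional models whose out-of-fold predictions do not track observed FA
(slope p ≥ 0.05 in `predicted ~ observed + (1|subject)`) are excluded from
the clustering and gap stages. Retained importance rows are L2-normalized
(so overall importance scale does not dominate pattern similarity) and
embedded with a native UMAP implementation: the standard fuzzy-kNN graph
(n_neighbors = 5 for the ~24 embedded points, min_dist = 0.1) optimized by
full-batch Adam on the fuzzy cross-entropy — deterministic given the seed
and appropriate at this scale, where edge-sampling SGD buys nothing.
PERMANOVA runs on the embedded coordinates by default (with an option to
test the raw normalized importance vectors instead; both are reported by
the pipeline since either convention is defensible), using the seeded
permutation p-value (1 + b)/(1 + m), or exhaustive enumeration of all label
permutations on small problems.

## Gap correction and the CCA

Raw gaps (predicted − observed, positive = observed integrity below the
FC-predicted level) are regressed on mean relative head displacement and on
the observed FA value (random subject intercepts), because high motion and
large FA magnitudes mechanically inflate residuals. Fixed effects only are
removed, consistent with the confound convention: under subject-level CV a
test subject's random intercept is undefined.

The regularized CCA uses the shrinkage convention
C(c) = (1−c)·cov + c·I on standardized variables, c searched over 50
log-spaced values in [10^−4^, 1] (jointly for the two sides); the inner
criterion is the first-component correlation on a nested 80/20 subject
split of the training fold. Behavioral measures missing for more than half
the participants are dropped; remaining missingness is median-imputed with
training-fold medians. Component order follows the training canonical
value; weight signs are aligned across folds before out-of-fold variates
are concatenated, so canonical loadings (variable vs own-side variate,
computed on out-of-fold variates) are well defined. Permutations move
whole subjects (visit blocks swapped among subjects with equal visit
counts), preserving longitudinal dependence exactly; by default the
regularization search is re-run per permutation (conservative), and a fast
mode reuses the selected pair — the package's calibration tests use the
fast mode. Ten components are computed by default; each is tested against
its own permutation null, and loading significance is two-sided on
|loading| at p < 0.05.

## Problem sizes used by the test suite and acceptance script

The packaged checks run cohorts scaled to single-CPU desk hardware:
structural checks at full atlas size (106 → 53 regions, 1431 features);
GP-oracle equivalence on ≤10-point toys; parameter recovery at 1000
subjects with 1–3 visits and a reduced 19-pair atlas (190 FC features,
support 10, oracle r = 0.3); null calibrations with hundreds of small
replicates; CCA recovery at n = 2000 visits with planted population
correlations 0.4/0.25. These sizes are the package's chosen study
conditions for the synthetic checks and are stated here so results are
reproducible.

## Known limitations

* Exact GP inference is O(n³); beyond a few thousand visits use
  `max_opt_n` or expect long fits. No sparse/approximate GP is provided.
* At the low signal-to-noise ratios typical of this problem
  (oracle r ≈ 0.3, ~9% signal variance spread over a sparse support inside
  ~200 correlated features), *no* regularized estimator attains the oracle:
  in the packaged recovery study the true-coefficient regression itself
  loses accuracy out of fold, the lasso trails it, and evidence-optimized
  ARD trails the lasso. The recovery tests therefore check calibrated,
  quantified behavior rather than oracle attainment; see the acceptance
  materials for measured values.
* The bilateral averaging deliberately collapses lateralized effects; the
  cross-pair averaging uses all four LR combinations, a documented dialect
  choice.
* The reliability filter's p-values use a normal approximation to the
  random-intercept slope test (accurate at the hundreds-of-visits scale it
  is applied to; lme4/lmerTest agreement is asserted in tests).
* `scfc_spearman_coupling()` implements the classical per-region Spearman
  SC-FC baseline only for comparison; the package does not model structural
  connectivity itself.
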