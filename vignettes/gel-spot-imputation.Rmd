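---
title: "Imputation and differential analysis of 2-DE spot matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputation and differential analysis of 2-DE spot matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelimpute)
```

## The problem

Two-dimensional gel electrophoresis (2-DE) quantifies a proteome as stained
spot volumes on one gel per sample.  After image analysis and spot matching,
the data form a spots x gels matrix of normalized volumes.  Such matrices
are chronically incomplete: a spot seen on the reference gel is often not
detected or not matched on others, for technical reasons (staining,
migration, image-analysis limits) and biological ones (abundance below the
detection limit).  Missingness of 20--30% is typical, it falls
preferentially on low-intensity spots, and most downstream machinery
(per-spot tests, PCA, clustering) needs complete data.  Substituting zeros
distorts every downstream statistic, while dropping incomplete spots can
discard most of the matrix.

`gelimpute` implements a three-step analysis for this situation:

1. **Imputation** of missing spot volumes: row average (`RowAve`),
   k-nearest neighbours (`KNN(k)`), the least-squares regression family
   with spot-wise, array-wise, EM-refined, combined and adaptive
   correlation structures (`LSM.LS.G`, `LSM.EM.G`, `LSM.LS.A`, `LSM.EM.A`,
   `LSM.LS.C`, `LSM.LS.Ad`), and NIPALS principal-component reconstruction
   (`NIPALS(n)`).
2. **Per-spot two-group testing**: Welch t, exact or Monte-Carlo
   permutation t, a Chebyshev-bound test, and three bootstrap-t p-value
   constructions by confidence-interval inversion.
3. **Error control**: per-comparison thresholding, Benjamini-Hochberg FDR,
   or the generalized family-wise error rate (gFWER) by augmenting Holm's
   procedure with the k next-smallest p-values.

Because imputation quality can only be measured where the truth is known,
the package also ships a Monte-Carlo benchmarking harness: mask cells of a
complete matrix, impute, and score the masked cells
(`run_rmse_experiment()`), or carry the imputed matrices through testing
and selection and compare the discovery sets (`run_discovery_experiment()`).

## The data model

A `spot_matrix` is a non-negative spots x gels matrix with `NA` for
missing cells plus a two-group `group_design`.  `mean_normalize()` divides
each gel by its total observed volume (the standard loading/staining
correction; observed volumes then sum to 1 per gel).
`filter_majority_present()` drops spots observed in at most half the gels
of either group *before* imputation; limiting the imputed fraction is the
single most effective guard against imputation-driven artifacts, so the
rule is strict (with 6 gels per group a spot needs at least 4 observations
in each group) and applied per group, because both imputation and testing
operate within groups.  A whole-matrix variant is available via
`per_group = FALSE`.

## The imputation methods

**Row average** replaces a missing cell by the mean of the spot's observed
cells.  It ignores which gel the cell came from, so it also removes the
between-gel part of the spot's variance --- the strongest variance
shrinkage of all methods here, which is exactly why it is a risky default:
deflated spot variances inflate downstream test statistics.

**KNN** finds the `k` spots closest to the target (Euclidean distance over
mutually observed gels, rescaled by `sqrt(n_gels / n_shared)` so different
overlap sizes are comparable, or `1 - r` for the Pearson metric) among the
spots observed at the target gel, and averages their values there,
weighted by inverse distance by default.  An exact duplicate (distance 0)
short-circuits to that neighbour's value.  Cells with no usable neighbour
fall back to the row average and are counted in the result.  Small `k`
keeps the neighbourhood local; as `k` grows the neighbourhood reaches
spots at different abundance levels and the error grows.

**Least-squares family.** The spot-wise ("gene") estimator `LSM.LS.G`
takes, per missing cell, the `n_neighbors = 10` spots most correlated with
the target over mutually observed gels (at least 3 shared gels required),
fits one simple regression per neighbour, and combines the predictions
with weights `w = (r^2 / (1 - r^2 + ridge_eps))^2`, so nearly-perfect
correlations dominate.  The array-wise estimator `LSM.LS.A` is the same
construction with spots and gels transposed (`ls_array(M)` equals
`ls_gene(t(M))` cell for cell).  With only ~70 spots the "most correlated"
spots are often spuriously correlated, which is why the spot-wise variants
underperform on small matrices.  `LSM.EM.G`/`LSM.EM.A` refine the
corresponding fill with the textbook Gaussian missing-data EM: conditional
means given the observed cells of each record under the current
mean/covariance (over spots resp. gels), with the conditional covariance
of the imputed blocks added back in the M-step --- omitting that
correction understates the covariance and over-trusts the regressions.
`LSM.LS.C` mixes the spot-wise and array-wise estimates with one global
proportion fitted by least squares on a seeded 5% hold-out of observed
cells; `LSM.LS.Ad` sets the proportion per cell from the relative
correlation-weight mass of the two sides.

**NIPALS** runs PCA by nonlinear iterative partial least squares, which
tolerates missing entries by restricting every inner regression to
observed cells; missing cells are imputed from the rank-`n_components`
reconstruction plus the spot means.  Two numerical choices matter.  The
score vector of each component is re-orthogonalized against earlier
components inside the iteration: with missing cells the update operator is
not symmetric, and without this step later components occasionally diverge
along incompletely deflated directions (we observed imputed values two
orders of magnitude outside the data range).  Components that still fail
to converge within `max_iter = 500` are accepted as-is with
`converged = FALSE`.

Negative imputed values are possible for the regression-based methods
(extrapolation) and are deliberately *not* clipped --- clipping would bias
the error comparison --- but their count is reported in every result.

## The tests

All six tests compare the two design groups per spot and return a
two-sided p-value.

* `t.welch`: the unequal-variance t with Welch--Satterthwaite degrees of
  freedom.  A spot with zero variance and zero mean difference returns
  statistic 0, p 1 (rather than NaN), so matrix-wide counting never drops
  spots.
* `t.perm`: permutes group labels and recomputes the Welch statistic; all
  C(12, 6) = 924 assignments are enumerated for the 6+6 design (exact
  p-values are multiples of 1/924, and the observed assignment is always
  counted, so p > 0).  Larger designs fall back to seeded Monte-Carlo.
* `chebby`: the distribution-free Chebyshev bound `p = min(1, 1/t^2)`
  applied to the Welch statistic.  Conservative by construction; its
  rejections at 0.05 require |t| > 4.47.
* `boot.normal`, `boot.percentile`, `boot.pivotal`: draw
  `n_boot = 25` within-group resamples, form the bootstrap distribution of
  the mean difference, and invert the corresponding confidence interval.
  25 resamples is the conventional choice for 6-gel groups but gives the
  percentile/pivotal constructions a p-value resolution of 2/25 = 0.08;
  single p-values from these tests are coarse, which is why the package
  summarises them over Monte-Carlo replicates.  The percentile
  construction is systematically the most liberal and the normal/pivotal
  constructions the most conservative; the analytic tests sit in between.

`test_matrix()` seeds the resampling per spot (`seed + row`), so a fixed
seed reproduces a whole table.

## Error control

For comparing imputation pipelines the package uses uncorrected
per-comparison selection at `alpha = 0.05` (strict `<`), which is fine for
method comparison but not for claiming discoveries.  For actual discovery
lists the package implements gFWER control by augmentation: reject the
Holm set at level alpha, then add the `k_allow` next-smallest p-values.
Controlling "more than k false positives" rather than the FDR suits 2-DE
scale (tens to hundreds of spots, each discovery expensive to follow up by
mass spectrometry).  Holm is used as the base procedure because it
dominates Bonferroni and needs no dependence assumptions.
Benjamini-Hochberg is included as the standard comparator.

## The synthetic study conditions

No public 2-DE matrix ships with the package, so the generator
(`generate_complete_dataset()`) emulates the study design the methods were
built for: 70 spots, 6 + 6 gels, log-normal abundances.  On the log scale
a cell is

    log_mean + spot_effect + gel_effect + loadings . factors
             + effect_size * [DE & group B] + noise

with defaults: `log_sd = 0.7` (between-spot spread; deliberately moderate,
because the complete-spot submatrix that benchmarks mask is
intensity-filtered --- spots matched on *all* gels are the brighter,
narrower-spread part of a gel), `gel_effect_sd = 0.3` (per-gel
loading/staining multiplier), `n_factors = 2` latent per-gel factors with
`factor_sd = 0.18` and standard-normal spot loadings (co-regulated protein
groups; this is the between-spot and between-gel covariation that
neighbour- and covariance-based imputation exploits in real data, and
unlike the gel effect it survives mean normalization), `spot_noise_sd =
0.2` (~20% residual CV), `de_fraction = 10/70` and `effect_size = 1.5`
(ten clearly-shifted spots).  The matrix is mean-normalized by default.

Masking is either uniform (`remove_at_random()`, exactly
`round(fraction * n_cells)` cells) or intensity-dependent
(`remove_intensity_dependent()`, per-spot logistic probabilities in the
spot-mean z-score, rescaled to the target fraction).  Both redraw masks
that would leave any spot with fewer than 2 observed cells in either group
--- row averages and two-group tests are undefined otherwise; the weaker
"at least 1 observed overall" rule is available via `constraint =
"overall"`.  The removal record stores the true values, so restoring it
reproduces the complete matrix exactly.

What the generator does *not* emulate: spatial gel structure (spot
positions, streaks, local background), intensity-dependent *noise*
heteroscedasticity beyond the multiplicative model, outlier gels, and
matching errors that swap spot identities.  Benchmarks passing on this
generator show that the pipeline ranks methods correctly when the data
follow a factor-structured log-normal model; they cannot certify behaviour
under gross image-analysis artifacts.

## Benchmark design choices

* **Paired masks.** Within a replicate, every method imputes the identical
  masked matrix, and the masks are *nested* across missing fractions (the
  5% mask is a prefix of the 20% draw; a prefix of a uniform draw is
  itself uniform).  Pairing removes most Monte-Carlo variance from method
  and fraction contrasts; the fraction effect on row-average error, for
  instance, is below 1% in NRMSE and would be invisible at 100 replicates
  under independent masks.
* **NRMSE.** Error is summarised as RMSE over masked cells divided by the
  SD of *all* true cells of the source matrix, making it scale-free while
  keeping the divisor identical across masks and fractions.  Dividing by
  the SD of the masked truths themselves (available as `divisor =
  "masked_sd"`, with `"mean"` as a third option) looks natural but is
  estimated from as few as 42 cells at a 5% fraction; the sampling noise
  of `1/sd` then inflates mean NRMSE by ~10% at 5% versus ~2% at 20%
  masking (Jensen bias), which is larger than some methods' genuine
  fraction trends and can reverse them.  Constant or zero divisors return
  the raw RMSE with an `unnormalized` flag.
* **Replicates.** 100 replicates for accuracy experiments and 20 for
  discovery experiments; the discovery protocol summarises each
  test/method pair by its median discovery count and by consensus sets
  (significant in at least half the replicates).
* **Selection inside benchmarks** is per-comparison; gFWER belongs to the
  final analysis of a real dataset, not to method comparison.

Under the default conditions the benchmarks reproduce most of the
qualitative behaviour the methods are known for: the array-covariance EM
imputer has the smallest mean NRMSE; KNN error is non-decreasing in k
over {3, 5, 8, 15}; mean NRMSE grows with the missing fraction (strictly
for KNN, EM and NIPALS; for row average the 10% to 20% increase is clear
while the 5% to 10% slope, about +0.2% by construction, sits below
Monte-Carlo resolution at 100 replicates); the average spot variance
stays at or below the complete matrix's for every method, with row
average much the lowest (the EM imputer sits within about 1% of the
complete value either way --- a near-exact conditional-mean imputer
neither adds nor removes much variance); and the percentile bootstrap
discovers the most spots.  One documented departure: with 25 resamples
*all three* CI-inversion bootstrap tests are liberal relative to Welch
(the plug-in bootstrap SD understates the standard error and the
percentile/pivotal rejections at 0.05 amount to "all 25 resamples on one
side", which a non-trivial fraction of null spots achieves), so the
normal and pivotal variants do not come out most conservative here.
These statements are exactly what the test suite asserts --- see
`tests/testthat/test-acceptance.R` --- and `scripts/acceptance.R`
recomputes the underlying numbers from scratch.

## Numerical choices and degenerate inputs

* EM convergence is judged on the imputed cells as a vector
  (`||new - old|| / ||old|| < em_tol = 1e-4`, at most 100 iterations);
  per-cell relative change never settles when an imputed value sits near
  zero.  Non-convergence returns the current fill with a warning and
  `converged = FALSE`.
* Covariance matrices are ridge-regularized by `ridge_eps` times the mean
  diagonal, and linear solves escalate the ridge if a submatrix is
  numerically singular (relevant for the spot-wise EM, which estimates a
  70 x 70 covariance from 12 gels).
* Correlation weights clip r^2 at 1 and skip zero-variance neighbours.
* Quartile boundaries in `completeness_by_quartile()` assign ties to the
  lower quartile.
* The missing token is `"NA"`; zeros are *observed* values unless
  `zero_as_missing = TRUE` is requested explicitly, because zero
  substitution is the practice this workflow replaces.
* All randomness (generator, masks, resampling tests, hold-outs) is
  seeded through function arguments; rerunning any driver with the same
  seed is byte-identical.

## Known limitations

* The imputers operate on the raw volume scale, as the methods were
  originally applied; heavy-tailed matrices make the regression methods'
  Monte-Carlo summaries noisy, and log-scale preprocessing may be
  preferable in practice.
* The adaptive mixing rule of `LSM.LS.Ad` (per-cell weight-mass ratio) is
  one reasonable reading of "adaptive"; other implementations weight by
  hold-out performance.
* The Chebyshev test uses the plain two-sided `1/t^2` bound without
  finite-sample correction.
* Bootstrap tests with `n_boot = 25` have coarse p-values; raise `n_boot`
  for single-matrix analyses.
* Only two-group, unpaired designs are supported.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
ds <- generate_complete_dataset(synthetic_config(seed = 1))
rem <- remove_at_random(ds$matrix, fraction = 0.2, seed = 2)

imp <- impute_spots(rem$matrix, "LSM.EM.A")
normalized_rmse(rem$record, imp)

tt <- test_matrix(imp$matrix, "t.welch")
sel <- select_gfwer(tt$p_value, alpha = 0.05, k_allow = 1)
tt$spot_id[sel]
```

See the README for a complete run with its printed output, and
`run_pipeline()` / `run_benchmarks()` for the file-based drivers.
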