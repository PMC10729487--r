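---
title: "Brain-age-gap trajectories over estimated years to symptom onset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-age-gap trajectories over estimated years to symptom onset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bagtraj)
```

## The problem

In autosomal dominant Alzheimer disease (ADAD), carriers of pathogenic
*PSEN1*, *PSEN2* or *APP* variants develop dementia at a roughly predictable
age, so each participant can be placed on a disease clock: the estimated
years to symptom onset (EYO), the difference between chronological age and
the mutation- or family-specific expected onset age. The brain age gap (BAG)
— a machine-learning prediction of age from structural MRI minus true age —
is a candidate summary marker of disease-related structural change. The
questions this package operationalizes are: after removing prediction bias
and scanner/site artifacts, *when* on the EYO clock does carrier BAG diverge
from non-carrier BAG, is that point earlier or later than for other MRI
measures, and how does BAG relate to fluid/PET biomarkers and cognition?

Because the cohorts that motivate these analyses are restricted-access, the
package pairs every stage with a synthetic-cohort generator that reproduces
the *structure* of such data with known ground truth, so each estimator has
a parameter-recovery test surface.

## Pipeline model, stage by stage

### Slice aggregation and regression-dilution calibration

Per-slice CNN predictions are collapsed by the median (mean-of-middle-two
for even counts; the conventional 80-slice input is even-length and the
convention must be fixed somewhere, so it is fixed here). Raw predictions
regress toward the training mean ("regression dilution"), which would leave
controls with an age-dependent BAG. We fit ordinary least squares
`raw ~ age` in non-carrier controls (NC) only and invert the fitted map:

    corrected = (raw - alpha) / beta .

Two corrections are in circulation — rescaling, as above, and residualizing
`raw - (fitted - age)`. Both zero the NC age trend; we fix the rescaling
form because it is a true inverse of the fitted calibration line (a second
fit+apply is then exactly the identity, which is tested). "BAG" everywhere
downstream means `corrected - age` from calibration-corrected, harmonized
predictions, with no second residualization on age.

Performance metrics are always computed on *uncorrected* predictions — the
calibration is fit on the same controls and would flatter the model. `R2`
is defined against the identity line, `1 - SSE/SST` with errors taken from
`pred = true`, not as squared correlation: a model can rank ages almost
perfectly (r near 1) while missing them by a constant, and the pair (high r,
much lower R2) is only coherent under this convention.

Test–retest reliability uses ICC(A,1): two-way model, single measurement,
absolute agreement, with the standard F-based confidence bounds
(Satterthwaite denominator df). The retest generator constructs the second
visit as `m + rho*(y1 - m) + sd(y1)*sqrt(1-rho^2)*z`, which matches means
and variances across visits so that the population absolute-agreement ICC
equals `rho` and the two degenerate limits (`rho` of 1 and 0) are exact.

### Site harmonization (single-variable ComBat)

Multi-site acquisition adds non-biological location/scale differences to
predicted age. We use the ComBat model on the single harmonization target
(predicted age): estimate covariate effects and per-batch means jointly by
least squares, standardize residuals by the pooled SD (denominator
`n - rank(design)`, which makes the no-shrinkage adjustment exactly
idempotent), then shrink per-batch locations (normal prior) and scales
(inverse-gamma prior) by parametric empirical Bayes, iterated to a 1e-6
tolerance with a 200-iteration cap.

One design point differs necessarily from expression-array ComBat: with a
single variable there is no across-feature axis on which to estimate the
prior moments, so they are estimated *across batches* by the same
method-of-moments formulas. The property that matters is preserved: a small
batch with an extreme mean is shrunk toward the consensus harder than a
large batch with the same shift, and covariate-explained variance (age, sex,
education, mutation group, EYO, APOE e4, variant) is restored exactly after
adjustment. Harmonization is applied to brain-predicted age (site as the
batch variable), and BAG is recomputed afterwards; scanner model is checked
with Kruskal–Wallis tests before and after, and a sequential
site-then-scanner pass is available behind `then_scanner = TRUE` but is not
the default. Family membership is not included in the harmonization design.

### Trajectory GAMMs and simultaneous bands

The trajectory model is a penalized-spline GAMM fit by REML with `mgcv`:

    bag ~ carrier + s(eyo, by = carrier, k = 4, bs = "cr")
          + sex + education + apoe4 + s(family, bs = "re")

Separate cubic regression spline smooths (4 basis functions, knots at EYO
quantiles; penalty null space = linear functions) for carriers and
non-carriers, a carrier main effect, linear covariates, and a family random
intercept expressed as a penalized term. Smooth significance is reported as
EDF plus the Wald-type test with EDF-adjusted reference distribution from
`summary.gam`. Two exact limits anchor the implementation and are tested:
with the penalty off the fit equals least squares on the basis columns, and
with the EYO penalties forced to infinity it equals the linear mixed model
with carrier-specific slopes (verified coefficient-for-coefficient against
`lme4` at a matched variance ratio).

Group comparison uses simultaneous 83.4% confidence bands: per-group
intervals at that level have the property that non-overlap approximates a
two-group test at alpha of about 0.05. Bands are simulation-based: draw
10,000 coefficient vectors from the posterior `N(beta, Vp)`, take the
`level` quantile of the maximal standardized absolute deviation over the
grid as the critical multiplier `m`, and set the band to `fit ± m*SE`. `m`
is never below the pointwise normal quantile (1.386 at 83.4%), covariates
are held at reference values, and the family intercept is excluded so the
band describes the population curve. The earliest divergence EYO is the
first grid point from which the two bands fail to overlap *at every later
grid point* (sustained separation, suppressing isolated crossings, which the
underlying report convention leaves unstated). The primary grid step is
0.01 EYO.

The bootstrap comparison across measures resamples participants with
replacement, stratified by mutation group (family-level resampling is
available as an option), refits every measure per replicate, and records
each replicate's divergence EYO, censoring non-divergent replicates at the
grid maximum and counting them; a measure censored in more than half of
replicates is flagged and reported with a one-sided interval. Pairwise
p-values are `2*min(Pr(diff<0), Pr(diff>0))` over paired replicate
differences, ties split evenly. Inside the bootstrap, smoothing parameters
(including the random-intercept variance ratio) are held at their
full-sample REML estimates and only coefficients and random intercepts are
refit per replicate (`fix_sp = TRUE`, the standard bootstrap-smoothing
design; per-replicate re-estimation is available). Replicate-scale and
other repeated fits can use `bam(method = "fREML", discrete = TRUE)`, which
agrees with the exact-REML fit to about 3e-4 on fitted values at cohort
scale and is an order of magnitude faster; primary fits use exact REML.

### Associations, sensitivity and mediation

Group BAG differences use a tie-corrected Kruskal–Wallis omnibus plus all
pairwise two-sided Wilcoxon tests with Benjamini–Hochberg adjustment;
pairwise tests are exact-enumeration when the combined n is at most 20 with
no ties, normal approximation with tie/continuity correction otherwise.
Variance homogeneity uses the classic mean-centered Levene test. Biomarker
models are linear mixed models (family random intercept) with a
biomarker-by-group interaction; terms are tested by Wald F with
Satterthwaite denominator df and summarized by partial eta squared
`F*df1/(F*df1 + df2)` — the formula choice is documented rather than claimed
to match any particular software's output. Log-transform sensitivity refits
everything on the natural-log scale and requires strictly positive inputs.
Effect size for the symptomatic-vs-NC contrast is pooled-SD Cohen's d with a
normal-approximation CI.

Mediation (biomarker -> BAG -> cognition) uses two nested least-squares
models, so total = direct + indirect holds exactly, with a percentile
bootstrap CI for the indirect path from participant resamples. Covariates
enter both sub-models. Family clustering is ignored inside the mediation
bootstrap by default (the cited nonparametric method resamples
observations); a family-resampling option exists. "Partial mediation" is
declared when the indirect CI excludes zero while the direct path remains
significant.

## The synthetic cohort: what it emulates, and what it does not

Defaults mirror the structure of a large multi-site ADAD observational
cohort: 179 NC / 183 asymptomatic-carrier /
74 symptomatic-carrier participants; NC age 37.5 (10.6); carrier EYO drawn
per group (asymptomatic -14.3 (9.0), symptomatic 1.4 (5.7)) with age induced
as family onset + EYO; 15 sites and 9 scanner models with additive site
shifts (SD 1.5 y) and multiplicative scanner factors (log-SD 0.02); Poisson
family sizes (mean 3) mixing carriers and non-carriers, one mutation
variant, one onset age and one random intercept (SD 2 y) per family; sex
offset +3.15 y (male - female); education slope -0.38 y per education year;
prediction noise SD 5 y, chosen so the implied NC BAG spread (~6 y) matches
what an age-prediction accuracy of r ≈ 0.8 at age SD ≈ 10.6 implies.

The carrier trajectory is zero until `divergence_eyo` (default -7) and then
a quadratic ramp, continuously differentiable at onset, scaled so its mean
over the symptomatic EYO distribution is `sym_elevation` (default 13.4 y) —
smooth enough for a k = 4 spline to track, while the true functional form in
real cohorts is unknown. Biomarkers are lognormal (so log-sensitivity always
has valid inputs) and acquire their within-group correlations with true BAG
through a shared latent severity variable; the targets are imposed — and
therefore recovered — on the log scale, with raw-scale attenuation below
0.05 at the log-SDs used. CDR is assigned deterministically from group
(symptomatic carriers have CDR > 0), mirroring how the groups are defined
clinically.

Not emulated: longitudinal within-person trajectories (only a single
test–retest pair), plateauing of late-stage decline (the ramp keeps
rising), dropout/missingness mechanisms, variant-specific trajectory
shapes, and any image-level structure. A single onset age per family is an
explicit simplification; real mutation-specific onset distributions within
families are not modeled. Passing parameter-recovery tests therefore shows
the estimators are correct under a realistic covariance/clustering
structure — not that real trajectories follow a quadratic ramp.

### Detection lag: why the divergence estimate trails the generative onset

Band non-overlap declares divergence where the group separation exceeds the
*joint* uncertainty of two fitted curves, so for a trajectory that leaves
zero with zero slope, the earliest detectable EYO is structurally later
than the generative onset: with ramp scale `c`, detection occurs roughly at
`onset + sqrt(gap/c)` where `gap` is the sum of the band half-widths. At
the default conditions (c ≈ 0.13, gap of 2-4.5 y) that lag is 4-6 EYO
years, and it shrinks only with the square root of the noise level. The
package's validation therefore treats the divergence estimate as what it
is — the earliest *statistically demonstrable* separation, not the
biological onset — and the corresponding recovery check against the
generative onset fails by design at realistic noise. Conversely, on real
data a detected divergence at some EYO implies the underlying trajectories
separated earlier.

## Numerical choices

- Pooled SD in ComBat standardization uses the residual df
  (`n - rank(design)`); EB updates iterate to 1e-6, cap 200.
- Degenerate inputs are defined, not errors, where a value is natural:
  all-tied Kruskal–Wallis returns H = 0, p = 1; all-zero Levene deviations
  return W = 0, p = 1; perfect-agreement ICC returns 1 with a [1, 1]
  interval.
- Identical-median slice sets: even-length medians use mean-of-middle-two.
- Every stochastic stage takes a seed; the pipeline derives stage seeds from
  one master seed, records them in the manifest, and is byte-reproducible.
- Bootstrap grids clip to each replicate's observed EYO range; replicate
  bands default to 0.1-0.2 EYO steps and 400-1000 posterior draws, the
  primary analysis to 0.01-0.02 steps and 10,000 draws.

## Validation problem sizes

The shipped test suite runs the generator-based checks at desk scale chosen
by the package: calibration/ICC oracles at n of a few hundred (tolerances
1e-8 to 1e-10); harmonization removal over 100 seeded replicates (n = 250,
10 sites) and covariate preservation at n = 2,000; band coverage over 500
simulated curves (n = 250); divergence recovery over 50 seeds at n = 450;
bootstrap comparisons with 500 replicates in 10 (calibration) and 5 (power)
meta-replicates at n = 600; association calibration over 200 null seeds and
100 power seeds at n = 402; mediation recovery at n = 400. The full-scale
analysis (10,000 bootstrap replicates, 0.01 grids) is available through the
same interfaces.

## Known limitations

- The divergence estimator inherits the detection-lag property above; its
  bootstrap distribution quantifies sampling variability, not that lag.
- Single-variable ComBat with across-batch priors is the appropriate
  reduction for one measure, but it cannot borrow strength across features
  the way image-level ComBat does.
- Approximate p-values for penalized smooths are known to be slightly
  liberal or conservative depending on regime; they are reported as such.
- The mediation model is linear with exogenous exposure; no
  exposure-mediator interaction is modeled.
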