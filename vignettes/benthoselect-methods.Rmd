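---
title: "Habitat and movement selection over a classified benthoscape: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat and movement selection over a classified benthoscape: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Fine-scale acoustic positioning arrays can resolve the movements of benthic
animals — lobster in the motivating application — to a few metres, every few
minutes, over a mapped mosaic of seabed substrates (a *benthoscape*). Two
questions follow: which substrates does an animal preferentially occupy, and
how does its movement change with the substrate it is on? `benthoselect`
implements the full chain from raw position fixes to answers: positioning
quality control, track regularization, a resource selection function (RSF),
and an integrated step-selection function (iSSF), together with a synthetic
data generator so that every stage can be validated by recovering known
parameters.

The benthoscape carries five named substrate classes (codes 0–4) plus a
distinct `nodata` level for unmapped cells. `nodata` is treated as an
ordinary categorical level throughout, because animals do use unmapped
areas and their selection of such areas is a reportable quantity. The
reference level for all selection contrasts is `silt_mud_gravel`
("silt/mud with ≤ 50% gravel"), chosen as in the motivating study because
it is scarce but used by every individual; it is configurable.

## Positioning quality control

Each calculated position carries a unitless horizontal position error
sensitivity score (HPE); stationary synchronization tags at known
locations additionally yield the measured error in metres (HPEm). The QC
protocol is:

1. **Candidate cut-offs.** Per receiver deployment, `candidate_cutoff()`
   finds the lowest *observed* HPE retaining at least 95% of sync
   positions. Candidate selection uses `≤` (a retention statement).
2. **Error reports.** `cutoff_report()` filters sync fixes at a candidate
   and reports the median, 90th and 95th percentiles of HPEm, using
   linear interpolation between order statistics (R's type-7 quantile).
   The percentile convention is stated because conventions differ and the
   choice affects the digits reported.
3. **Final filter.** The final cut-off is a *human* decision balancing
   confidence against data loss; the package takes it as configuration
   (default 25) and applies it strictly (`HPE < cutoff`), together with
   removal of everything within 48 h of each tag's release. Fixes whose
   tag has no release time are an error, never silently kept.

Candidates are computed from sync tags by default; computing them from all
fixes is available, as the aggregation population is ambiguous in general.

## Track preparation

Filtered fixes are regularized to a 10-min rate with a greedy rule: keep
the first fix; from each kept fix, keep the earliest later fix whose gap
falls in `rate ± tolerance` (default 600 ± 120 s); when the gap exceeds
the window, close the burst and restart. The tolerance and the burst rule
are declared package conventions — a fixed-rate statement alone does not
determine them. Steps connect consecutive kept fixes; the turning angle is
the change in bearing wrapped into `(-π, π]`, counter-clockwise positive
(only `cos(ta)` enters any model, so the sign convention is inert but
fixed). Steps with non-finite `log(sl)` and steps without a defined
turning angle are filtered with per-reason counts. Substrate is sampled at
step *endpoints* only; cells crossed mid-step are ignored.

## The RSF with subsample refits

The use–availability model is a logistic regression of presences against
pseudo-absences with substrate class as the fixed effect and individual as
a random intercept. Pseudo-absences are drawn uniformly inside each
individual's minimum convex polygon of presences (10 per presence by
default); an explicit array polygon can be used instead. Because
consecutive positions are strongly autocorrelated, the model is refit 100
times on random subsets — by default 100 presences *and* 100
pseudo-absences per individual per rerun, sampled without replacement —
and the spread of the 100 exponentiated coefficients (relative selection
strengths, RSS) carries the uncertainty. The subset wording is ambiguous
between "100 of each" and "100 presences plus their 10× absences"; both
are implemented (`scheme = "equal"` is the default) and the class
coefficients agree between them because the use:available ratio only
shifts the intercept in this framework. Classes whose interquartile range
spans RSS = 1 are flagged as showing no clear selection.

Pseudo-absences are drawn once and subsampled per rerun; a class
represented only among presences or only among absences in a given
subsample is quasi-separated (its coefficient is infinite), so the rerun
omits that class and a count of skipped reruns is reported.

The random-intercept logistic likelihood is maximized with an in-package
Laplace approximation: for a candidate variance, fixed effects and group
modes are found by penalized Newton (IRLS with a ridge on the group
intercepts), and the profile of the Laplace objective over the log SD is
maximized in one dimension. This matches `lme4::glmer` to about two
decimal places on the fits used here (cross-checked in tests).

## The iSSF

For each individual: a *tentative* movement kernel — gamma step lengths,
von Mises (mean 0) turning angles — is fitted to the observed steps by
maximum likelihood. Each observed step with a defined turning angle then
anchors a stratum of 1 observed + 100 random steps sharing the start
point, the random ones drawn from the tentative kernel about the previous
bearing. The conditional logistic model is

    case ~ end_class + log(sl) + cos(ta)
         + start_class:log(sl) + start_class:cos(ta)  (stratified)

Start-class *main* effects are intentionally absent: they are constant
within a stratum and hence inestimable under the conditional likelihood.
The fit is by Newton–Raphson on the analytic conditional score with step
halving; coefficients passing |15| raise a separation error naming the
term instead of diverging silently. Uncertainty comes from a stratum
bootstrap (1000 replicates by default): strata are resampled with
replacement and the model refit, implemented as a weighted fit with
multinomial stratum counts (exactly equivalent to duplicating strata, but
without materializing rows). Replicate means and SDs are reported per
term; more than 20% non-converged replicates is an error flagging an
unstable fit. Both Wald and bootstrap-percentile intervals are emitted,
since either convention is defensible for the per-individual summaries.

Movement coefficients update the tentative kernel per start class: the
gamma shape gains the `log(sl)` coefficient (plus the class interaction),
the von Mises concentration gains the `cos(ta)` coefficient (plus its
interaction). A non-positive corrected shape or negative concentration is
flagged invalid rather than clipped. `interpret_estimates()` renders the
standard sign reading: negative `cos(ta)` interactions mean more turning
(lower directionality) on that substrate, negative `log(sl)` interactions
mean shorter steps (more residency), and end-class RSS above 1 means
selection over the reference.

**Identifiability floors.** A class reached by fewer than 5 observed step
ends, or a start class occurring in fewer than 5 strata, cannot support a
stable coefficient: its conditional MLE is infinite or its bootstrap
degenerates. Such levels are flagged inestimable and excluded from the
design — the analogue of the empty cells in per-individual results tables
— rather than being allowed to crash the fit or to contribute estimates
with SDs an order of magnitude larger than the estimate. Individuals with
fewer than 20 usable strata are refused entirely.

## The synthetic positioning system

The generator provides ground truth for every stage:

* **Benthoscape**: white noise smoothed with a Gaussian kernel at a patch
  scale (default 10 m), thresholded at the quantiles of the target class
  proportions, so realized proportions track the targets while classes
  form spatial patches. Deterministic given the seed.
* **Tracks**: the iSSF's own generative model run forward. At each step,
  20 candidate displacements are drawn from the movement kernel and one
  is chosen with probability proportional to `exp(β[end class])`.
  Out-of-bounds proposals are redrawn; if a step exhausts its retries the
  animal holds position, avoiding reflecting-boundary bias at the cost of
  slight edge attraction.
* **Observation**: transmissions at cumulative uniform 120–240 s
  intervals, linear interpolation of the true position, Bernoulli
  detection (default 0.85), and an isotropic bivariate normal error with
  per-fix scale `σ_i = σ₀·exp(N(0, s))` — a continuous, heavy-tailed
  log-normal scale mixture. HPE is generated as `a·σ_i·exp(N(0, τ))`:
  monotone in expectation with the true error but noisy, because the QC
  procedure is only meaningful when HPE is an imperfect proxy.
* **Sync tags**: stationary grid positions observed through the same
  model, with `HPEm = |observed − true|` exact.

Calibration: with `s = 0.6`, the median of `σ_i·R` (R a unit Rayleigh) is
approximately `1.177·σ₀`, so `σ₀ = 2.04` m puts the median positional
error at ≈ 2.4 m, the design accuracy of the motivating array. `a = 10`
puts HPE values on the familiar tens scale, and `τ = 0.35` yields a
Spearman correlation between HPE and HPEm of about 0.6 on sync fixes —
informative but far from perfect, as in real systems. These values were
fixed once from these considerations. The generator does *not* emulate
receiver-level detection geometry, multilateration artifacts (position
error is isotropic and unimodal per fix), tides, or tag loss; passing
tests therefore demonstrate correctness of the estimators under the
stated model, not robustness to every field pathology.

## Numerical choices

* Gamma MLE: Newton on the digamma profile equation, Minka-style
  initialization, gradient tolerance 1e-10; exact on analytic sufficient
  statistics to 1e-8.
* von Mises MLE: inversion of `A(κ) = I₁/I₀` with scaled Bessel
  functions; negative mean cosine gives κ = 0; κ capped at 500 for
  degenerate all-equal-angle samples. Sampling uses the Best–Fisher
  wrapped-Cauchy envelope.
* Conditional logistic Newton: log-sum-exp stabilization engages only
  when linear predictors become extreme; convergence at gradient < 1e-6
  and step < 1e-9; ridge fallback on a singular information matrix.
* Raster cells are half-open intervals, so edge points belong to exactly
  one cell; the internal row order is south-up, converted at file
  boundaries (ESRI ASCII grids and single-band 8-bit TIFF with an ESRI
  world file; nodata encoded as −9999 and 255 respectively).
* The unsupervised classifier is k-means with k-means++ seeding, Lloyd
  iterations to an assignment fixpoint, and empty clusters reseeded from
  the farthest point. The split/merge heuristics of classical ISODATA and
  object-based segmentation are out of scope. Cohen's kappa is reported
  as a proportion in [−1, 1].

## Problem sizes used in validation

The test-suite study conditions are scaled so the whole suite runs on one
CPU in well under half an hour while leaving the statistical checks
informative: parameter recovery uses 12 replicates of 3 individuals ×
800 steps with 25 random steps per stratum and 200 bootstrap replicates;
null calibration uses 50 single-individual replicates of 600 steps on a
three-class benthoscape; RSF recovery uses 4 individuals × 250 presences
under the full 100 × 100 subsample-refit scheme; kernel MLE checks use
100,000 draws. The pipeline defaults remain the full-scale settings (100
random steps, 1000 bootstrap replicates, 100 × 100 reruns). The bundled
demo scenario tracks 4 animals for 100 h so that the 48-h post-release
window still leaves ample data, with stage sizes reduced for a fast desk
run.

## Known limitations

* The RSF's subsample refitting mitigates — it does not model — spatial
  and serial autocorrelation; no explicit autocorrelation structure is
  fitted.
* Consecutive iSSF strata share endpoints, so replicate draws are not
  fully independent; the stratum bootstrap treats them as exchangeable,
  which is the standard practice the package follows.
* The printed iSSF formula corrects the gamma shape (via `log sl`) but
  not the scale (no plain `sl` term); kernel updates inherit this
  restriction.
* Population-level pooling across individuals, continuous-time movement
  models, and step-length families other than the gamma are out of scope.
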