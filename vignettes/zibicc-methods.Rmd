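---
title: "Rater reliability for zero-inflated bounded ratings: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rater reliability for zero-inflated bounded ratings: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zibicc)
```

## The measurement problem

Therapists rating compensatory movement from video produce data that defeat
the classical reliability toolkit. Each rating is a slider score on
[0, 100] (0 = no compensation, 100 = highest possible compensation), given
per movement phase of a standardized drinking task (reaching, forward
transport, drinking, back transport, returning) and per movement direction
(trunk, shoulder, elbow, forearm, wrist, grasp, plus two global
movement-quality judgements: smoothness and interjoint coordination).
Because the filmed individuals are only mildly to moderately impaired, a
large share of ratings is exactly 0, and the positive ratings crowd the
lower third of the scale. ANOVA-based intraclass correlations (ICCs) assume
approximately normal, homoscedastic scores; a point mass at zero plus a
bounded right-skewed continuum breaks both assumptions.

`zibicc` instead models a phase-level score $y \in [0, 100]$ as a
zero-inflated beta mixture,

$$P(y = 0) = \pi, \qquad
  \frac{y}{100}\,\Big|\,y > 0 \sim \mathrm{Beta}\!\big(\mu\phi,\,
  (1-\mu)\phi\big),$$

with the beta mean on the logit scale decomposed into crossed random
effects,

$$\mathrm{logit}(\mu_{rvt}) = \mu_0 + a_v + b_r + c_{rv} + e_{rvt},$$

where $a_v \sim N(0, \sigma^2_v)$ is video severity,
$b_r \sim N(0, \sigma^2_r)$ rater bias, $c_{rv} \sim N(0, \sigma^2_{rv})$
rater-by-video consistency, and $e_{rvt} \sim N(0, \sigma^2_e)$ an
observation-level (one per rater-video-round cell) effect that carries the
round-to-round, test-retest noise. The model is sampled by MCMC (JAGS),
and reliability is a posterior functional of the variance components:

$$\mathrm{ICC}_\text{inter} =
  \frac{\sigma^2_v}{\sigma^2_v + \sigma^2_r + \sigma^2_{rv} + \sigma^2_e},
  \qquad
  \mathrm{ICC}_\text{intra} =
  \frac{\sigma^2_v + \sigma^2_r + \sigma^2_{rv}}
       {\sigma^2_v + \sigma^2_r + \sigma^2_{rv} + \sigma^2_e}.$$

Each ratio is evaluated draw by draw, so the posterior median and the
equal-tailed 95% credible interval of the ICC come for free, and both
reliability targets reuse one fitted model per phase.

### Why an observation-level logit effect

A beta likelihood has no free residual variance: its dispersion is
mean-dependent, $\mathrm{Var}(y') = \mu(1-\mu)/(1+\phi)$, and cannot be
entered into a variance ratio against the logit-scale components. The
explicit observation-level effect $e_{rvt}$ gives the test-retest noise a
well-defined variance on the same (logit) scale as the other components,
which is what makes the intra-rater ICC a coherent ratio. The price is a
weakly identified ridge between $\sigma^2_e$ and $\phi$ (both absorb
overdispersion); see the convergence notes below.

### Scale of the ICC

The ICCs above live on the latent logit scale. A response-scale
(observed 0-100 values, zeros included) analogue is available through the
generator's Monte-Carlo oracle `true_icc_response()`; the two scales agree
in ordering but not numerically, because zeros and the logistic
transform compress the observed correlations. The latent scale is the
default because the variance components literally are the model's random
effects; the report metadata records the convention.

### Interpretation thresholds

Point estimates are labelled on the Koo & Li scale with left-closed
intervals: below 0.5 poor, [0.5, 0.75) moderate, [0.75, 0.90) good, and
[0.90, 1] excellent. The verbal scale as commonly quoted overlaps at the
boundaries (0.75 appears in both "moderate" and "good", 0.9 in both
"good" and "excellent"); the left-closed convention resolves the overlap
deterministically and is recorded in every report.

## Priors, boundary handling and numerical choices

* **Priors.** Half-normal(0, 1) on each variance-component standard
  deviation, normal(0, 2.5) on the two intercepts (logit scale),
  exponential(0.5) on $\phi$. On a logit scale bounded data rarely support
  standard deviations above ~2, so these are weakly informative without
  being flat.
* **Boundary squeeze.** Positive scores are mapped into the open unit
  interval by $y' = (y/100)(1 - 2\varepsilon) + \varepsilon$ with
  $\varepsilon = 10^{-4}$ by default. This is the standard beta-regression
  device for boundary observations; it means a score of exactly 100 is
  handled by the squeeze rather than by a one-inflation component
  (observed ratings concentrate low, so one-inflation has nothing to
  model). The squeeze is a change of variables, so the continuous density
  loses the $\varepsilon$-tail mass of the beta; with both shape
  parameters $\geq 1$ that loss is $O(\varepsilon)$, while shapes $< 1$
  (a boundary singularity) can lose more - the density checks in the test
  suite therefore run on shapes $\geq 1$.
* **Zero-inflation structure.** Intercept-only by default. With only 7
  videos, random effects in the zero logit are barely identifiable; a
  flag (`zero_random_effects`) enables a shared loading on the stable
  effects for users with richer designs.
* **Degenerate inputs.** All-zero score tables are rejected with an
  explicit error (the beta component has no data). ICC draws with an
  all-zero denominator are excluded and counted; more than 10% such draws
  is an error rather than a silent answer.
* **Sampler defaults.** 4 chains, 1000 warmup + 1000 kept draws each,
  seed-deterministic JAGS RNG streams, split-$\hat R$ threshold 1.01.
  Heavier settings (3 chains, 3000 warmup + 2000 kept) are used in the
  calibration studies shipped with the tests.

### Convergence in practice

The $\sigma^2_e$-$\phi$ ridge mixes slowly: at routine chain lengths their
split-$\hat R$ often sits in the 1.05-1.5 range while the video and rater
components converge quickly, and the overall intercept drifts against the
mean of the observation-level effects. Fits flag themselves not converged
(with a warning) whenever any parameter exceeds the threshold; the ICC
ratios are much better behaved than their ingredients because the ridge
moves probability mass along directions that largely cancel in the
ratio. For final inferences, run longer chains until the flag clears or
inspect `convergence_report()`.

## What the generator emulates - and what it does not

`simulate_ratings()` reproduces the *statistical shape* of therapist
compensation ratings: heavy zero inflation (the default preset gives
roughly 60% exact zeros, between the per-phase concordant-zero rates
observable in such studies), positive scores concentrated in the lower
third of the scale, distinct video severities, rater bias, rater-by-video
consistency, round-to-round noise, and not-assessable flags that
concentrate on wrist/hand items during the drinking phase (face
anonymisation hides the hand near the face) and correlate across rounds.
Zeros are more likely for mildly affected videos through a shared loading
(`zero_effect_scale`) on the zero-inflation logit.

It deliberately does not emulate: phase-specific severity (the latent
model has no phase effect, matching the per-phase analysis), item-level
random effects (items within a phase share the cell latent, since the
analysis averages items per phase), rater demographics, or any real
video's severity profile. Global movement-quality items instead carry an
attenuated video effect (`global_video_scale`), reflecting that global
judgements separate videos less well - this is what makes their simulated
reliability poor, mirroring the qualitative finding for smoothness and
interjoint coordination. Passing tests on simulated data therefore
demonstrate that the pipeline recovers known structure of this shape; they
cannot certify any particular clinical dataset.

### Variance targeting in calibration studies

With only 7 videos, the realized sample variance of 7 simulated video
effects follows $\sigma^2_v \chi^2_6 / 6$ - a coefficient of variation
near 58%. A replicate whose realized video spread is half the nominal
value genuinely has lower reliability than nominal, and no estimator can
report 0.8 from such data. Calibration studies that want to measure
*estimator* accuracy rather than this design noise can set
`variance_targeting = TRUE`, which rescales each realized effect vector to
exactly its nominal variance (the same idea as
`MASS::mvrnorm(empirical = TRUE)`). The shipped recovery study does so:
at the study scale (22 raters x 7 videos x 2 rounds, true inter-rater ICC
0.8) it requires the posterior median within ±0.1 and the truth inside
the 95% interval in at least 8 of 10 replicates. The default is `FALSE`
because realistic data has no such luxury.

### Problem sizes used by the shipped studies

The recovery study runs 10 replicates of a single-phase design
(22 x 7 x 2 = 308 scores per fit; the single-item schema makes the fitted
likelihood exactly the generative one) with 3 chains x (3000 warmup +
2000 kept) draws. Secondary simulation checks (zero-free data, null video
variance) use 5-10 raters and 3-5 videos with shorter chains. Monte-Carlo
oracles use 20,000-50,000 simulated videos.

## Study-design arithmetic

Precision-based planning uses Bonett's variance approximation for an ICC
from `n` subjects and `k` ratings per subject,

$$\mathrm{Var}(\hat\rho) \approx
  \frac{2(1-\rho)^2\big(1+(k-1)\rho\big)^2}{k(k-1)(n-1)},$$

with the videos as subjects and the rater panel as the ratings - with the
video count fixed by the available recordings, the panel size is the free
variable. `required_raters()` scans `k` upward and returns the first value
whose approximate 95% interval width meets the target. For an expected
ICC of 0.85, a width of 0.3, $\alpha = 0.05$ and 7 videos this gives
k = 18 (achieved width 0.2998); the width has a large-`k` floor of
$2z\sqrt{2}\,\rho(1-\rho)/\sqrt{n-1} \approx 0.289$ at these inputs, so
nearby variants of the same calculation (slightly different variance
denominators or rounding of the two rating occasions) land anywhere in
the 18-20 range. The package pins its own convention and verifies it
against a brute-force search in the tests rather than chasing any
particular published panel size. Dropout inflation is multiplicative with
ceiling, $n_\text{recruit} = \lceil n(1+r)\rceil$, so a 20-rater panel at
25% redundancy recruits 25.

## Open choices made here

* **Credible intervals** are equal-tailed (2.5%/97.5% quantiles), the most
  common reading of a 95% credible interval; highest-density intervals
  would be narrower for the skewed ICC posteriors but are not what "95%
  probability inside the interval" usually denotes in reliability tables.
* **Intra-rater pooling**: one model per phase with all raters, the
  intra-rater ICC taken from the pooled components, rather than per-rater
  fits - 7 videos per rater cannot support 22 separate models.
* **Global domains** are pooled by averaging the item over the 5 phases
  per (rater, video, round) before fitting, consistent with treating the
  55-field sheet as 5 x 11 with the global items rated once per phase.
* **Phase means exclude the global items** by default: they are reported
  as separate overall domains, and including them would double-count
  their information.

## Known limitations

* The intercepts and $\phi$ mix slowly (see above); treat their posterior
  summaries, and any non-converged fit, with caution.
* The latent-scale ICC is not numerically comparable to ANOVA ICCs on raw
  scores; use `true_icc_response()` or the naive `icc_anova()` (didactic
  only) when a response-scale number is needed.
* With 7 videos the video-variance posterior - and hence every ICC - has
  wide credible intervals no matter how many raters rate; that is a
  property of the design, not of the estimator.
* The generator's preset magnitudes are calibration choices, not
  estimates from any clinical dataset.
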