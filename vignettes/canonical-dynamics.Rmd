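---
title: "Canonical BOLD dynamics, episode decoding, and cortico-hippocampal coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical BOLD dynamics, episode decoding, and cortico-hippocampal coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navdyn)
```

## The problem

When many people watch the *same* one-minute first-person navigation video,
the region-averaged BOLD time course of a visual or spatial-processing region
unfolds in a highly similar way across individuals. `navdyn` analyses this
shared temporal structure. Its core quantity is the
**individual-to-canonical similarity (ICS)**: for participant $i$, region $k$,
and episode $e$, the Pearson correlation between $i$'s 26-frame navigation
segment and the *canonical dynamics* of that region/episode — the frame-wise
average over all other participants (leave-one-subject-out) — Fisher
Z-transformed:

$$\mathrm{ICS}_{i,k,e} = \operatorname{artanh}\,
  r\!\left(y_{i,k,e},\ \tfrac{1}{n-1}\textstyle\sum_{j \ne i} y_{j,k,e}\right).$$

Everything else in the package is built on this primitive:

* **Episode decoding** — correlate one segment against all 24 canonical
  templates; predict the argmax; chance is $1/24 = 0.041\overline{6}$.
* **Event regression** — regress the concatenated canonical dynamics of region
  $k$ on HRF-convolved angular velocity (turning) and HRF-convolved
  landmark-viewing status: $Y_k = \beta_1 X_1 + \beta_2 X_2 + i + e$, all
  variables z-scored.
* **Intersubject functional connectivity (ISFC)** — correlate an individual's
  *hippocampal* dynamics with the leave-one-out canonical dynamics of each of
  the 44 cortical targets, Fisher-Z, averaged over episodes on the Z scale.
* **Brain–behaviour statistics** — motion-partialled correlations between ICS
  (or ISFC, or average activation) and spatial-memory performance; the age
  regression $\mathrm{ICS} = a\,\mathrm{Age} + b\,\mathrm{Motion} + c + e$
  with the VIF for age; and a three-equation mediation of the age-related
  performance decline by MTL coupling, tested with the Sobel $z$.

Because the package cannot ship scanner data, the first-class
`synthetic_cohort` module generates a complete study with known ground truth,
so that every analysis stage has a recovery test.

## The generative model

`simulate_cohort()` draws everything from named substreams of one master seed
(design / streams / motion / coupling / bold / gaze / behavior / mediator), so
stages regenerate independently and reruns are bit-identical.

**Design.** 76 participants by default (45 aged 20–30, 31 aged 50–65, ages
truncated normal per group), 24 episodes = 4 cue conditions × 6, dealt evenly
into 4 runs of 6 trials. Each 102-s trial: 8 s fixation, 8 s map, 60 s
navigation, 8 s fixation, 4 s map, 10 s question, 4 s padding — all phase
boundaries on the 2-s frame grid.

**Event streams** (10 Hz, 60 s): angular velocity is a sum of 4–8 half-cosine
turn bumps, 1–3 s wide, onsets ≥ 2 s apart, zero during the stationary first
and last 2 s. Nothing constrains the exact velocity profile, so the bump
shape is a modelling choice; only its timing matters downstream. Episodes in
the two local-landmark conditions also carry a latent gaze-on-landmark ratio
(2–4 smooth bumps); other conditions have an identically zero ratio.

**Canonical dynamics.** For region $k$ the ground-truth canonical signal is

$$g_{k,e}(t) = \beta_1^{(k)}\,\tilde X_1(t) + \beta_2^{(k)}\,\tilde X_2(t)
  + \sigma_k \left(\sqrt{\rho}\,L_e(t) + \sqrt{1-\rho}\,L_{e,k}(t)\right),$$

where $\tilde X_1,\tilde X_2$ are the standardized HRF-convolved turning and
landmark-viewing streams, the $L$ terms are episode-specific smoothed
Gaussian latents (white noise smoothed with a 4-s-FWHM Gaussian kernel —
wide enough to be BOLD-plausible, narrow enough that each episode's dynamics
are unique and decoding is non-trivial), $\rho$ (default 0.3) is shared across
regions so that ISFC has signal, and
$\sigma_k = \sqrt{1 - \beta_1^2 - \beta_2^2}$ makes $g$ unit-variance. That
normalization is what lets a standardized fit of the canonical dynamics
recover $(\beta_1, \beta_2)$ directly. Note a deliberate modelling choice: the
landmark term is driven by the *thresholded* landmark-viewing status (the
top-20% mask of the latent ratio), i.e. exactly the regressor the analysis
uses, so the generative and analysis models are the same model.

**Individuals.** Participant $i$'s navigation segment in region $k$ is
$w_{ik}\, g_{k,e} + \sqrt{1-w_{ik}^2}\,\varepsilon$ with unit-variance noise,
so $w_{ik}$ *is* the expected correlation with the ground-truth canonical
signal. Baseline weights per region are tuning constants chosen to land mean
ICS in the empirically typical 0.02–0.22 band (highest in dorsal/ventral
visual regions, lowest in the hippocampal formation); they are not estimates.
On top of the neural signal the generator adds phase-specific means, slow
cosine drift, a motion artifact shared across regions (removed by confound
regression), and region-idiosyncratic motion-locked noise (which survives
confound regression — this is what makes head motion a genuine confound of
ICS), and converts to raw scanner units around a baseline of 800.

**Motion.** Six rigid-body parameters per run as AR(1) walks with occasional
spikes. The participant-level innovation scale is linear in standardized age
(`motion_gamma` 0.285) with noise (SD 0.5), targeting the cohort age–FD
correlation near 0.49; framewise displacement uses the Power convention
(sum of absolute backward differences, rotations scaled by a 50-mm sphere).

**Behaviour and mediation.** The latent mediator is
$M = a\,z(\mathrm{age}) + \sqrt{1-a^2}\,\epsilon$; it shifts the alignment
weight of the two MTL regions (hippocampal formation, parahippocampal region)
by `w_med_scale` $\times M$ and drives latent performance
$P = c' z(\mathrm{age}) + b M + \epsilon'$, with residual variances chosen so
$(a, b, c')$ are exactly the standardized paths a mediation fit estimates.
Defaults $a=-0.318$, $b=0.313$, $c'=-0.598$ give indirect effect
$ab = -0.0995$ and total effect $c = -0.697$, the internally consistent values
the study design implies. Trial correctness is Bernoulli through a logistic
link (mean accuracy ≈ 0.69), with 2% missing responses scored as incorrect.

## Signal conditioning

Exactly three run-wise steps, in a fixed stage order (`raw → psc → cleaned →
zscored`, enforced): percent signal change about the run mean; OLS residuals
on 30 confound columns (6 motion parameters, backward-difference derivatives
with the first frame zeroed, squares, squared derivatives; framewise
displacement; the 5 lowest non-constant DCT-II basis columns) plus intercept;
and z-scoring (sample SD, $n-1$). Degenerate regions raise errors rather than
propagating NaN; a rank-deficient confound matrix falls back to the
pseudo-inverse with a warning (this happens, for instance, with identically
zero motion). Trial windows: 30 navigation frames, of which the first 4 are
discarded for the hemodynamic delay (26 retained); baselines are the last 2
frames of each of the two fixation phases. Misaligned onsets are an error,
never rounded.

## Numerical and inferential choices

* **Fisher-Z clipping** at $|r| = 1 - 10^{-7}$ keeps perfect correlations
  finite (relevant only in noise-free tests).
* **Decoding ties** break deterministically toward the lowest episode index
  and are flagged.
* **Permutation nulls.** The decoding null permutes the episode labels of the
  canonical templates; its null accuracy has mean $1/24$ and the test is
  calibrated. For mean ICS, the obvious-looking null — keep the templates
  fixed and pair them with segments of mismatched episodes — turns out to be
  *anticonservative by construction*: matched leave-one-out correlations
  within an episode contain each other's segments at weight
  $\sim 1/\sqrt{n-1}$, giving them pairwise covariance
  $\approx 1/((n-1)\,T)$ over $T$ frames and making the matched mean's
  variance about twice the mismatched-pair null's at any cohort size
  (measured type-I ≈ 0.15 at $\alpha = 0.05$). The default strategy
  therefore re-labels every participant's episodes per replicate and
  *recomputes the templates* before taking the matched mean; under the global
  null the observed labelling is exchangeable with the permuted ones and the
  measured type-I rate is at the nominal level. The template-fixed pairings
  remain available (`strategy = "same_participant"` / `"any_participant"`)
  for comparison. All permutation p-values use the one-sided add-one
  estimator, so they are never zero.
* **Pearson p-values** use the exact equivalence
  $t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ df, which integrates the null
  density $f(r) = (1-r^2)^{(n-4)/2} / B(\tfrac12, \tfrac{n-2}{2})$; the test
  suite verifies agreement with direct numeric integration to $10^{-6}$.
  Partial correlations keep $n$ = participant count (no df correction for the
  motion regression), which is slightly anti-conservative and is the
  documented convention here.
* **Sobel test** uses the classic two-term standard error
  $\sqrt{a^2\mathrm{SE}_b^2 + b^2\mathrm{SE}_a^2}$ and a two-tailed normal
  reference; it is conservative under the null (measured type-I ≤ 0.05 at
  $n=76$). Candidate regions for mediation require $a < 0$ with $p < 0.05$
  in the mediator model (a config flag; the full table is always available).
* **Landmark threshold**: strict `>` at the type-7 80th percentile, so
  tie-free series mark exactly 20% of samples; all-tied series mark none.
* **Regressor sampling** happens at frame onset after causal convolution on
  the 10-Hz grid (a frame-midpoint offset is available via the `offset`
  argument).
* **ISFC averaging** happens on the Fisher-Z scale, and a hippocampal seed
  excludes both hemispheres of its own bilateral region (44 targets). Seeds
  can be analysed per hemisphere or jointly (profiles averaged across the two
  seed labels).

## What the tests do and do not show

The synthetic cohort reproduces the statistical *structure* the analyses
assume — shared episode-locked dynamics, age-correlated motion that inflates
ICS differences, an MTL-coupling mediator of the age–performance decline —
at region-series level. It does not emulate voxel-space imaging, vascular or
baseline-signal aging effects, vestibular/active navigation, or realistic
autocorrelated physiological noise; passing tests certify the estimators and
their calibration, not any empirical claim about real cohorts.

Two measurement-chain properties are worth knowing. First, recovering the
event-model couplings is exact against the generator's canonical dynamics
(the recovery suite uses 20 cohorts and a ±0.05 band), but the full chain —
run-wise conditioning, then cohort-averaged canonical estimates — attenuates
the landmark coefficient somewhat, because the per-run confound regression
(intercept + 5 smooth DCT columns against 6 trials) absorbs part of the
between-episode mean structure; an analysis of real data with this pipeline
shares that property. Second, measured ICS is a noisy monotone transform of
the generative alignment weight, so age/mediation effects measured through
ICS are attenuated relative to the latent paths; the mediation recovery suite
therefore tests the estimator on the latent chain (500 replications at
$n=76$), and the pipeline's cohort-level mediation output is interpreted as
directionally faithful rather than numerically equal to the latent truth.

## Problem sizes

Defaults used by the analysis scripts and the reproduction script: the full
76-participant, 46-region cohort; 1000 permutations per region in the
analysis scripts and 500 in the reproduction script (10,000 for the single
chance-level null, which is cheap); recovery suites use reduced cohorts
(2–20 participants, 1–4 regions) chosen so each suite completes in minutes
while keeping Monte-Carlo error well inside its tolerance. All sizes are
plain function arguments; nothing in the code depends on them structurally.
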