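---
title: "Methods: RNL colour vision modelling and psychophysics in chromafish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RNL colour vision modelling and psychophysics in chromafish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromafish)
```

chromafish implements the computational chain used to measure ultraviolet
colour discrimination in a tetrachromatic reef fish: pigment template
fitting, a receptor-noise-limited (RNL) colour model over a multi-primary
LED display, psychometric threshold estimation, and selection among
candidate visual models. This vignette explains each model, the parameters
that matter, the numerical choices, and what the synthetic-data tests do
and do not establish.

## Spectral core

All spectra are tibbles of `wavelength` (nm) and `value`, resampled by
linear interpolation onto a common 300–700 nm grid at 1 nm and integrated
by the trapezoid rule. The range covers the visual spectrum of
*A. ocellaris* including the near-UV; 1 nm resolves every feature of the
LED channels (20 nm FWHM) and the pigment templates, and the trapezoid
rule on that grid agrees with fine-grid quadrature to better than 0.1%
(tested against 0.01 nm quadrature). Linear interpolation is used because
the curves are smooth at this resolution and splines can overshoot near
steep lens cut-offs. Resampling outside a spectrum's support is an error
unless zero-fill is requested explicitly — silent extrapolation hides
calibration mistakes; zero-fill is appropriate only for emission spectra
that genuinely end before the grid does.

## Pigment analysis

Absorbance templates follow the Govardovskii et al. (2000)
parameterisation: an α band that is a function of `x = λmax/λ` plus a
Gaussian β band, with separate constant sets for A1 (retinal) and A2
(3,4-didehydroretinal) chromophores. Templates are renormalised to peak 1
on the grid and are valid for λmax in 330–600 nm.

`estimate_lambda_max()` reproduces the classic microspectrophotometry
workflow: normalise the scan, regress absorbance on wavelength over the
points of the long-wavelength limb lying between 30% and 70% of the
normalised maximum, read off λ50 where the regression line crosses 0.5,
and invert the template's own long-limb 50% crossing to get λmax
(bisection to 0.01 nm; exact within ±0.5 nm on noiseless templates across
360–560 nm for both chromophores). Two numerical choices deserve note:

- **Peak normalisation is noise-robust.** Dividing a noisy scan by its raw
  maximum biases the normalised curve downward (the maximum of 400 noisy
  points overshoots the true peak by roughly 2.8 standard deviations),
  which drags λ50 — and hence λmax — short by 2–3 nm at noise sd 0.05.
  The peak height is instead taken from a quadratic fit to the ±25 nm
  window around the boxcar-smoothed argmax, which removes that bias
  (measured residual bias ≈ 0.1–0.3 nm at sd 0.05, 100 scans per class).
- **Chromophore selection** under `auto` fits both templates and keeps the
  lower full-curve residual sum of squares. On noisy synthetic A2 scans
  the correct chromophore is chosen in ≥ 95% of cases.

Scans are binned when their λmax estimates differ by ≤ 10 nm, with single
linkage: the grouping criterion is pairwise, so chains (500, 509, 518)
merge. Complete linkage would be equally defensible; single linkage is the
minimal reading of "similar within 10 nm" and is what the tests pin down.
Bin means are averaged on the intersection grid, renormalised and refitted.

Lens transmission profiles are normalised at 700 nm and T50 is the
longest-wavelength upward crossing of 0.5, linearly interpolated; multiple
crossings warn and take the longest-wavelength one (short-wavelength
noise in transmission scans can produce spurious crossings).

## The RNL model

For receptor class *i* with lens-filtered sensitivity `R_i(λ)`, stimulus
radiance `S(λ)` and adapting background `S_b(λ)`:

- quantum catch `q_i = ∫S·R_i / ∫S_b·R_i` (von Kries adaptation: the
  background itself has `q = 1` in every class and is the achromatic
  point),
- log signal `f_i = ln q_i`,
- channel noise `e_i = σ_i/√η_i`, where σ is the Weber-fraction numerator
  of a single cone and η the relative abundance of the class. Defaults are
  the study's best-fit values: σ = 0.11 for the single (UV) cone, 0.14 for
  the three double-cone classes, abundances 1:2:1:1 (U:M1:M2:L).

ΔS between two stimuli is computed for any 2–4 receptor system as the
Euclidean norm of the noise-whitened signal difference `Δf/e` after
projecting off the achromatic direction `(1/e_1, …, 1/e_n)`. This is
algebraically identical to the published dichromat, trichromat and
tetrachromat closed forms (verified in the tests to 1e-12 against
independently coded closed forms), makes "uniform intensity shifts give
ΔS = 0" true by construction, and extends uniformly to all receptor
counts.

`noise_corrected_xyz()` maps catches into 3-D colour space by an
orthonormal basis of the whitened chromatic subspace, built by
Gram–Schmidt on the three opponent contrasts L−(M1+M2), M1−(M2+L) and
U−(M1+M2+L), with signs anchored so that exciting L, M1 or U alone moves
a stimulus toward +x, +y or +z. Because the basis is orthonormal in the
whitened space, Euclidean distance between any two mapped points equals
their ΔS exactly (contract: 1e-9), and hue angles are reproducible:
elevation Θ = asin(z/‖v‖), azimuth φ = atan2(y, x) mapped to [0, 360),
undefined at the poles.

Complementary colours sit on opposite sides of the achromatic point.
Azimuth alone is not sufficient to identify them: a UV-positive and a
UV-negative line can share polar azimuths with a second, same-side line
only a few degrees away. `complementary_pairs()` therefore requires both
an azimuth difference within tolerance of 180° (default 15°, since the
study's accepted pairs sit 10° from exact polarity) and, when elevations
are supplied, opposite elevation signs. Non-spectral colours are flagged
when some intermediate receptor class is excited strictly less than
classes on both of its sides.

## Stimulus design

The LED display model is linear: a pixel spectrum is the background screen
radiance plus the weighted sum of the five channel radiances, weights in
[0, 1]. Colour lines are built by solving, for each requested ΔS level
along a fixed direction in xyz space, a box-constrained least-squares
projection of the target point onto the display gamut (L-BFGS-B with a
warm start from the previous level plus deterministic single-channel
seeds; a residual above 0.02 ΔS is treated as gamut exhaustion and is an
error, which keeps "varied in saturation but not hue" an enforceable
contract — achieved hue angles stay within 2° along every default line).

Grey distractors must lie within 1 ΔS of the achromatic point while being
mutually 0.3–0.8 ΔS apart. Thirteen such points are placed
constructively: a near-achromatic centre plus twelve vertices of a
randomly rotated icosahedral shell whose radius satisfies both pairwise
bounds by construction (centre–vertex = R ≥ 0.3, diameter = 2R ≤ 0.8);
each shell point is then realised as LED weights (projection tolerance
0.01 ΔS) and the constraints are audited strictly on the realised loci,
restarting with a fresh seeded rotation on failure. Greedy rejection
sampling was tried first and reliably stalls near 9–10 of 13 points; the
constructive placement is deterministic under the seed and always
auditable.

Intensity-matched distractor subsets are found by exhaustive search over
subset sizes 6–10: the smallest subset whose per-receptor quantum-catch
range *strictly* brackets the target's catches in all four classes, ties
broken by total ΔS proximity to the target. Strict bracketing means the
target is never the brightest or dimmest pixel in any receptor channel,
so it cannot be found by brightness alone.

## Psychometric fitting

Choice data are Bernoulli trials. The psychometric function is
`P(correct|ΔS) = γ + (1 − γ − λ)·F((ΔS − m)/s)` with logistic `F` by
default (the cumulative normal is available; the study reports only "a
sigmoid"). The guess rate γ is fixed at 0 by default because zero-contrast
control targets were never pecked in the study; the lapse rate λ is fixed
at 0 by default and can be freed, capped at 0.5 so the 0.5-probability
threshold stays identifiable. Control rows (ΔS = 0) are excluded from the
likelihood — with γ fixed they carry no information about (m, s) and would
otherwise bias the fit.

Fitting is maximum likelihood (binomial), with five deterministic starts:
a binomial-GLM warm start plus a coarse grid over location and spread.
When γ = λ = 0 with the logistic F, the model *is* a logistic regression
in ΔS, so the GLM solution is already the global maximum and a single
polish suffices; this equivalence is asserted in the tests and exploited
for speed in the model scan. All-correct, all-incorrect, or
never-above-0.5 data raise a boundary flag and return no threshold. The
threshold solves `P(ΔS) = 0.5` by bisection (1e-6), which equals `m` when
γ = λ = 0 and is checked against the closed-form logistic inversion
otherwise. Bootstrap CIs (default 500 resamples) resample trial counts
within levels under a fixed seed.

Measured performance at the study's scale (8 levels × 10 trials): the
median absolute threshold recovery error over 200 seeded simulations
spanning m = 0.4–1.6 is ≈ 0.06 ΔS; at the study's unit of report — the
set mean over five fish — a planted 0.4 ΔS threshold is recovered within
±0.1 ΔS in every replicate tested.

## Model comparison

The scan asks which visual system makes the behavioural thresholds sit
closest to the nominal 1 ΔS. For each candidate — the full tetrachromat
and each drop-one trichromat, crossed with a σ grid (default 0.05–0.15 in
0.01 steps for single and double cones independently) — every target's
ΔS is recomputed from its spectrum, every fish-by-set curve is refitted
against the rescaled ΔS axis, and the model is scored by the mean over
colour sets of |threshold − 1|. Absolute deviation is used because a
signed mean could reward cancelling errors and make "smallest"
meaningless. Dropped-receptor variants keep the remaining abundances
unchanged, preserving each surviving channel's noise; no renormalisation
rule is implied by the design being emulated. Catches are precomputed
once (they do not depend on σ), so the scan is a few seconds for 605
grid cells. Variants that drive a discriminated stimulus to ΔS ≈ 0 are
flagged in the output rather than failing the scan.

On synthetic data generated under the tetrachromat with σ = (0.11, 0.14)
and thresholds planted at 1 ΔS, the scan ranks the full U-M1-M2-L model
first and localises both σ values within one grid step. Identifiability
at this scale is real but not lavish: with five fish per set the correct
model wins in 9 of 10 seeds, with six fish (the size of the study's larger
testing group, used for the model-comparison experiment here) in 10 of
10.

## The synthetic experiment

The generator's defaults are the study conditions: LED peaks
367/395/466/526/629 nm with Gaussian lineshapes (20 nm FWHM; the true
spectra are not published, and a flat, dim screen background stands in
for the measured one), cone λmax 386/497/515/535 nm as A1 templates
behind a logistic lens with T50 = 334 nm (slope 0.1 nm⁻¹), σ =
(0.11, 0.14), abundances 1:2:1:1, nine colour lines of 6–11 targets, 13
greys, five fish per set and 10 trials per level, with planted logistic
thresholds equal to the nine reported set means (spreads steeper for the
sets described as having steep curves).

The nine line directions are synthetic stand-ins: the published per-target
LED weights live in external supplementary data, and the real display's
gamut geometry is not recoverable from the article text. Directions were
chosen once, inside the synthetic display's measured gamut (reach ≥ 2 ΔS
along each ray), to preserve the study's qualitative geometry — four
UV-positive lines, five UV-negative, exactly two complementary pairs
(UV/green and purple/violet-green) with every other azimuth pair ≥ 20°
from polarity. Consequently per-set hue angles and which sets come out
"non-spectral" are display-specific here and are not comparable
number-for-number with the study; thresholds, T50, λmax, σ recovery and
the pair structure are.

What passing tests show — and what they do not. The synthetic trials are
exactly Bernoulli draws from a stationary logistic curve; real fish
learn, lapse, and vary between individuals and sessions. Recovery results
therefore demonstrate the estimators' correctness and precision under the
declared noise model, not robustness to motivational drift, serial
dependence, or mis-specified sigmoids. Similarly, synthetic absorbance
noise is independent Gaussian per wavelength; instrument noise is
correlated, so real λmax uncertainties will be somewhat larger than the
simulated ±0.5–1 nm.

## Known limitations

- The xyz axis convention fixes a rotation; any distance-preserving
  construction is equally valid, and published coordinates built with a
  different rotation will differ by a global rotation (angles between
  stimuli are preserved).
- `select_grey_set()` places at most 13 greys (centre + icosahedron);
  larger distractor sets would need a second shell.
- The scan varies σ-single and σ-double independently but assumes one σ
  per cone class; per-receptor σ is not explored.
- Inferential statistics on thresholds (mixed models, post-hoc contrasts)
  are out of scope; the package reports means, SEMs and bootstrap CIs.
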