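---
title: "Methods: SFDI forward modeling, inversion, and the synthetic skin cohort"
author: "sfdiskin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SFDI forward modeling, inversion, and the synthetic skin cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfdiskin)
```

# Overview

`sfdiskin` implements a complete spatial frequency domain imaging (SFDI)
analysis chain for in vivo skin, together with a ground-truthed synthetic
cohort generator used to validate it. SFDI projects sinusoidal illumination
patterns at several spatial frequencies onto tissue, demodulates the
captured images into per-frequency diffuse reflectance, calibrates against
a phantom of known optical properties, and inverts each pixel's
reflectance-versus-frequency curve to an absorption coefficient
$\mu_a$ and a reduced scattering coefficient $\mu_s'$ (both in
$\mathrm{mm}^{-1}$).

This vignette documents the model, the numerical choices, and the design of
the synthetic cohort, including the decisions taken where a choice had to
be made.

# Forward model

## Diffuse reflectance in the spatial frequency domain

The core forward model (`rdDiffusion`) is the standard diffusion
approximation for a semi-infinite homogeneous medium under sinusoidal
irradiance. With transport coefficient
$\mu_{tr} = \mu_a + \mu_s'$, reduced albedo $a' = \mu_s'/\mu_{tr}$, and
scalar attenuation

$$\mu_{\mathrm{eff}}'(f_x) = \sqrt{3\mu_a\mu_{tr} + (2\pi f_x)^2},$$

the diffuse reflectance at spatial frequency $f_x$
($\mathrm{mm}^{-1}$) is

$$R_d(f_x) = \frac{3 A a'}
{\left(\mu_{\mathrm{eff}}'/\mu_{tr} + 1\right)
 \left(\mu_{\mathrm{eff}}'/\mu_{tr} + 3A\right)},$$

where the boundary mismatch parameter is
$A = (1 - r_{\mathrm{eff}})/\left(2(1 + r_{\mathrm{eff}})\right)$ with the
polynomial approximation
$r_{\mathrm{eff}} = 0.0636\,n + 0.668 + 0.710/n - 1.440/n^2$ for relative
refractive index $n$ (default $n = 1.4$, typical for soft tissue against
air).

Two frozen reference values used throughout the tests:
$R_d(\mu_a = 0.02, \mu_s' = 1.4, f_x = 0) = 0.5657747$ and
$R_d(f_x = 0.2) = 0.1740013$.

**Validity.** The diffusion approximation assumes scattering-dominated
transport. At low albedo ($\mu_s' \lesssim 0.6\ \mathrm{mm}^{-1}$ with
$f_x > 0$) the closed form is genuinely non-monotone in $\mu_a$ — raising
$\mu_a$ raises $\mu_{tr}$ faster than it lowers the albedo, so $R_d$
first rises. The package keeps those values in the lookup table (they are
what the formula says) but the monotonicity contracts in the test suite
are asserted only on the diffusion-valid region.

## Penetration depth

`penetrationDepth` returns
$\delta(f_x) = 1/\sqrt{3\mu_a\mu_{tr} + (2\pi f_x)^2}$ in mm — the
effective $1/e$ depth of the frequency-damped fluence. For typical dermis
($\mu_a = 0.02$, $\mu_s' = 1.4$) it falls from about 3.43 mm at planar
illumination to about 0.78 mm at $f_x = 0.2\ \mathrm{mm}^{-1}$; this
frequency-dependent sampling depth is what makes SFDI sensitive to
superficial layers at high frequency.

## Monte Carlo oracle

`mcReflectance` / `mcLayeredRadial` implement an independent layered
photon-transport simulation in C++ (Henyey–Greenstein scattering with
anisotropy $g = 0.8$, so $\mu_s = \mu_s'/(1-g)$; Fresnel boundary
reflection; implicit-capture weighting; Russian roulette below weight
$10^{-4}$ with survival probability $0.1$; a 64-bit Mersenne Twister
seeded explicitly). Radially binned diffuse reflectance is transformed to
the spatial frequency domain with the zeroth-order Hankel transform

$$R_d(f_x) = 2\pi \int_0^\infty R(\rho)\, J_0(2\pi f_x \rho)\, \rho\, d\rho,$$

evaluated by the midpoint rule on the simulation's radial bins
(`hankelToSFD`). The transform is verified against the analytic pair
$e^{-a\rho} \leftrightarrow 2\pi a / (a^2 + (2\pi f)^2)^{3/2}$, and the
simulation against exact energy conservation at $\mu_a = 0$. At
skin-typical high albedo the Monte Carlo and diffusion models agree to
within 15% over $f_x \le 0.2$ — the documented accuracy envelope of the
diffusion approximation, not a defect to be calibrated away.

# Acquisition simulation

`renderAcquisition` renders one image per (wavelength, frequency, phase)
with illumination $I_k(x) = \tfrac{I_0}{2}\left[1 + \cos(2\pi f_x x +
\phi_k)\right]$ at the three phases $\phi_k \in \{0, 2\pi/3, 4\pi/3\}$,
multiplied by the scene's $R_d$. At $f_x = 0$ the three frames are
identical at level $I_0/2$, as a DC projector pattern has no phase.
Optional multiplicative Gaussian noise of fractional standard deviation
`noiseLevel` (default 0.01) models shot-noise-limited detection; it is
applied per pixel per frame from the acquisition seed, so renders are
fully reproducible.

# Demodulation and calibration

Three-phase demodulation (`demodulate`) recovers modulation amplitude and
offset exactly for noiseless sinusoids:

$$M_{AC} = \frac{\sqrt{2}}{3}\sqrt{(I_1-I_2)^2 + (I_2-I_3)^2 + (I_3-I_1)^2},
\qquad M_{DC} = \frac{I_1+I_2+I_3}{3},$$

with the $f_x = 0$ channel read from $M_{DC}$. Calibration
(`calibrate`) removes the instrument response by ratioing against a
phantom measured under the same illumination:

$$R_d^{\mathrm{samp}}(f_x) = \frac{M^{\mathrm{samp}}(f_x)}
{M^{\mathrm{ref}}(f_x)}\, R_d^{\mathrm{ref,pred}}(f_x),$$

where $R_d^{\mathrm{ref,pred}}$ is the diffusion prediction for the
phantom's known properties. The identity ($\mathrm{samp} =
\mathrm{ref}$) and scale invariance (common gain cancels) are exact and
tested at machine precision. Calibrated values outside $(0, 1]$ are
carried through but flagged in the validity mask rather than clipped, so
downstream stages can distinguish "measured nonsense" from "valid data".

# Inversion

`invertPixel` / `invertMap` invert the five-frequency reflectance vector
against a precomputed lookup table (LUT).

* **LUT grid.** 768 × 768 nodes, linear in $\mu_a \in [0, 3]$ and
  $\mu_s' \in [0.01, 4]$ $\mathrm{mm}^{-1}$ (steps
  $\approx 0.0039$ and $0.0052$). Linear axes keep bilinear
  interpolation unbiased across the skin-typical range; the upper bounds
  bracket reported in vivo values with margin.
* **Search.** A decimated (every 8th node) exhaustive pass finds the
  best coarse cell by sum of squared residuals over frequencies (computed
  as one matrix product per pixel chunk; ties broken toward lower
  $\mu_a$). A damped Gauss–Newton refinement then iterates on the
  bilinearly interpolated LUT surface with analytic in-cell gradients,
  Levenberg damping (start $10^{-3}$, $\div 4$ on accepted steps,
  $\times 10$ on rejected, up to 8 retries per iteration), steps clamped
  to ±20 cells, convergence when the largest parameter update falls
  below $10^{-4}\ \mathrm{mm}^{-1}$, cap 100 iterations. Plain
  pattern search was tried first and stalls in the narrow diagonal
  misfit valley at high $\mu_a$ / low $\mu_s'$; the damped Newton
  refinement recovers noiseless round trips to about $10^{-6}$
  $\mathrm{mm}^{-1}$, far inside one grid step.
* **Out-of-range policy.** Pixels whose residual norm remains above
  0.01 or that pin to the table edge are flagged invalid with a reason
  code (1 = unattainable reflectance, 2 = bad calibration channel)
  instead of returning a silently wrong pair.

Everything is deterministic: no random restarts, and `invertMap` equals
pixelwise `invertPixel` up to BLAS summation order.

# Synthetic skin cohort

## Tissue model

Skin is modeled as two layers: a thin melanized epidermis (default
thickness 0.12 mm, subject-specific) over a semi-infinite dermis.

* **Dermis scattering.** Each location has a target mean and SD for
  $\mu_s'$ at 851 nm (e.g. forehead 1.65 ± 0.174, chest 1.28 ±
  0.141 $\mathrm{mm}^{-1}$); each subject draws a per-location scale.
  Other wavelengths follow the scattering power law
  $\mu_s'(\lambda) = \mu_s'(851)\,(\lambda/851)^{-b}$ with default
  $b = 1.3$, a typical dermal slope.
* **Dermis absorption.** A fixed per-wavelength baseline (0.060 at
  471 nm down to 0.012 $\mathrm{mm}^{-1}$ at 851 nm) standing in for
  blood and water background.
* **Epidermal melanin.** Absorption
  $\mu_{a,\mathrm{mel}}(\lambda) = 51.9\,(\lambda/500)^{-8}\,
  \mathrm{mm}^{-1}$ scaled by the subject's melanosome volume fraction.
  The steep $\lambda^{-8}$ exponent is deliberately at the steep end of
  published melanin models: it concentrates the confound at the blue end
  of the band while leaving 851 nm nearly clean, which is the contrast
  the cohort is designed to exhibit. Fitzpatrick defaults for the
  fraction are I–VI = 0.01, 0.02, 0.04, 0.06, 0.09, 0.12. Palmar skin
  multiplies the fraction by 0.1 (glabrous skin is largely
  unpigmented).

## Two-layer effective reflectance

Rendering every pixel with Monte Carlo is infeasible, so
`effectiveRd` uses a fast two-layer approximation: the layered
$(\mu_a, \mu_s')$ profile is collapsed to depth-averaged coefficients
with weights $\propto e^{-2z/\delta(f_x)}$, where $\delta$ is the
penetration depth of the terminal layer, then fed to the homogeneous
diffusion formula. The factor 2 reflects the round trip (in and back out)
of remitted light. This captures the essential physics — high spatial
frequencies weight the epidermis more heavily — while staying closed-form
and fast. It is an approximation by construction; its role is to generate
a controlled, physically plausible confound, not to be a layered transport
solver.

## What the generator reproduces — and what it does not

Processing the rendered cohort with the homogeneous (single-layer) LUT
reproduces the designed phenomenology: apparent $\mu_s'$ at 471 nm falls
strictly and substantially from Fitzpatrick I to VI while changing under
5% at 851 nm; intersubject coefficient of variation at 471 nm exceeds the
851 nm CV at every non-palm location; and the palm — nearly melanin-free
across subjects — shows the smallest CV spread between wavelengths. These
are emergent results of the rendering + inversion chain, not quantities
inserted downstream.

Known limitations: no blood pulsatility or oxygenation dynamics, no
spatial texture within a location (scenes are uniform per region), no
surface curvature or height-dependent illumination, single global
anisotropy, and the two-layer collapse above in place of full layered
transport.

# Data container

Acquisition stacks persist as multi-page 32-bit greyscale TIFF plus a JSON
sidecar (wavelengths, frequencies, phases, pixel pitch, seed,
normalization scale, format version). The TIFF container stores
unit-range samples quantized to 32 bits, so `writeStack` normalizes by the
stack maximum and records that scale in the sidecar; round trips are exact
to an absolute resolution of $\max(\mathrm{data}) \times 2^{-31}$.
Negative or non-finite pixels are refused at write time because the
container cannot represent them.

# Statistics

`extractROI` aggregates per-pixel maps over a region of interest,
honoring the validity mask and requiring at least half the pixels valid.
`cohortSummary` gives per-location intersubject mean and sample SD
($n-1$), `coefficientOfVariation` their ratio, `oneWayAnova` /
`anovaFromSummary` the one-way fixed-effects decomposition (the
summary-statistic form is algebraically identical to the raw-data form and
is tested as such), and `tukeyHsd` pairwise comparisons via the
studentized range distribution (`ptukey`). `reproduceTables`
reconstructs the ANOVA and Tukey matrices from the bundled per-location
summary table alone, which is how printed group summaries can be audited
without raw data.

# Reproducibility

All stochastic stages (cohort draws, rendering noise, Monte Carlo) take
explicit integer seeds, and the pipeline persists its configuration, the
ground truth, and every stage's tabular output. `runPipeline` re-run with
the same spec writes byte-identical tables.
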