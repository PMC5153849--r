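---
title: "Calibrating optical density against cell concentration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating optical density against cell concentration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odcal)
```

## The measurement model

A spectrophotometer or plate reader reports the decadic attenuation of a
beam through a suspension. For microbes and beads at 600 nm essentially no
light is absorbed; the attenuation is *turbidity*, light scattered out of
the beam. `odcal` models the reading in three layers.

**Single particle.** A sphere of diameter $D$ and refractive index $n_p$ in
a medium of index $n_m$, illuminated at vacuum wavelength $\lambda$, is
characterised by the size parameter $x = \pi D n_m / \lambda$ and relative
index $m = n_p / n_m$. `mieEfficiencies()` evaluates the exact Mie series
for real $m$: extinction and scattering efficiencies from the partial-wave
coefficients $a_n, b_n$, truncated at the Wiscombe cutoff
$N = \lceil x + 4x^{1/3} + 2\rceil$, with the logarithmic derivative
computed by downward recurrence started $15$ orders above $N$ (numerically
stable; the standard scheme). The limiting forms are exposed separately:
`rayleighQsca()` for $x \lesssim 0.3$ and `adaQext()`, the
anomalous-diffraction efficiency for optically soft spheres, in terms of
the phase shift $\rho = 2x(m-1)$:
$q(\rho) = 2 - \tfrac{4}{\rho}\sin\rho + \tfrac{4}{\rho^2}(1-\cos\rho)$.
For $\rho \to 0$ this reduces to $\rho^2/2$, giving the small-phase-shift
cross-section `jobstSigma()` $= (\rho^2/2)\,\pi r^2 \propto r^4$. That
fourth-power law is the reason bacterial OD calibrations are so sensitive
to cell size, and it is exact in the implementation (a log–log regression
of $\sigma$ on $r$ returns slope 4 to machine precision).

**Instrument geometry.** A real detector subtends a half-angle
$\theta_{acc} = \arctan(R/d)$ at the sample; forward-scattered light inside
that cone is counted as transmitted. `acceptanceCorrection()` subtracts
from $Q_{ext}$ the phase-function integral
$\frac{1}{x^2}\int_0^{\theta_{acc}}(|S_1|^2+|S_2|^2)\sin\theta\,d\theta$,
computed by Gauss–Legendre quadrature (64 nodes, doubled until the result
is stable to $10^{-6}$ relative; failure to stabilise after two doublings
is an error rather than a silent inaccuracy). The default geometry is
ideal ($\theta_{acc}=0$) because published instrument apertures are rarely
known; geometry is a configuration option. The two limits behave correctly:
a vanishing aperture recovers $Q_{ext}$, and collecting the full sphere
leaves zero effective extinction for a non-absorbing particle.

**Suspension.** With effective per-particle cross-section $\sigma$ (cm²),
concentration $C$ (ml⁻¹) and path $L$ (cm), the decadic turbidity is
$\tau = \sigma C L / \ln 10$. In the single-scattering regime
(OD $\lesssim 0.2$; `regimeClassify()`, boundary inclusive on the single
side) the reading is $\tau$ itself — Beer–Lambert. At higher density the
reading bends below the line; `odMultipleScattering()` models this as
$\mathrm{OD} = \tau - q\tau^2$ with a single dimensionless $q \ge 0$, valid
on the monotone branch $\tau \le 1/(2q)$. The full correction factor for
multiple scattering depends on the cross-section and depth in ways that
require the concentration itself, so a one-parameter parabola — the
empirically observed shape of plate-reader calibration curves, exactly
reducible to Beer–Lambert at $q = 0$ — is used instead, with $q$ fit per
instrument and scatterer (default 0.1). Beyond the monotone branch the
suspension enters the photon-diffusion regime, which this model refuses to
evaluate rather than extrapolate.

Polydispersity: when a `Scatterer` has `size_cv > 0` the cross-section is
averaged over a lognormal diameter distribution with that coefficient of
variation, by 11-point Gauss–Hermite quadrature; commercial bead lots have
stated diameter SDs and microbial populations are never monodisperse.

Microplate fill volumes shorten the vertical optical path, so readings are
rescaled to a 1 cm-equivalent scale by instrument-specific multiplicative
factors (`applyVolumeCorrection()`), default table 1.0560 (300 µl), 1.5848
(200 µl), 6.3694 (100 µl). These factors are treated as instrument
configuration, not derived from geometry: the 100 µl factor is inconsistent
with naive path-length scaling (menisci and well optics intervene), so no
geometric derivation is attempted.

## Calibration fitting and inversion

`fitCalibration()` fits $\mathrm{OD}(C) = p_0 + p_1 C + p_2 C^2$ (degree
configurable) to a dilution series after `trimSaturated()` removes
concentrations whose mean OD reaches the instrument's saturation level
(default 3.5). The loss is Tukey's bisquare, minimised by iteratively
reweighted least squares: tuning constant 4.685, scale re-estimated each
iteration as the normalised median absolute deviation of the residuals
(MAD/0.6745). Replicate readings enter as individual observations; the
robust loss handles their weighting. The intercept is retained so a blank
offset is visible rather than hidden.

Numerical choices worth stating:

* The concentration axis spans many decades, so the fit runs on
  $u = C/\max C$; raw-scale powers of $10^9$ would make the design matrix
  hopeless and an absolute convergence test meaningless. Convergence is a
  maximum coefficient change below $10^{-8}$ *on the rescaled axis*;
  coefficients are mapped back afterwards.
* A residual sitting exactly at the bisquare cutoff can make the weights
  cycle between two sets; the 50-iteration cap is then the stopping rule
  (recorded in the diagnostics, warned about) provided the remaining
  movement is below $10^{-4}$ relative — beyond that it is an error.
* An exact fit (robust scale collapsing to zero) terminates immediately.
* For a downward-curving quadratic whose vertex falls inside the data span,
  the stored validity ranges are capped at the vertex: the curve is only
  invertible on its monotone increasing branch, and the validity object
  enforces a strictly positive derivative across `cValidRange`.

`invertCalibration()` solves the quadratic for the increasing-branch root
using the numerically stable form $2(\mathrm{OD}-p_0)/(p_1+\sqrt{\Delta})$,
refuses OD values outside the fitted range unless `extrapolate = TRUE`, and
distinguishes "saturated" (above the range or the parabola's vertex) from
"below blank" failures. Round trips hold to $10^{-9}$ relative on the valid
branch. `concentrationTable()` inverts a set of curves at the conventional
OD values 0.05, 0.1, 0.5, 1 and 10, marking out-of-range cells missing
rather than extrapolating. `crossCalibrate()` maps one instrument's
readings onto another's by the closed-form proportional least-squares scale
$\sum \mathrm{od}_A\,\mathrm{od}_B / \sum \mathrm{od}_A^2$; the offset is
fixed at zero by default because the mapping is a relative difference
between instruments, and is freed only on request. `alignODCounts()` uses
the same closed form to scale a count-derived concentration series onto an
OD series after linear interpolation to shared timepoints; a single ratio
is estimated (scaling both axes of a proportionality is one degree of
freedom, so one factor is identifiable).

`selectCalibrationDegree()` formalises "is a quadratic enough?":
ordinary-least-squares fits of increasing degree are compared by nested
F-tests and the lowest degree whose next-order term is not significant at
$\alpha = 0.01$ is accepted. On data generated from the forward model —
exactly quadratic in $C$ — the modal selected degree across seeded
replicates is 2.

## Growth metrics

`growthRateSeries()` estimates the specific growth rate as the slope of
$\ln v$ against time in a centred sliding window (default 5 points; at the
7.5-minute sampling interval that is a 37.5-minute window), in hr⁻¹.
Windows containing non-positive values are skipped with a warning rather
than silently log-transformed. The estimator is exact on noiseless
exponentials for any window length. `growthMetrics()` takes `mu_max` as the
maximum of that series, its timing, the yield as the curve maximum, and the
lag as the intersection of the log-space tangent at the fastest-growth
point with the initial baseline (mean of the first three log values),
clamped to $[0, t_{\mu_{max}}]$; "lag time" has no universal definition and
the tangent construction is the transparent, common choice. Non-growing
curves return `NA` lag. Replicates are analysed individually and
summarised as mean ± SEM.

`compareRateEstimates()` contrasts the OD-based and count-based maximum
rates. Because the max-of-noisy-windows estimator is biased upward by an
amount that grows with per-window noise, the two series should be compared
with windows spanning comparable *time* (the `count_window_points`
argument): OD sampled every 7.5 min and counts every 30 min are compared
with 13- and 5-point windows respectively in the packaged scenarios. The
same estimator is applied to both sides so the bias largely cancels in the
ratio.

## What the synthetic generator does and does not emulate

`makeBeadSeries()`, `simulateGrowth()`, `simulateODReadout()` and
`simulateCounting()` produce every input the rest of the package consumes,
with ground truth attached and byte-reproducible output under a seed.

Defaults mirror the standard experimental protocol: the five-size
polystyrene bead set (0.51, 0.96, 3.00, 10.0, 15.7 µm; $n_p = 1.59$) in
water, readings at 600 nm as the mean of 5 noisy reads, 7.5-minute
sampling, multiplicative Gaussian readout noise with CV 2% (no noise model
is published for these readers; 2% is a realistic plate-reader figure and
the generator parameter is free), and Poisson counts over
55.6 × 55.6 × 100 µm microscope fields, 20–50 fields per sample. Cells are
modelled as equivalent-volume spheres with $n_p = 1.40$ (a typical
bacterial cytoplasm value; real cell indices vary by strain and state).

Three size trajectories are generated. *Constant* size: cell number follows
the growth model (exponential or logistic) and OD tracks concentration up
to the multiple-scattering bend. *Stationary shrink*: per-cell volume falls
by a set fraction as a logistic culture approaches capacity, so an
OD-to-count proportionality fitted in exponential phase degrades after
stationary onset. *Filamentation*: total biovolume follows the model
throughout, but division halts during a pulse window — cell number is held
flat while per-cell volume (filament mass) grows — and afterwards filaments
divide, per-cell volume relaxing back to baseline over a configurable
timescale (default 0.3 hr; division of an existing filament needs no
growth, so it is fast). With a baseline diameter in the size-sensitive
regime ($D \lesssim \lambda$, e.g. 0.8 µm), this produces the
characteristic signature: OD rising while counts are flat, an OD dip just
after the pulse as large scatterers divide into small ones, and an OD-based
maximum rate that exceeds and postdates the count-based one. The packaged
filamentation comparison deliberately observes the culture through the end
of the pulse: once the division burst begins, the count series rises at the
division rate, which is not a growth rate, and comparing maxima across that
phase would be meaningless. Counting in the scenarios starts once the OD
has risen above baseline (as one would in practice); counting near-empty
fields at inoculation densities yields Poisson noise that swamps any rate
estimate. Field count 50 and a starting density of $3\times10^8$ ml⁻¹ keep
the per-point counting CV (~1.5%) comparable to the OD readout noise, so
neither estimator is structurally noisier than the other.

What passing tests on these data do *not* show about real cultures:
filaments are mapped to equivalent-volume spheres (no rod or coil optics),
readout noise is uncorrelated across wells and times (real plates have
drift, edge effects and condensation), counting error is purely Poisson
(manual counting has segmentation and dilution errors), and media indices
are constant in time. The generator is a test of the *inference machinery*
under known truth, not a simulation of any particular experiment.

## Problem sizes

The shipped tests and acceptance checks use desk-scale sizes chosen to make
sampling error negligible relative to the tolerances tested: 24-point
dilution series with 1–5 replicates, growth grids of 49–160 timepoints,
20-point (x, m) grids against the independent Mie oracle (itself a direct
Bessel-function evaluation, algorithmically disjoint from the package
path), 1000-seed means for counting-estimator bias, and 10-seed replicates
for degree selection.

## Known limitations

Real refractive indices only (no absorbing or pigmented particles);
spheres and equivalent spheres only; the quadratic turbidity correction is
a stand-in with one free parameter, not a derived transport solution, and
its validity ends at $\tau = 1/(2q)$; lag times from the tangent
construction depend on the chosen baseline points for curves with drifting
baselines; and cross-calibration is proportional by default, which is only
appropriate when both instruments are blanked consistently.
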