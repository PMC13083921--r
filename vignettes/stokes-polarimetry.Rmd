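---
title: "Quantitative Stokes polarimetric microscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative Stokes polarimetric microscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stokespol)
```

## The measurement model

A dual photoelastic-modulator (PEM) Stokes polarimeter measures the full
polarisation state of light at every camera pixel. Two resonant PEMs
(frequencies $f_1$, $f_2$) and a linear analyser sit in the imaging path; the
PEM retardances oscillate as $\delta_i(t) = A_i \sin(2\pi f_i t)$, shifting
polarisation-dependent signal into harmonics of the drive frequencies. The
coordinate system is set by the instrument itself: the optic axis of PEM2
defines the x-axis, PEM1 sits at $\alpha$ (default 45°) and the analyser at
$\beta$ (default 23°) from it.

The detected intensity is the first Stokes component of

$$ S_\text{det}(t) = M_\text{pol}(\beta)\, M_\text{ret}(\delta_2(t), 0)\,
   M_\text{ret}(\delta_1(t), \alpha)\, S_\text{in}, $$

with the standard Mueller matrices for an ideal polariser and linear
retarder (`mueller_polariser()`, `mueller_retarder()`). Four demodulated
signals are extracted per pixel by lock-in detection: the DC level
$S_{DC}$, the second harmonics $S_{QU1}$ (at $2f_1$) and $S_{QU2}$ (at
$2f_2$), and the first harmonic $S_v$ (at $f_1$). `lockin_demodulate()`
implements this numerically — multiplication by the reference waveforms and
averaging over an integer number of common drive periods.

### The Bessel-series oracle

Because the chain is linear in each Mueller factor, the intensity is
bilinear in $(1, \cos\delta_1, \sin\delta_1)$ and
$(1, \cos\delta_2, \sin\delta_2)$. `analytic_harmonics()` evaluates the
static chain at nine retardance pairs to obtain the nine bilinear
coefficients exactly, then applies the Jacobi–Anger expansion

$$ \cos(A\sin\omega t) = J_0(A) + 2\sum_k J_{2k}(A)\cos(2k\omega t), \qquad
   \sin(A\sin\omega t) = 2\sum_k J_{2k+1}(A)\sin((2k+1)\omega t) $$

to read off the DC, $f_1$, $2f_1$ and $2f_2$ line amplitudes in terms of
$J_0$, $J_1$, $J_2$. This is an *independent* derivation of the same four
quantities that the numerical lock-in produces, and the two are held to
agree to better than $10^{-6}$ relative error in the tests. Cross-harmonic
coincidences (a PEM harmonic combination landing on a demodulation
reference) are checked up to order 8 and warned about; with the default
50/42 frequency pair the lowest-order coincidence involves Bessel factors
of order $\geq 8$, whose contribution is far below $10^{-9}$.

Two consequences worth knowing: each signal is a *linear* functional of
$(I, Q, U, V)$, and for purely circular input at the default amplitudes the
second-harmonic channels carry no signal at all (there is no linear
component to modulate) — the circular information travels entirely in the
$f_1$ line.

### Choice of PEM amplitudes and frequencies

The default peak retardation is $A_1 = A_2 = 2.405$ rad, the first zero of
$J_0$. At this working point the retardance-dependent DC terms vanish, so
$S_{DC} = I/2$ exactly — standard dual-PEM practice. The simulation
frequencies 50 and 42 are arbitrary time units mirroring the 50 kHz and
42 kHz optical heads of the modelled instrument; only their ratio matters
to the mathematics, and the common period is $1/\gcd = 0.5$ time units.
Time series default to 8192 samples per common period, comfortably beyond
the 20-samples-per-cycle floor the demodulator enforces for its fastest
reference.

## Calibration: the sparse matrix K

The Stokes parameters relate to the signals through a $4\times4$ matrix
$K$:

$$ (I, Q, U, V)^\top = K\, (S_{DC}, S_{QU1}, S_{QU2}, S_v)^\top, \qquad
 K = \begin{pmatrix} k_1 & k_2 & k_3 & 0\\ 0 & k_4 & k_5 & 0\\
 0 & k_6 & k_7 & 0\\ 0 & 0 & 0 & k_8 \end{pmatrix}. $$

The zero pattern is structural: the circular component only enters the
odd-harmonic channel, and the DC/second-harmonic channels only carry
intensity and linear components. `validate_k_sparsity()` demonstrates this
empirically by fitting an *unconstrained* $4\times4$ matrix to simulated
calibration data and reporting the largest magnitude at the zero
positions (relative to the largest free element); for the default geometry
it sits at numerical round-off.

Given pairs of known generator states and measured signals, the relation is
linear in $k_1..k_8$, so `calibrate()` solves row-wise linear least squares
by default, with per-row identifiability checks that name the elements a
deficient design cannot determine (e.g. $k_8$ when no state excites $V$).
A `"nonlinear"` option additionally refines the generator states' azimuth
and ellipticity by Levenberg–Marquardt, for the realistic case of an
imperfect polarisation state generator; on exact data it reproduces the
linear solution. The default calibration set is the six Poincaré-axis
states (H, V, ±45°, RCP, LCP). Solver tolerances: sparsity pass threshold
$10^{-6}$ relative, Levenberg–Marquardt `ftol`/`ptol` $10^{-12}$.

## Derived polarisation maps

With $I_p = \sqrt{Q^2+U^2+V^2}$ the polarised intensity, the package
computes per pixel: normalised components $q = Q/I_p$ etc. (so
$q^2+u^2+v^2 = 1$ wherever defined), ellipticity angle
$\varepsilon = \tfrac12\arcsin(V/I_p)$, polarisation azimuth
$\theta = \tfrac12\arctan(U/Q)$, degree of polarisation $P = I_p/I$ and
depolarisation $D_p = \sqrt{1-P^2}$.

Numerical choices:

* **Masking, not NaN.** Pixels with $I_p$ below $10^{-12}\max(I)$ have no
  defined normalised state; they are set `NA`, flagged in a mask and
  counted, so downstream ROI statistics remain well defined.
* **Azimuth quadrant.** The single-argument arctangent is ambiguous;
  `azimuth_map()` uses `atan2(U, Q)/2`, covering the full $(-\pi/2,
  \pi/2]$ range and handling $Q = 0$.
* **Clamping.** Noise can push measured $P$ marginally above 1, which
  would make $D_p$ imaginary; such pixels are clamped to 1 and counted in
  a diagnostic attribute.

## The uniaxial sample model and its inversion

A birefringent sample with in-plane optic axis at $\gamma$, retardation
$\delta_s$ and depolarisation factor $\sigma = P^{-1} \ge 1$ acts on
normalised Stokes vectors through a matrix whose polarised block is a
rotation (implemented verbatim in `sample_mueller()`; for $\sigma = 1$ it
equals the rotated ideal retarder). $\sigma$ scales the intensity row, so
the transmitted degree of polarisation of fully polarised input is
$1/\sigma$ and $D_p = \sqrt{1 - \sigma^{-2}}$ — this is how the phantom's
depolarisation ground truth propagates to the reconstructed maps.

Under perfectly circular illumination $(1, 0, 0, 1)$ the transmitted
components reduce to $q' = -\sin 2\gamma \sin\delta_s$,
$u' = \cos 2\gamma \sin\delta_s$, $v' = \cos\delta_s$, giving the direct
estimators `retardation_from_circular()` ($\delta_s = \arccos v'$) and
`axis_from_linear()` ($\gamma = \tfrac12\,\mathrm{atan2}(-q', u')$,
reduced to $[0, \pi)$).

* **Principal value.** $\arccos$ cannot distinguish $\delta$ from
  $2\pi-\delta$; $\delta_s$ is reported in $[0, \pi]$, appropriate for
  thin sections whose retardation is far below $\pi$.
* **Sign convention.** The handedness sign linking the $\sin\delta_s$
  terms to $V$ is fixed once by the forward model and verified by the
  round-trip tests (forward then invert reproduces $\delta_s$ and
  $\gamma$ mod $\pi$ to $10^{-10}$ over a grid).
* **Degenerate axis.** Where $\sin\delta_s \approx 0$ the axis is
  undefined; it is masked below a threshold of $10^{-6}$ times the largest
  linear-component magnitude.
* **Precision near zero retardation.** $\arccos$ has infinite slope at
  $v' = 1$, so a $10^{-16}$ rounding error in $v'$ becomes a $10^{-8}$
  absolute error in $\delta_s$; end-to-end recovery is therefore asserted
  at $10^{-6}$, not at double precision.

### Elliptical illumination and the full inversion

Real illumination is never perfectly circular (the modelled instrument
measures an ellipticity angle of about 41° rather than 45°). The shortcut
$\delta_s = \arccos v'$ then acquires a bias that depends on both the
input azimuth and the sample orientation; `circular_input_error_profile()`
maps it (for $\delta_s = 1$ rad at 41° ellipticity the worst-case error is
about 0.14 rad, with a $\pi/2$-periodic envelope). When the input state is
known — measured without the sample, as the acquisition protocol
prescribes — `retardation_full_inversion()` solves the three transmitted
component equations for the two unknowns $(\delta_s, \gamma)$ per pixel by
damped Gauss–Newton least squares, started from the circular-approximation
estimates plus a set of axis offsets to avoid the periodic ambiguity of
the residual surface. On the 41° sweep it recovers $\delta_s$ to
$10^{-6}$ at every orientation, and its error is bounded by the circular
approximation's everywhere. Pixels that fail to converge fall back to the
circular estimate and are flagged.

### Background correction

Retardation images of real acquisitions carry a non-specific baseline (a
representative observed value is 0.11 rad). `background_correct()`
estimates it from a user-drawn no-tissue region (default) or as the map's
modal value, and subtracts it. Negative corrected values are retained
deliberately: they indicate regions whose optic axis is rotated by 90°
relative to the polarimeter x-axis.

## Synthetic phantoms: what they emulate and what they do not

`generate_phantom()` produces per-pixel ground truth $(\delta_s, \gamma,
\sigma)$ for four procedural geometries:

* `placenta_villi` — concentric rings with the optic axis tangential,
  emulating collagen wrapping villous vessels; peak retardation 0.04 rad.
* `dermis` — two crossing systems of oriented fibre bands with a smooth
  orientation-jitter field; retardation up to 1.00 rad.
* `keloid` — a dermis background plus an elliptical lesion of dense,
  chaotically oriented, strongly depolarising tissue; retardation
  1.40 rad, maximum depolarisation 0.96.
* `flat` — constant fields, for smoke tests and noise studies.

Magnitudes default to representative tissue values (tissue $D_p$ 0.37,
substrate $D_p$ 0.44 — mid-range of a typical 0.40–0.48 background band)
so simulated experiments read against familiar numbers; all are
overridable, and retardation fields are rescaled so their maximum equals
the configured peak *by construction*. Phantoms are deterministic per
seed.

The geometry is procedural — annuli, bands, blobs — and intentionally not
image-realistic: it exercises every estimator (spatially varying
$\delta_s$, $\gamma$ wrapping through the full $[0, \pi)$ range, mixed
depolarisation) without claiming histological texture. Passing tests
therefore demonstrate correctness of the *computational chain*, not
robustness to real-tissue confounds such as scattering anisotropy,
out-of-plane optic-axis tilt, multi-layer structure or stain-dependent
contrast, none of which the sample model represents.

### Noise model and the retardation noise floor

The camera noise model (`noise_spec()`) is a stand-in: Gaussian read noise
on each demodulated plane plus optional Poisson shot noise on the DC
plane. `read_noise_for_retardation_sd()` inverts first-order error
propagation through the reconstruction chain to find the read-noise level
that produces a requested retardation noise SD (0.005 rad is the
representative floor used in the tests). The operating point for that
propagation is the 0.11 rad background baseline, not zero: at
$\delta_s = 0$ the arccos relation is degenerate (infinite slope, folded
noise), so a Gaussian signal noise has no linear image in retardation
there.

## ROI statistics

`extract_rois()` cuts square ROIs specified by centre and side length
(micrometre sides are converted at the sampling density with
round-to-nearest; 48.6 µm at 0.617 px/µm gives 30 px and hence the
canonical ~900-pixel ROI). Masked pixels are excluded and counted.
Summaries use the sample SD. `compare_groups()` operationalises
"t-test or Mann–Whitney where appropriate" in the conventional way: both
groups must pass Shapiro–Wilk at 0.05 for the t-test, otherwise the
two-sided Mann–Whitney U is used (exact for small untied samples). The
t-test is Welch's by default — the safer choice when only "unpaired
t-test" is specified — with a pooled-variance option. No multiple-testing
correction is applied (raw p-values are reported); box plots use Tukey
1.5×IQR whiskers. The gated procedure's empirical type-I error is held at
$0.05 \pm 0.02$ over 2000 replicates under both Normal and exponential
nulls, and the Mann–Whitney p-values are verified against exhaustive
permutation for group sizes up to 5.

Constant-valued groups (possible on degenerate maps) have no defined
Shapiro–Wilk statistic; they are routed to the rank test, and two
identical constant groups report p = 1.

## File formats and interfaces

Images travel as multi-page 32-bit float TIFF (page order in the
description tag: I,Q,U,V for Stokes images; $S_{DC}, S_{QU1}, S_{QU2},
S_v$ for signal stacks; $\delta_s, \gamma, \sigma$ for truth sidecars).
Radiometric maps need sign and full float range, which mainstream R TIFF
bindings restrict to [0, 1]; the package therefore carries a minimal
strip-based float TIFF codec of its own, and its output is cross-validated
against an independent TIFF implementation in the tests. Angles are
radians internally and degrees at every human-facing boundary (YAML
configs, CLI flags). All file writes are atomic (temp file + rename).
Calibration sets, ROI specs and results are plain CSV; K matrices and
states are YAML.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
demodulation checks on 8192-sample series over 20 random states and three
configurations; calibration recovery on 6–50 states; inversion sweeps on
~1200-point grids; end-to-end phantom recovery at 512×512 per tissue kind
(noiseless) and 256×256 for the noise-floor experiment; statistical
calibration at 2000 replicates per null. These sizes were chosen to give
tight Monte-Carlo error on every asserted quantity while keeping a full
run in the seconds-to-minutes range on one CPU.

## Known limitations

* The instrument model is ideal: perfect sinusoidal PEM waveforms, no
  wavelength dispersion of retardance, no detector nonlinearity, no
  reference-phase error (a real demodulation unit's phase and gain
  conventions are absorbed by calibration, which is exactly why the
  calibration module exists).
* The sample model is a single uniaxial in-plane retarder with an
  isotropic depolarisation factor; multi-layer samples, biaxial
  anisotropy and out-of-plane tilt are out of scope.
* $\delta_s$ is reported modulo the $[0, \pi]$ principal value.
* The Mueller-matrix of the *instrument* is never imaged — the pipeline
  measures Stokes vectors, and sample properties are inferred through the
  with/without-sample protocol.
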