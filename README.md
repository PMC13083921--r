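# stokespol

Quantitative Stokes polarimetric microscopy with dual photoelastic
modulators, in R.

Polarisation microscopy is a label-free way to quantify tissue
architecture: birefringent structures such as collagen impose a phase
retardation between orthogonal polarisation components, and scattering
microstructure depolarises the beam. A dual photoelastic-modulator (PEM)
Stokes polarimeter measures the full polarisation state — the Stokes
vector (I, Q, U, V) — at every camera pixel, from which per-pixel maps of
phase retardation, optic-axis orientation and depolarisation follow. These
are objective, quantitative readouts of extracellular-matrix organisation
(e.g. dense disorganised collagen in keloid scars versus normal dermis).

`stokespol` implements the complete computational chain of such an
instrument, exercised end-to-end on synthetic tissue phantoms with known
ground truth:

* **Instrument forward model** — the time-varying Mueller chain
  analyser(β) · PEM2(δ₂(t)) · PEM1(δ₁(t), α), with lock-in recovery of
  the four demodulated signals (S_DC, S_QU1, S_QU2, S_v) and an
  independent Bessel-series (Jacobi–Anger) oracle for the same
  amplitudes.
* **Calibration** — least-squares estimation of the sparse 4×4 matrix K
  in (I, Q, U, V)ᵀ = K (S_DC, S_QU1, S_QU2, S_v)ᵀ, with identifiability
  diagnostics and an empirical check that K's zero pattern emerges from
  unconstrained fits.
* **Polarisation maps** — normalised Stokes components, ellipticity angle
  ε = ½ arcsin(V/Ip), azimuth θ = ½ arctan(U/Q), degree of polarisation
  P = Ip/I and depolarisation Dp = √(1 − P²), with explicit masking and
  clamping semantics.
* **Birefringence inversion** — the uniaxial sample Mueller model with
  retardation δ_s, optic axis γ and depolarisation factor σ = 1/P;
  the circular-illumination estimators δ_s = arccos v′,
  γ = ½ atan2(−q′, u′); a per-pixel Gauss–Newton inversion for
  elliptical illumination; error profiling of the circular approximation;
  background-baseline correction.
* **Phantoms** — procedural placental-villi / dermis / keloid geometries
  with seeded ground truth, rendered through the full instrument model
  with a tunable noise floor.
* **ROI statistics** — square-ROI extraction, Shapiro–Wilk-gated
  Welch-t / Mann–Whitney group comparisons with exact small-sample
  p-values.
* **I/O + CLI** — multi-page 32-bit float TIFF, CSV and YAML formats, and
  a `stokespol` command-line tool (`simulate`, `calibrate`,
  `reconstruct`, `maps`, `retard`, `roistats`, `errorsweep`).

## Worked example

Simulate a keloid phantom, calibrate the instrument from the six
Poincaré-axis generator states, reconstruct the Stokes image and derive
the quantitative maps:

```r
library(stokespol)

cfg <- polarimeter_config()                    # α = 45°, β = 23°, A = 2.405 rad
fit <- calibrate(simulate_calibration_set(canonical_states(), cfg))
fit
#> Calibration fit (linear least squares, 6 states)
#>          k1          k2          k3          k4          k5          k6
#>  2.00000000  0.00020973  0.00020973  3.33398362  0.00000000  0.00000000
#>          k7          k8
#>  3.21959055 -2.77312516
#> Residual sum of squares: 2.09e-30

ph  <- generate_phantom(phantom_spec("keloid", c(256, 256), seed = 7))
acq <- render_acquisition(ph, input = c(1, 0, 0, 1), cfg = cfg)
img <- reconstruct_stokes(acq$signals, fit)

rmap <- retardation_map(img, mode = "circular")
rmap
#> Retardation map (circular mode): 256 x 256 pixels
#>   delta in [0.0001514, 1.4] rad
max(depolarisation_map(img))
#> [1] 0.96
```

The keloid lesion reaches 1.40 rad retardation and 0.96 depolarisation —
the phantom's construction anchors — and the reconstruction recovers both
through the full signal chain. ROI statistics compare the lesion core
against the background:

```r
rois <- list(roi_spec("lesion", 128, 128, 30, side_unit = "px"),
             roi_spec("background", 30, 30, 30, side_unit = "px"))
vals <- extract_rois(rmap$delta, rois)
compare_groups(vals$lesion, vals$background, c("lesion", "background"))
#> Group comparison: lesion (n=900, mean 1.094, SD 0.182) vs background (n=900, mean 0.5932, SD 0.2892)
#>   Shapiro-Wilk p: 1.2e-16 / 6.89e-19 -> Mann-Whitney U
#>   statistic = 7.603e+05, two-sided p = 8.064e-228  (significant at 0.05)
```

Both groups fail the Shapiro–Wilk normality gate (the retardation fields
are strongly structured), so the comparison routes to the two-sided
Mann–Whitney U test.

The same pipeline is available from the shell:

```sh
stokespol simulate --kind keloid --size 256 --seed 7 --out acq.tif --truth truth.tif
stokespol calibrate --states states.csv --out K.yaml
stokespol reconstruct --acq acq.tif --k K.yaml --out stokes.tif
stokespol retard --stokes stokes.tif --out-dir maps/
```

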