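---
title: "Axial line-scanning FCS: models, corrections and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Axial line-scanning FCS: models, corrections and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(axialFCS)
```

## The measurement

A ligand secreted into the medium binds receptors diffusing in the
plasma membrane. Labeling the ligand green and the receptor red and
focusing a confocal volume on the membrane, the intensity fluctuations
caused by molecules diffusing through the observation area carry the
local concentrations of free receptors, free ligand–receptor complexes
and their diffusion coefficients. Because a live membrane moves, the
focus is swept across it along the optical axis by a resonant lens
(~147 kHz, period ~6.8 µs), so each oscillation crosses the membrane
twice and membrane drift only shifts where along the sweep the crossing
occurs. Pulsed interleaved excitation separates the two colors into
alternating 12.5 ns micro-time gates, making the two detection channels
crosstalk-free.

The analysis chain implemented here — gating, z-mapping, kymograph,
membrane tracking, background and photobleaching corrections,
correlation, model fits, and the binding isotherm — is validated
end-to-end against a photon-level simulator whose every ingredient is
part of the package and tested.

## Correlation models

For a circular observation area of 1/e² waist $\omega_0$ on the
membrane and 2D diffusion, the autocorrelation is
$G(\tau) = N^{-1}(1+\tau/\tau_D)^{-1}$ with $N = C\,\pi\omega_0^2$ the
mean number of fluorescent molecules in the area and
$\tau_D = \omega_0^2/4D$. Lateral line scanning instead sweeps an area
elongated along the optical axis; its correlation carries the extra
factor $(1+S^2\tau/\tau_D)^{-1/2}$ with $S=\omega_0/z_0$, and the extra
parameter makes fits more ambiguous — one reason axial scanning reaches
a given precision in several-fold less acquisition time, which the
package demonstrates with paired simulations (`sdVsTime()`).

Amplitudes of the three curves combine into
$$\Gamma(C_L) = \frac{G_\times(0)^2}{G_G(0)\,G_R(0)}
             = A\,\beta\,\frac{1}{1+K_D/C_L},$$
with $A = A_G A_R / A_{\rm eff}^2$,
$A_{\rm eff}=\pi(\omega_G^2+\omega_R^2)/2$. $A$ is computed from the
calibration, never fitted; for the default waists (207 nm, 251 nm) it
is 0.964. The uncorrelated-background correction factors of the three
amplitudes cancel in $\Gamma$, which the acceptance suite verifies by
fitting the same simulated series with background subtraction switched
on and off at a signal-to-background ratio of about three.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `omegaG`, `omegaR` | 207, 251 nm | lateral 1/e² waists (calibrated from 100-nm bead scans via FWHM² = FWHM_m² − d², ω₀ = FWHM/√(2 ln 2)) |
| `z0G`, `z0R` | 5·ω | axial 1/e² half-lengths; the axial extension of a confocal spot is about five times the lateral one |
| `tagFrequency` | 147 kHz | axial resonance; one membrane crossing per half period (~3.4 µs) |
| `tagAmplitude × driveFraction` | 3.53 µm × 0.75 | sweep amplitude a = 2.65 µm, i.e. a 5.3 µm span |
| `pieWindow` | 12.5 ns | PIE gate boundary; green gate [0, 12.5), red [12.5, 25) ns, half-open |
| `nPixels` | 26 | z pixels over the sweep (~0.2 µm/pixel, so ±10 pixels ≈ 2 µm) |
| `halfwidth` | 2 px | membrane signal window: ridge ± 2 pixels (5 pixels total) |
| `offset` | 10 px | background regions: 1 pixel, ±10 pixels from each tracked membrane |
| `binWidth` | 0.1 ms | correlation time base; ≥300× shorter than typical τ_D (30–50 ms) |
| `coarseLineTime` | 0.5 s | tracking/display kymograph line time |
| `maxLag` | min(10 s, T/4) | multi-tau lag range, m = 16 lags per doubling stage |

## The synthetic-data generator

`simulateTrajectories()` places Poisson numbers of particles per species
on a periodic membrane patch, assigns label states with the maturation
yields (η_G = 0.9 for the green, η_R = 0.5 for the red fluorescent
protein by default) and propagates 2D Brownian motion.
`simulatePhotons()` sweeps 3D Gaussian observation volumes along
z(t) = a sin(2πft), emitting Poisson photons with mean
brightness × exp(−2r²/ω²) × (axial transit dose per cycle, integrated
numerically), adds homogeneous Poisson background, bleaches each
fluorophore once its accumulated exposure crosses an exponential
threshold, and encodes channel identity in PIE micro times. Default
densities (~45 labeled receptors µm⁻²), diffusion (0.35 µm² s⁻¹),
per-molecule count rates (a few kHz) and bleach cross sections are
chosen to emulate a stably transfected cell line; the bleach defaults
were set so that a default 60-s scan yields time-averaged correction
factors ⟨γ⟩ ≈ 1.2–1.6, the range reported for such recordings.

What the generator does **not** emulate: explicit 3D diffusion of free
ligand in the medium (its fast, uncorrelated contribution on the
millisecond correlation scale is folded into the background rate),
triplet/blinking photophysics, vectorial-diffraction PSF shapes, and
detector dead time. Passing tests therefore demonstrate correctness of
the analysis chain under idealized Gaussian optics and memoryless
photophysics, not robustness to every instrumental artifact of real
recordings.

Two deliberate deviations from a brute-force implementation keep the
simulator tractable without touching the membrane-signal statistics:

* **Trajectory time base.** Positions advance on a configurable
  `timeStep` (default 0.1 ms, the correlation bin width) rather than
  once per 3.4-µs crossing; the r.m.s. displacement per step (~9 nm) is
  far below the 207-nm waist, and photon phases within a step are drawn
  from the exact axial-profile distribution, so per-crossing structure
  in the photon stream is preserved. Validation runs use 0.5–1 ms steps
  with the correlation bin width matched.
* **Brownian-bridge chunks.** Chunk boundary positions are drawn
  directly (the sum of n steps is Gaussian) and within-chunk paths are
  re-materialized as Brownian bridges from stored sub-seeds — a
  distributionally exact construction verified against the 4DΔt law at
  lags from one step to thousands.

## Numerical choices

* **Six-sine smoothing.** Background traces and the bleaching ratio
  I'(0)/I'(t) are fitted with a₁sin(b₁t+c₁)+…+a₆sin(b₆t+c₆). The first
  term is pinned at zero frequency (a pure DC term); the remaining
  frequencies are bounded to [0.25, 3] cycles per trace for correction
  purposes — a near-zero free frequency with free amplitude degenerates
  into an unbounded polynomial, and frequencies above a few cycles per
  trace would let the "smooth" curve follow genuine diffusion
  fluctuations and distort the correlations. Initialization is
  spectral (largest discrete-spectrum components), refined by
  Levenberg–Marquardt from several starts; if nothing converges a
  monotone spline is substituted and flagged.
* **Bleach-correction gate.** γ(t) is only fitted when the trace shows
  a statistically significant net decline (block-mean slope more than
  three standard errors below zero, and at least 10% total loss).
  On a stationary trace the correct correction is γ ≡ 1, and fitting
  γ to slow occupancy fluctuations — which mimic decay on short
  recordings — would corrupt the amplitudes it is meant to fix. The
  smoothed denominator is floored at 20% of the trace mean and γ is
  clipped to [0.2, 5].
* **Baseline term in correlation fits.** On short recordings the
  normalization of the correlation estimator biases all lags by a small
  common constant (of order −2G₀(τ_D/T)ln(T/τ_D), plus a −1/M term for
  a closed simulation patch). Fits optionally include a bounded
  constant offset (|c| ≤ 0.25·G(first lag)) that absorbs it, keeping
  amplitudes unbiased; the bound prevents amplitude–offset trade-off on
  noisy curves.
* **Cross amplitude for Γ.** A free fit of a dim cross-correlation
  locks onto noise excursions and biases the amplitude upward. All
  membrane species share one diffusion coefficient, so the cross decay
  time is derived from the two autocorrelation fits and the waist
  ratio, leaving a linear, symmetric-noise amplitude estimate. The
  squared amplitude entering Γ is additionally debiased by a
  segment-based variance estimate (E[X̂²] = X² + Var X̂).
* **Weights.** Per-lag errors come from splitting each scan into six
  segments; lags longer than a quarter segment carry three times the
  largest observed error. Isotherm fits weight points by 1/SEM² with
  the SEM floored at half the median and at 20% of the value — SEMs
  estimated from three or four scans are themselves noisy, and an
  unluckily tight one must not dominate the fit. β is constrained to
  its physical range (0, 1].
* **Scan pooling (option).** By default, per-scan Γ values are
  aggregated into mean ± SEM per concentration. `poolScans = TRUE` instead
  averages the correlation curves of the surviving scans per
  concentration before fitting amplitudes (jackknife SEMs); this
  reduces both fit noise and the squaring bias at low occupancy and is
  used by the validation suite.
* **Degenerate inputs.** Zero-mean traces, non-decaying curves, traces
  whose smoothed intensity collapses, and amplitude ratios incompatible
  with the assumed maturation yield all raise typed errors; the
  pipeline converts per-scan failures into logged exclusions and only
  aborts when fewer than three scans survive at every concentration.

## Quality control

The discard rules applied to recorded kymographs are automated as
deterministic thresholds: membrane-position SD > 2 pixels
(`fluctuating_membrane`), mean ridge distance from the sweep center
> 25% of the pixel range (`off_center`), samples above
median + 8·MAD for ≥ 2 consecutive tracking lines (`bright_cluster`),
and mean signal below twice the mean background (`low_signal`). Scans
whose diffusion fits disagree between the color channels by more than a
factor three in τ_D, or whose τ_D leaves [1 ms, 1 s], are excluded from
binding curves, as are non-finite or unphysically large Γ values
(> 1.5; Γ is bounded by A ≤ 1). All thresholds are configurable.

## Validation problem sizes

The test and acceptance suites run the simulator at reduced scale:
amplitude-oracle scans of 6 s on a 5 µm patch over 20 seeds, K_D
recovery series of six concentrations × four 30-s scans at K_D ∈
{0.1, 1, 10} nM on a 2.5 µm patch with a half-labeled receptor pool
(β = 0.5), background-robustness series at a signal-to-background ratio
of ~3, and a 60-s default-parameter scan for the ⟨γ⟩ range. The
recovery series disable bleaching so that binding estimation is
validated orthogonally to the bleaching correction, which has its own
closed-form and envelope tests. Concentration grids span ±0.9 decades
around K_D: the isotherm needs both the transition and the approach to
its plateau to separate K_D from β.

## Known limitations

* Fitted amplitudes carry a small (few percent) downward bias on short
  recordings because segment-based weights are estimated from the same
  data; it is negligible at the 60-s scans the method is designed for.
* Γ values at very low occupancy (≲1 green molecule per observation
  area) are noisy and, averaged over few scans, heavy-tailed; the
  binding fit guards against this with SEM floors and the pooled
  aggregation mode.
* The simulator's maturation and bleaching are independent per label;
  correlated photophysics (e.g. dark-state conversion coupled between
  tandem fluorophores) is out of scope.
* The phase→z mapping is assumed ideally sinusoidal; a measured
  calibration table can override it (`zMapping(calibration = )`), but
  none ships with the package.
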