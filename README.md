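# axialFCS

Dual-color **axial line-scanning fluorescence correlation spectroscopy
(lsFCS)** analysis for measuring ligand–receptor binding affinities on
live-cell membranes.

In axial lsFCS a confocal observation volume is swept sinusoidally along
the optical axis through the plasma membrane at ~147 kHz by a resonant
acoustic lens, so that membrane movement no longer corrupts the
fluorescence fluctuation signal. With pulsed interleaved excitation, a
green-labeled ligand and a red-labeled receptor are read out
crosstalk-free in two micro-time gates. This package implements the full
analysis chain from the time-tagged photon stream to the equilibrium
dissociation coefficient:

1. **Photon processing** — PIE channel gating, phase→z mapping of the
   sinusoidal sweep, kymograph construction with dwell-time rescaling.
2. **Membrane extraction** — ridge tracking, 5-pixel signal integration,
   four 1-pixel background regions ±10 pixels from the membrane,
   automated quality control.
3. **Corrections** — background subtraction and photobleaching
   compensation. The decaying trace is rescaled by a smooth correction
   function γ(t) (a sum of six sines fitted to I'(0)/I'(t)); its time
   average ⟨γ⟩ rescales autocorrelation amplitudes.
4. **Correlation** — multi-tau auto- and cross-correlation,

   G_C(τ) = ⟨γ⟩⁻¹ (⟨I_C(t) I_C(t+τ)⟩/⟨I_C⟩² − 1),   C ∈ {G, R},
   G_×(τ) = ⟨I_G(t) I_R(t+τ)⟩/(⟨I_G⟩⟨I_R⟩) − 1,

   with segment-split error bars; diffusion-model fits
   G(τ) = N⁻¹(1 + τ/τ_D)⁻¹ (circular observation area) and the
   elongated-area variant with anisotropy S = ω₀/z₀.
5. **Binding analysis** — the amplitude statistic

   Γ(C_L) = G_×(0)² / (G_G(0) G_R(0)) = A·β · 1/(1 + K_D/C_L),

   a scaled binding isotherm that is robust against uncorrelated
   background. A = A_G·A_R/A_eff² is the two-color observation-area
   factor and β the fraction of binding-competent receptors carrying a
   mature red tag. Nonlinear least squares on Γ(C_L) yields K_D and β;
   maturation-yield corrections and heterodimer bound fractions
   (F_R, F_G) are included.
6. **Simulator** — a photon-level Monte-Carlo model of the experiment
   (2D Brownian membrane diffusion, 3D Gaussian observation volume swept
   sinusoidally in z, Poisson emission, maturation, bleaching,
   background, drift), used as the ground-truth generator for every
   validation test.

## Worked example

```r
library(axialFCS)

## observation-area arithmetic from the calibrated waists (nm)
cal <- waistCalibration(207, 251)
cal
#> OpticsCalibration
#>   omega0: G 207.0 nm, R 251.0 nm
#>   areas: A_G 0.1346, A_R 0.1979, A_eff 0.1663 um^2
#>   A_eff/A_G = 1.235, A_eff/A_R = 0.840, A = 0.9638

## simulate a 60-s axial scan of a membrane carrying dual-labeled
## receptor-ligand complexes, then run the per-scan analysis
cfg <- simConfig(densities = c(R = 22, RL = 22), seed = 1, duration = 10)
stream <- simulatePhotons(simulateTrajectories(cfg), opticsConfig(), cfg)
scan <- processScan(stream, cal)
scan$amplitudes        # fitted G_G(0), G_R(0), G_x(0)
scan$gamma             # the Gamma statistic of this scan
scan$density           # labeled-molecule densities (um^-2)
scan$diffusion         # D = omega0^2 / (4 tauD) per channel

## a full concentration series (4 replicate scans per concentration)
## and the K_D fit
datasets <- list()
for (r in 1:4) {
  cfg <- simConfig(densities = c(R = 40, dark = 40), kD = 1,
                   cLSeries = 10^seq(-0.9, 0.9, length.out = 6),
                   boxSide = 2.5, duration = 30, timeStep = 1e-3,
                   etaG = 1, etaR = 1, brightness = c(G = 0.03, R = 0.024),
                   bleachCrossSection = 0, backgroundRate = c(G = 1, R = 1),
                   seed = 40 + r)
  for (el in makeBindingSeries(cfg, opticsConfig()))
    datasets[[length(datasets) + 1]] <- list(stream = el$stream, cL = el$cL)
}
run <- runPipeline(datasets, cal, binWidth = 1e-3, poolScans = TRUE)
run$fit
#> IsothermFit: K_D = 1.19 +- 0.42 nM, beta = 0.513 +- 0.09 (A = 0.964)
```

The fitted K_D recovers the simulated 1 nM dissociation coefficient
within its standard error, and β ≈ 0.5 reflects that half of the
receptor pool carries no red label in this simulation. This snippet is
the same configuration the validation suite runs at K_D = 0.1, 1 and
10 nM.

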