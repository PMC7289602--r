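#' @include AllClasses.R
NULL

#' Construct an OpticsConfig
#'
#' Defaults describe a dual-color confocal with a resonant axial scanner:
#' calibrated waists of 207 nm (green, 470 nm excitation) and 251 nm (red,
#' 561 nm excitation), an axial extension about five times the lateral one,
#' a 147 kHz resonance (period ~6.8 us) driven at 75% of the maximum
#' amplitude so that the sweep spans about 5.3 um, and 12.5 ns pulsed
#' interleaved excitation gates.
#'
#' @param omegaG,omegaR lateral 1/e^2 waists (nm)
#' @param z0G,z0R axial 1/e^2 half-lengths (nm)
#' @param tagFrequency axial resonance frequency (kHz)
#' @param tagAmplitude peak axial excursion at full drive (um)
#' @param driveFraction fraction of the maximum drive amplitude
#' @param pieWindow PIE gate boundary (ns)
#' @return an \linkS4class{OpticsConfig}
#' @examples
#' opt <- opticsConfig()
#' scanPeriod(opt)       # ~6.8 us
#' sweepAmplitude(opt)   # ~2.65 um, i.e. a 5.3 um span
#' @export
opticsConfig <- function(omegaG = 207, omegaR = 251,
                         z0G = 5 * omegaG, z0R = 5 * omegaR,
                         tagFrequency = 147, tagAmplitude = 5.3 / (2 * 0.75),
                         driveFraction = 0.75, pieWindow = 12.5) {
  new("OpticsConfig", omegaG = omegaG, omegaR = omegaR, z0G = z0G, z0R = z0R,
      tagFrequency = tagFrequency, tagAmplitude = tagAmplitude,
      driveFraction = driveFraction, pieWindow = pieWindow)
}

#' Scan period and sweep amplitude of an axial scanner
#'
#' @param optics an \linkS4class{OpticsConfig}
#' @return \code{scanPeriod}: the oscillation period in microseconds
#'   (1000/frequency in kHz); \code{sweepAmplitude}: the actual sweep
#'   amplitude a = tagAmplitude * driveFraction in micrometers, so the
#'   focus spans 2a.
#' @export
scanPeriod <- function(optics) 1e3 / optics@tagFrequency

#' @rdname scanPeriod
#' @export
sweepAmplitude <- function(optics) optics@tagAmplitude * optics@driveFraction

#' Construct a SimConfig
#'
#' Defaults emulate a typical live-cell measurement: a labeled receptor
#' density around 45 um^-2 (a stably transfected cell line), membrane
#' diffusion at 0.35 um^2/s, fluorescent-protein maturation yields of 0.9
#' (eGFP) and 0.5 (mCherry-class labels), per-molecule detected count
#' rates of a few kHz, a few kHz of uncorrelated autofluorescence
#' background, mild photobleaching giving time-average correction factors
#' <gamma> around 1.2-1.6 over a 60-s scan, and a 60-s acquisition.
#'
#' @param boxSide membrane patch side (um); the patch is periodic
#' @param densities named species densities (um^-2); see
#'   \linkS4class{SimConfig} for species semantics
#' @param dCoef diffusion coefficient(s) (um^2 s^-1)
#' @param kD dissociation coefficient (nM) for binding series, or NA
#' @param cLSeries ligand concentrations (nM)
#' @param etaG,etaR maturation yields
#' @param brightness named per-channel brightness (photons per fluorophore
#'   per us at the focus center)
#' @param backgroundRate named per-channel background (kHz)
#' @param bleachCrossSection named per-channel bleaching probability per
#'   us of center-equivalent exposure
#' @param duration scan duration (s)
#' @param timeStep trajectory update interval (s)
#' @param driftAmplitude,driftPeriod slow sinusoidal membrane drift (um, s)
#' @param crosstalk green-to-red leakage fraction
#' @param lateralAspect lateral observation-area aspect ratio (1 circular)
#' @param seed integer RNG seed
#' @return a \linkS4class{SimConfig}
#' @export
simConfig <- function(boxSide = 3,
                      densities = c(R = 22, RL = 22),
                      dCoef = 0.35,
                      kD = NA_real_,
                      cLSeries = 10^seq(-2, 1, by = 0.5),
                      etaG = 0.9, etaR = 0.5,
                      brightness = c(G = 0.015, R = 0.012),
                      backgroundRate = c(G = 2, R = 2),
                      bleachCrossSection = c(G = 1.5e-5, R = 1e-5),
                      duration = 60, timeStep = 1e-4,
                      driftAmplitude = 0, driftPeriod = 20,
                      crosstalk = 0, lateralAspect = 1,
                      seed = 1L) {
  densities <- .namedPair(densities, c("R", "G", "RL", "rL", "dark"),
                          fill = 0)
  brightness <- .namedPair(brightness, c("G", "R"))
  backgroundRate <- .namedPair(backgroundRate, c("G", "R"))
  bleachCrossSection <- .namedPair(bleachCrossSection, c("G", "R"))
  new("SimConfig", boxSide = boxSide, densities = densities, dCoef = dCoef,
      kD = kD, cLSeries = cLSeries, etaG = etaG, etaR = etaR,
      brightness = brightness, backgroundRate = backgroundRate,
      bleachCrossSection = bleachCrossSection, duration = duration,
      timeStep = timeStep, driftAmplitude = driftAmplitude,
      driftPeriod = driftPeriod, crosstalk = crosstalk,
      lateralAspect = lateralAspect, seed = as.integer(seed))
}

## expand a scalar or partially named vector onto a fixed name set
.namedPair <- function(x, nms, fill = NA_real_) {
  if (is.null(names(x))) {
    if (length(x) == 1L) x <- rep(x, length(nms))
    if (length(x) != length(nms))
      stop("expected a scalar or values named among: ", paste(nms, collapse = ", "))
    names(x) <- nms
    return(x)
  }
  out <- rep(if (is.na(fill)) x[[1L]] else fill, length(nms))
  names(out) <- nms
  bad <- setdiff(names(x), nms)
  if (length(bad)) stop("unknown names: ", paste(bad, collapse = ", "))
  out[names(x)] <- x
  out
}

## derive a child seed from a base seed, kept within 32-bit integer range
.childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 9973) %% 2147483629)
}
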