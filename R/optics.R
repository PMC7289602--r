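#' @include AllClasses.R
NULL

## Observation-area arithmetic shared by both calibration constructors.
.calibFromWaists <- function(omegaG, omegaR, fwhmMeasured = c(G = NA_real_, R = NA_real_),
                             beadDiameter = NA_real_, fwhm = c(G = NA_real_, R = NA_real_)) {
  wG <- omegaG * 1e-3   # um
  wR <- omegaR * 1e-3
  aG <- pi * wG^2
  aR <- pi * wR^2
  wEff2 <- (wG^2 + wR^2) / 2
  aEff <- pi * wEff2
  new("OpticsCalibration",
      fwhmMeasured = fwhmMeasured, beadDiameter = beadDiameter, fwhm = fwhm,
      omega0 = c(G = omegaG, R = omegaR),
      areas = c(AG = aG, AR = aR, Aeff = aEff),
      ratios = c(AeffAG = aEff / aG, AeffAR = aEff / aR),
      aFactor = (aG * aR) / aEff^2)
}

#' Focus size calibration from bead scans
#'
#' Converts measured bead-image widths into observation areas. The
#' measured full width at half maximum is corrected for the finite bead
#' size, FWHM = (FWHM_m^2 - d^2)^(1/2), and converted to the 1/e^2 waist
#' omega_0 = FWHM / (2 ln 2)^(1/2). From the two waists the per-channel
#' observation areas A_C = pi omega_C^2, the effective dual-color area
#' A_eff = pi (omega_G^2 + omega_R^2)/2 and the geometric factor
#' A = A_G A_R / A_eff^2 are derived. A equals 1 for identical waists and
#' decreases as the two areas diverge.
#'
#' @param fwhmMeasured measured FWHM per channel (nm), a scalar or a
#'   vector named G/R
#' @param beadDiameter bead diameter (nm); 0 leaves the FWHM unchanged
#' @return an \linkS4class{OpticsCalibration}
#' @examples
#' calibrateFocus(c(G = 242, R = 295), beadDiameter = 0)
#' @export
calibrateFocus <- function(fwhmMeasured, beadDiameter = 100) {
  fwhmMeasured <- .namedPair(fwhmMeasured, c("G", "R"))
  if (any(!is.finite(fwhmMeasured)) || any(fwhmMeasured <= 0))
    stop("fwhmMeasured must be positive")
  if (beadDiameter < 0 || any(fwhmMeasured <= beadDiameter))
    stop("fwhmMeasured must exceed the bead diameter")
  fwhm <- sqrt(fwhmMeasured^2 - beadDiameter^2)
  om <- fwhm / sqrt(2 * log(2))
  .calibFromWaists(om[["G"]], om[["R"]], fwhmMeasured = fwhmMeasured,
                   beadDiameter = beadDiameter, fwhm = fwhm)
}

#' Observation areas from known waists
#'
#' @param omegaG,omegaR 1/e^2 waists (nm)
#' @return an \linkS4class{OpticsCalibration}
#' @examples
#' cal <- waistCalibration(207, 251)
#' obsAreas(cal)["Aeff"] / obsAreas(cal)["AG"]   # ~1.23
#' @export
waistCalibration <- function(omegaG, omegaR) {
  if (omegaG <= 0 || omegaR <= 0) stop("waists must be > 0")
  .calibFromWaists(omegaG, omegaR)
}

#' Observation area of a circular focus
#'
#' A = pi omega_0^2, the membrane area sampled by the scanned focus.
#'
#' @param omega0um 1/e^2 waist in micrometers
#' @return area in um^2
#' @examples
#' observationArea(0.25)   # ~0.20 um^2
#' @export
observationArea <- function(omega0um) {
  if (any(omega0um <= 0)) stop("omega0 must be > 0")
  pi * omega0um^2
}
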