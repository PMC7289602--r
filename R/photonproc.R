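#' @include config.R
NULL

#' Split a photon stream into the two PIE color channels
#'
#' Pulsed interleaved excitation separates the two colors into consecutive
#' micro-time windows: photons with micro time in [0, pieWindow) ns belong
#' to the green channel, photons in [pieWindow, 25) ns to the red channel.
#' The gates are half-open, so every photon lands in exactly one channel.
#'
#' @param stream a \linkS4class{PhotonStream}
#' @param pieWindow gate boundary (ns); defaults to the stream's optics
#' @return named list of event data.frames, \code{G} and \code{R}
#' @export
gateChannels <- function(stream, pieWindow = stream@optics@pieWindow) {
  if (pieWindow <= 0 || pieWindow >= 25)
    stop("pieWindow must lie strictly inside (0, 25) ns")
  ev <- stream@events
  g <- ev$micro_time_ns < pieWindow
  list(G = ev[g, , drop = FALSE], R = ev[!g, , drop = FALSE])
}

#' Map oscillation phase to axial focus position
#'
#' For the ideal resonant scanner the focus follows
#' z = a sin(2 pi phase) with a the sweep amplitude, so the sweep center
#' is crossed at phases 0 and 0.5 and the turning points sit at phases
#' 0.25 and 0.75. The sweep direction is "up" for phase in
#' [0.75, 1) or [0, 0.25) and "down" otherwise.
#'
#' @param phase oscillation phase(s) in [0, 1)
#' @param optics an \linkS4class{OpticsConfig}
#' @return data.frame with columns \code{z} (um) and \code{direction}
#' @export
mapPhaseToZ <- function(phase, optics) {
  if (any(phase < 0 | phase >= 1)) stop("phase must lie in [0, 1)")
  a <- sweepAmplitude(optics)
  data.frame(z = a * sin(2 * pi * phase),
             direction = ifelse(phase < 0.25 | phase >= 0.75, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Build the phase-to-z mapping and dwell-weight calibration
#'
#' Divides the axial sweep range [-a, a] into \code{nPixels} uniform z
#' pixels and computes the relative dwell time per pixel. For the
#' sinusoidal sweep the time spent in [z1, z2] per half cycle is
#' (asin(z2/a) - asin(z1/a))/pi, which diverges toward the turning
#' points; dwell weights at the edges are therefore capped at five times
#' the center-pixel weight (the membrane is kept near the sweep center,
#' so the edge pixels never carry signal). Weights are normalized to mean
#' one. A measured calibration can be supplied as a function
#' phase -> z (um), overriding the sinusoid.
#'
#' @param optics an \linkS4class{OpticsConfig}
#' @param nPixels number of z pixels (default 26, ~0.2 um per pixel over
#'   a 5.3 um span so that 10 pixels is about 2 um)
#' @param calibration optional function(phase) -> z (um)
#' @param dwellCap cap on edge dwell weights, in units of the
#'   center-pixel weight
#' @return a \linkS4class{ZMapping}
#' @export
zMapping <- function(optics, nPixels = 26L, calibration = NULL,
                     dwellCap = 5) {
  a <- sweepAmplitude(optics)
  edges <- seq(-a, a, length.out = nPixels + 1L)
  if (is.null(calibration)) {
    frac <- (asin(pmin(1, pmax(-1, edges / a)))) / pi   # cumulative time fraction
    dwell <- diff(frac)
  } else {
    phi <- (seq_len(8192L) - 0.5) / 8192L
    z <- calibration(phi)
    px <- pmin(pmax(findInterval(z, edges), 1L), nPixels)
    dwell <- tabulate(px, nPixels) / length(phi)
  }
  dwell[dwell <= 0] <- min(dwell[dwell > 0])
  ctr <- min(dwell)
  dwell <- pmin(dwell, dwellCap * ctr)
  dwell <- dwell / mean(dwell)
  new("ZMapping", amplitude = a, pixelEdges = edges, dwellWeight = dwell,
      calibration = calibration)
}

## z position of photons from their tag phase under a mapping
.photonZ <- function(phase, mapping) {
  if (is.null(mapping@calibration))
    mapping@amplitude * sin(2 * pi * phase)
  else mapping@calibration(phase)
}

#' Build a kymograph from photon events
#'
#' Histograms photons into (scan line, z pixel) bins. Both half-cycle
#' crossings of an oscillation accumulate into the same z pixels. The
#' dwell-rescaled matrix \code{counts} equals the raw histogram divided by
#' the per-pixel dwell weights, compensating the nonuniform speed of the
#' sweep; the raw histogram is kept alongside so the rescaling is
#' invertible.
#'
#' @param x a \linkS4class{PhotonStream} (both channels are gated and
#'   binned) or a single-channel event data.frame from
#'   \code{\link{gateChannels}}
#' @param mapping a \linkS4class{ZMapping}
#' @param lineTime line duration (s); must cover several scan periods
#' @param duration total acquisition duration (s); taken from the stream
#'   metadata, or the last photon, when NULL
#' @param channel channel name used when \code{x} is an event data.frame
#' @return a \linkS4class{Kymograph}
#' @export
buildKymograph <- function(x, mapping, lineTime = 0.5, duration = NULL,
                           channel = "G") {
  if (is(x, "PhotonStream")) {
    if (is.null(duration)) duration <- x@info$duration
    subsets <- gateChannels(x)
  } else {
    subsets <- stats::setNames(list(x), channel)
  }
  if (is.null(duration)) {
    mx <- max(0, unlist(lapply(subsets, function(s) s$macro_time_ns)))
    duration <- mx * 1e-9
  }
  if (duration <= 0) duration <- lineTime
  nLn <- as.integer(ceiling(duration / lineTime - 1e-9))
  np <- length(mapping@pixelEdges) - 1L

  raw <- counts <- list()
  empty <- logical(0)
  for (ch in names(subsets)) {
    ev <- subsets[[ch]]
    if (nrow(ev)) {
      line <- pmin(floor(ev$macro_time_ns * 1e-9 / lineTime) + 1L, nLn)
      z <- .photonZ(ev$tag_phase, mapping)
      px <- pmin(pmax(findInterval(z, mapping@pixelEdges), 1L), np)
      m <- matrix(tabulate((px - 1L) * nLn + line, nLn * np), nLn, np)
    } else {
      m <- matrix(0L, nLn, np)
    }
    raw[[ch]] <- m
    counts[[ch]] <- sweep(m, 2L, mapping@dwellWeight, "/")
    empty[ch] <- sum(m) == 0L
  }
  new("Kymograph", counts = counts, raw = raw, lineTime = lineTime,
      mapping = mapping, empty = empty)
}
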