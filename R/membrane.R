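#' @include photonproc.R
NULL

#' Track membrane crossing positions in a kymograph
#'
#' The membrane shows up as a bright ridge in the kymograph; its position
#' per scan line is the pixel with the highest photon count of the
#' channel-summed, 3-line boxcar-smoothed counts. In two-membrane mode
#' (vesicle-style data with two crossings per sweep) the two highest
#' non-adjacent ridges are returned, sorted by z. Smoothing is used only
#' for localization, never for the extracted intensities.
#'
#' @param kymo a \linkS4class{Kymograph}
#' @param nRidges 1 (cell, single membrane in view) or 2 (two crossings)
#' @return a \linkS4class{MembraneTrace}
#' @export
trackMembrane <- function(kymo, nRidges = 1L) {
  M <- Reduce(`+`, kymo@counts)
  nLn <- nrow(M); np <- ncol(M)
  if (sum(M) == 0) stop("cannot track an all-zero kymograph")
  ## 3-line boxcar along time, ends use the available neighbors
  sm <- M
  if (nLn >= 3L) {
    sm <- (rbind(M[1L, , drop = FALSE], M[-nLn, , drop = FALSE]) + M +
           rbind(M[-1L, , drop = FALSE], M[nLn, , drop = FALSE])) / 3
  }
  pos <- matrix(NA_real_, nLn, nRidges)
  lowSignal <- FALSE
  for (l in seq_len(nLn)) {
    v <- sm[l, ]
    if (all(v == 0)) { lowSignal <- TRUE; next }
    p1 <- which.max(v)
    if (nRidges == 1L) {
      pos[l, 1L] <- p1
    } else {
      v2 <- v
      v2[max(1L, p1 - 1L):min(np, p1 + 1L)] <- -Inf
      p2 <- which.max(v2)
      pos[l, ] <- sort(c(p1, p2))
    }
  }
  ## carry positions across empty lines
  for (j in seq_len(nRidges)) {
    col <- pos[, j]
    if (anyNA(col)) {
      ok <- which(!is.na(col))
      if (!length(ok)) stop("no line with signal")
      col <- stats::approx(ok, col[ok], xout = seq_len(nLn), rule = 2,
                           method = "constant", f = 0)$y
      pos[, j] <- col
    }
  }
  new("MembraneTrace", positions = pos, lineTime = kymo@lineTime,
      nPixels = as.integer(np),
      smoothness = apply(pos, 2L, stats::sd),
      centering = mean(abs(pos - (np + 1) / 2)),
      lowSignal = lowSignal)
}

## ridge positions interpolated onto arbitrary times (s)
.ridgeAt <- function(trace, times) {
  nLn <- nrow(trace@positions)
  nR <- ncol(trace@positions)
  centers <- (seq_len(nLn) - 0.5) * trace@lineTime
  out <- vapply(seq_len(nR), function(j) {
    if (nLn == 1L) rep(trace@positions[1L, j], length(times))
    else stats::approx(centers, trace@positions[, j], xout = times,
                       rule = 2)$y
  }, numeric(length(times)))
  matrix(out, nrow = length(times), ncol = nR)
}

## sum of a pixel window around (possibly fractional) ridge positions,
## per line; returns NA where the window is clipped by the array edge
.windowSum <- function(M, ridge, halfwidth) {
  nLn <- nrow(M); np <- ncol(M)
  r <- round(ridge)
  out <- numeric(nLn)
  bad <- r - halfwidth < 1L | r + halfwidth > np
  for (off in -halfwidth:halfwidth) {
    px <- pmin(pmax(r + off, 1L), np)
    out <- out + M[cbind(seq_len(nLn), px)]
  }
  out[bad] <- NA_real_
  out
}

#' Extract the membrane signal trace from a kymograph
#'
#' Integrates, per scan line and per channel, the dwell-rescaled counts
#' over the ridge pixel and \code{halfwidth} neighbors on either side
#' (5 pixels by default). With two membranes both windows are summed into
#' one time-ordered trace. Ridge positions are interpolated onto the
#' kymograph's line times, so a trace tracked on a coarse kymograph can
#' be applied to a finely binned one.
#'
#' @param kymo a \linkS4class{Kymograph}
#' @param trace a \linkS4class{MembraneTrace}
#' @param halfwidth pixels on either side of the ridge (default 2)
#' @return list with \code{t} (line centers, s), \code{traces} (named list
#'   of per-channel numeric vectors) and \code{dropped} (logical; lines
#'   whose window was clipped by the array edge)
#' @export
extractSignal <- function(kymo, trace, halfwidth = 2L) {
  if (halfwidth < 0L) stop("halfwidth must be >= 0")
  nLn <- nLines(kymo)
  t <- (seq_len(nLn) - 0.5) * kymo@lineTime
  ridge <- .ridgeAt(trace, t)
  traces <- lapply(kymo@counts, function(M) {
    s <- 0
    for (j in seq_len(ncol(ridge)))
      s <- s + .windowSum(M, ridge[, j], halfwidth)
    s
  })
  dropped <- Reduce(`|`, lapply(traces, is.na))
  list(t = t, traces = traces, dropped = dropped)
}

#' Extract the scaled background trace
#'
#' Sums, per line, single-pixel regions placed \code{offset} pixels on
#' either side of every tracked membrane position (four 1-pixel regions
#' for two membranes, two for one) and scales the sum to the signal
#' window by the pixel-number ratio, (2 halfwidth + 1) x nRidges /
#' nRegions. Regions falling outside the pixel range are dropped and the
#' scaling is adjusted accordingly.
#'
#' @param kymo a \linkS4class{Kymograph}
#' @param trace a \linkS4class{MembraneTrace}
#' @param offset pixel offset of the background regions (default 10,
#'   about 2 um at the default pixelization)
#' @param halfwidth signal window half width the trace is scaled to
#' @return list with \code{t}, \code{traces} (per channel), and
#'   \code{droppedRegions}, the per-line count of out-of-range regions
#' @export
extractBackground <- function(kymo, trace, offset = 10L, halfwidth = 2L) {
  nLn <- nLines(kymo); np <- nPixels(kymo)
  t <- (seq_len(nLn) - 0.5) * kymo@lineTime
  ridge <- .ridgeAt(trace, t)
  nSig <- (2L * halfwidth + 1L) * ncol(ridge)

  regions <- list()
  for (j in seq_len(ncol(ridge))) {
    regions[[length(regions) + 1L]] <- round(ridge[, j]) - offset
    regions[[length(regions) + 1L]] <- round(ridge[, j]) + offset
  }
  valid <- lapply(regions, function(px) px >= 1L & px <= np)
  nValid <- Reduce(`+`, lapply(valid, as.integer))
  droppedRegions <- length(regions) - nValid
  if (any(nValid == 0L))
    stop("all background regions fall outside the kymograph")

  traces <- lapply(kymo@counts, function(M) {
    s <- numeric(nLn)
    for (k in seq_along(regions)) {
      px <- pmin(pmax(regions[[k]], 1L), np)
      v <- M[cbind(seq_len(nLn), px)]
      v[!valid[[k]]] <- 0
      s <- s + v
    }
    s * nSig / nValid
  })
  list(t = t, traces = traces, droppedRegions = droppedRegions)
}

#' Automated scan quality control
#'
#' Automates the visual discard rules applied to recorded kymographs:
#' \itemize{
#'   \item \code{fluctuating_membrane}: membrane position SD above
#'     \code{maxPositionSD} pixels;
#'   \item \code{off_center}: mean ridge distance from the sweep center
#'     above \code{maxCenterFrac} of the pixel range (the membrane must
#'     stay near the middle of the oscillation range);
#'   \item \code{bright_cluster}: signal samples above
#'     median + \code{clusterMADs} x MAD for at least two consecutive
#'     lines at the tracking line time (a bright feature comoving with
#'     the membrane);
#'   \item \code{low_signal}: mean signal below \code{minSignalRatio} x
#'     mean background.
#' }
#' All thresholds are deterministic functions of the scan.
#'
#' @param kymo the tracking \linkS4class{Kymograph}
#' @param trace its \linkS4class{MembraneTrace}
#' @param signal,bg outputs of \code{\link{extractSignal}} and
#'   \code{\link{extractBackground}} (any binning; signal is rebinned to
#'   the kymograph line time for the cluster test)
#' @param maxPositionSD,maxCenterFrac,clusterMADs,minSignalRatio
#'   thresholds, see above
#' @return a \linkS4class{QCReport}
#' @export
qcChecks <- function(kymo, trace, signal, bg,
                     maxPositionSD = 2, maxCenterFrac = 0.25,
                     clusterMADs = 8, minSignalRatio = 2) {
  np <- nPixels(kymo)
  posSD <- max(trace@smoothness)
  center <- trace@centering

  ## rebin a fine trace onto the tracking line time
  rebin <- function(x, tIn) {
    idx <- pmin(floor(tIn / kymo@lineTime) + 1L, nLines(kymo))
    as.numeric(tapply(x, idx, mean))
  }
  clusterRuns <- 0
  for (ch in names(signal$traces)) {
    v <- signal$traces[[ch]]
    v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    if (length(v) != nLines(kymo)) v <- rebin(v, signal$t)
    thr <- stats::median(v) + clusterMADs * stats::mad(v)
    r <- rle(v > thr)
    hits <- r$lengths[r$values]
    if (length(hits)) clusterRuns <- max(clusterRuns, max(hits))
  }

  meanSig <- mean(unlist(lapply(signal$traces, mean, na.rm = TRUE)))
  meanBg <- mean(unlist(lapply(bg$traces, mean, na.rm = TRUE)))

  flags <- c(
    bright_cluster = clusterRuns >= 2,
    fluctuating_membrane = posSD > maxPositionSD,
    off_center = center > maxCenterFrac * np,
    low_signal = trace@lowSignal || meanSig < minSignalRatio * meanBg
  )
  evidence <- c(
    bright_cluster = clusterRuns,
    fluctuating_membrane = posSD,
    off_center = center / np,
    low_signal = if (meanBg > 0) meanSig / meanBg else Inf
  )
  new("QCReport", flags = flags, evidence = evidence, pass = !any(flags))
}

#' Photon stream to intensity traces
#'
#' The extraction stage of the pipeline: gates a photon stream into the
#' two color channels, builds a coarse kymograph for membrane tracking
#' and quality control, a finely binned kymograph for the intensity
#' traces, and extracts membrane signal and scaled background per
#' channel.
#'
#' @param stream a \linkS4class{PhotonStream}
#' @param mapping a \linkS4class{ZMapping}; default from the stream optics
#' @param coarseLineTime tracking/kymograph display binning (s)
#' @param binWidth fine trace bin width (s), the correlation time base
#' @param halfwidth signal window half width (pixels)
#' @param offset background region offset (pixels)
#' @param nRidges membranes in view (1 or 2)
#' @param qc logical; run \code{\link{qcChecks}}
#' @return an \linkS4class{IntensityTraces}; the tracking kymograph and
#'   membrane trace are attached in \code{meta}
#' @export
extractIntensityTraces <- function(stream, mapping = zMapping(stream@optics),
                                   coarseLineTime = 0.5, binWidth = 1e-4,
                                   halfwidth = 2L, offset = 10L,
                                   nRidges = 1L, qc = TRUE) {
  coarse <- buildKymograph(stream, mapping, lineTime = coarseLineTime)
  trace <- trackMembrane(coarse, nRidges = nRidges)
  fine <- buildKymograph(stream, mapping, lineTime = binWidth)
  sig <- extractSignal(fine, trace, halfwidth = halfwidth)
  bg <- extractBackground(fine, trace, offset = offset,
                          halfwidth = halfwidth)
  report <- if (qc) qcChecks(coarse, trace, sig, bg) else NULL

  raw <- lapply(sig$traces, function(v) {
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    v
  })
  new("IntensityTraces", t = sig$t, sampleTime = binWidth,
      raw = raw, bg = bg$traces, qc = report,
      meta = list(halfwidth = halfwidth, offset = offset,
                  nRidges = nRidges, nDropped = sum(sig$dropped),
                  trackingKymograph = coarse, membraneTrace = trace))
}
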