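#' @include AllClasses.R
NULL

## symmetrically normalized correlation at integer lag k (in bins):
## G = <Y1(t) Y2(t+k)> / (<Y1>_left <Y2>_right) - 1
.pairCorr <- function(y1, y2, k) {
  n <- length(y1)
  if (k >= n - 1L) return(NA_real_)
  x <- y1[seq_len(n - k)]
  z <- y2[(k + 1L):n]
  mx <- mean(x); mz <- mean(z)
  if (mx == 0 || mz == 0) stop("zero-mean trace: correlation undefined")
  mean(x * z) / (mx * mz) - 1
}

## rebin a trace by averaging pairs (multi-tau coarsening step)
.coarsen <- function(y) {
  n <- length(y) %/% 2L
  (y[2L * seq_len(n) - 1L] + y[2L * seq_len(n)]) / 2
}

## multi-tau cascade: m linear lags, then m/2 lags per doubling stage
.multiTauLags <- function(n, m, maxLagBins) {
  lags <- list(); bs <- 1L; stage <- 0L
  repeat {
    ls <- if (stage == 0L) seq_len(m) else (m %/% 2L + 1L):m
    keep <- ls * bs <= maxLagBins & ls < n - 1L
    if (!any(keep)) break
    lags[[stage + 1L]] <- list(bs = bs, lags = ls[keep])
    if (!all(keep) || n %/% 2L < 2L * m) break
    bs <- bs * 2L; n <- n %/% 2L; stage <- stage + 1L
  }
  lags
}

#' Multi-tau correlation of one or two traces
#'
#' Computes the correlation function on a quasi-logarithmic lag grid by
#' the multi-tau cascade: \code{m} linearly spaced lags at the native bin
#' width, then \code{m/2} lags per stage with the trace rebinned by a
#' factor two between stages. At every lag the estimator is the
#' symmetrically normalized product average
#' \code{<Y1(t) Y2(t+tau)> / (<Y1> <Y2>) - 1} over the full (rebinned)
#' trace, identical to what a direct sum over the rebinned trace yields
#' (see \code{\link{directCorrelate}}).
#'
#' @param y1 trace (counts per bin)
#' @param y2 second trace for cross-correlation; NULL autocorrelates y1
#' @param binWidth bin width (s)
#' @param m lags per stage (default 16)
#' @param maxLag largest lag (s); default a quarter of the trace
#' @return data.frame with \code{tau} (s), \code{G}, and \code{binFactor},
#'   the rebinning factor at each lag
#' @export
multiTauCorrelate <- function(y1, y2 = NULL, binWidth, m = 16L,
                              maxLag = NULL) {
  n <- length(y1)
  if (!is.null(y2) && length(y2) != n) stop("traces must be aligned")
  if (is.null(maxLag)) maxLag <- n * binWidth / 4
  maxLagBins <- max(1, floor(maxLag / binWidth))
  plan <- .multiTauLags(n, as.integer(m), maxLagBins)
  if (!length(plan)) stop("trace too short for the requested lags")

  a <- y1; b <- if (is.null(y2)) y1 else y2
  out <- list()
  for (st in seq_along(plan)) {
    if (st > 1L) { a <- .coarsen(a); b <- if (is.null(y2)) a else .coarsen(b) }
    bs <- plan[[st]]$bs
    G <- vapply(plan[[st]]$lags, function(k) .pairCorr(a, b, k), 0)
    out[[st]] <- data.frame(tau = plan[[st]]$lags * bs * binWidth, G = G,
                            binFactor = bs)
  }
  do.call(rbind, out)
}

#' Direct-sum reference correlator
#'
#' Brute-force O(n^2) evaluation of the same estimator as
#' \code{\link{multiTauCorrelate}}: the trace is explicitly rebinned by
#' each requested bin factor and all sums are accumulated in plain loops.
#' Used as the independent oracle for the multi-tau cascade; the two must
#' agree to floating-point precision on shared lags.
#'
#' @param y1,y2 traces (y2 NULL autocorrelates)
#' @param binWidth bin width (s)
#' @param lagBins integer lags, in units of the rebinned width
#' @param binFactor rebinning factor per lag (same length as lagBins)
#' @return data.frame with \code{tau} and \code{G}
#' @export
directCorrelate <- function(y1, y2 = NULL, binWidth, lagBins,
                            binFactor = rep(1L, length(lagBins))) {
  if (is.null(y2)) y2 <- y1
  rebin <- function(y, f) {
    if (f == 1L) return(y)
    nb <- length(y) %/% f
    out <- numeric(nb)
    for (i in seq_len(nb)) {
      s <- 0
      for (j in seq_len(f)) s <- s + y[(i - 1L) * f + j]
      out[i] <- s / f
    }
    out
  }
  G <- numeric(length(lagBins))
  for (q in seq_along(lagBins)) {
    f <- binFactor[q]; k <- lagBins[q]
    a <- rebin(y1, f); b <- rebin(y2, f)
    n <- length(a)
    sxz <- sx <- sz <- 0
    for (t in seq_len(n - k)) {
      sxz <- sxz + a[t] * b[t + k]
      sx <- sx + a[t]
      sz <- sz + b[t + k]
    }
    nn <- n - k
    G[q] <- (sxz / nn) / ((sx / nn) * (sz / nn)) - 1
  }
  data.frame(tau = lagBins * binFactor * binWidth, G = G)
}

#' Autocorrelation with photobleaching amplitude rescaling
#'
#' G_C(tau) = (1/<gamma>) (<I(t) I(t+tau)> / <I>^2 - 1). The prefactor
#' 1/<gamma(t)> corrects the amplitude for the loss of fluorophores to
#' photobleaching and applies to autocorrelations only.
#'
#' @param i corrected intensity trace
#' @param gammaMean time average of the bleaching correction function
#' @param binWidth bin width (s)
#' @param ... passed to \code{\link{multiTauCorrelate}}
#' @return data.frame with \code{tau}, \code{G}
#' @export
autocorrelate <- function(i, gammaMean = 1, binWidth, ...) {
  mt <- multiTauCorrelate(i, NULL, binWidth = binWidth, ...)
  data.frame(tau = mt$tau, G = mt$G / gammaMean)
}

#' Dual-color cross-correlation
#'
#' G_x(tau) = <I_G(t) I_R(t+tau)> / (<I_G> <I_R>) - 1. No bleaching
#' rescaling is applied: photobleaching reduces numerator and denominator
#' to equal extents, so the effect cancels.
#'
#' @param iG,iR corrected green and red traces
#' @param binWidth bin width (s)
#' @param ... passed to \code{\link{multiTauCorrelate}}
#' @return data.frame with \code{tau}, \code{G}
#' @export
crosscorrelate <- function(iG, iR, binWidth, ...) {
  mt <- multiTauCorrelate(iG, iR, binWidth = binWidth, ...)
  data.frame(tau = mt$tau, G = mt$G)
}

#' Correlate a corrected scan
#'
#' Computes G_G, G_R (gamma-rescaled) and G_x on a common multi-tau lag
#' grid, with per-lag uncertainties from splitting the scan into
#' \code{nSegments} equal segments (SD of the per-segment estimates
#' divided by sqrt(nSegments)). Lags longer than a quarter segment have
#' no segment-based error and carry NA.
#'
#' @param state a \linkS4class{CorrectionState}
#' @param m lags per multi-tau stage
#' @param maxLag largest lag (s); default min(10 s, T/4)
#' @param nSegments segments for the error estimate
#' @param scanId identifier stored in the metadata
#' @return a \linkS4class{CorrelationSet}
#' @export
correlateTraces <- function(state, m = 16L, maxLag = NULL, nSegments = 6L,
                            scanId = NA_character_) {
  iG <- state@corrected[["G"]]; iR <- state@corrected[["R"]]
  bw <- state@sampleTime
  T <- length(iG) * bw
  if (is.null(maxLag)) maxLag <- min(10, T / 4)

  full <- list(
    G = autocorrelate(iG, state@gammaMean[["G"]], bw, m = m, maxLag = maxLag),
    R = autocorrelate(iR, state@gammaMean[["R"]], bw, m = m, maxLag = maxLag),
    x = crosscorrelate(iG, iR, bw, m = m, maxLag = maxLag))
  tau <- full$G$tau

  err <- lapply(full, function(f) rep(NA_real_, length(tau)))
  if (nSegments >= 2L) {
    segLen <- length(iG) %/% nSegments
    if (segLen * bw / 4 >= tau[1L]) {
      segMax <- segLen * bw / 4
      acc <- lapply(full, function(f) matrix(NA_real_, nSegments, length(tau)))
      for (s in seq_len(nSegments)) {
        idx <- (s - 1L) * segLen + seq_len(segLen)
        sg <- tryCatch(list(
          G = autocorrelate(iG[idx], state@gammaMean[["G"]], bw, m = m,
                            maxLag = segMax),
          R = autocorrelate(iR[idx], state@gammaMean[["R"]], bw, m = m,
                            maxLag = segMax),
          x = crosscorrelate(iG[idx], iR[idx], bw, m = m, maxLag = segMax)),
          error = function(e) NULL)
        if (is.null(sg)) next
        for (ch in names(acc)) {
          mi <- match(round(sg[[ch]]$tau, 12), round(tau, 12))
          ok <- !is.na(mi)
          acc[[ch]][s, mi[ok]] <- sg[[ch]]$G[ok]
        }
      }
      for (ch in names(acc)) {
        nOk <- colSums(!is.na(acc[[ch]]))
        sdv <- apply(acc[[ch]], 2L, stats::sd, na.rm = TRUE)
        err[[ch]] <- ifelse(nOk >= 2L, sdv / sqrt(pmax(nOk, 1L)), NA_real_)
      }
      segments <- acc
    }
  }
  if (!exists("segments", inherits = FALSE)) segments <- NULL

  new("CorrelationSet", tau = tau,
      G = lapply(full, `[[`, "G"), err = err,
      meta = list(binWidth = bw, gammaMean = state@gammaMean,
                  nSegments = nSegments, scanId = scanId,
                  segments = segments))
}

#' Curve scatter as a function of acquisition time
#'
#' Quantifies the precision of correlation curves by the standard
#' deviation of each curve around the group average,
#' SD_i = sqrt(mean_tau (G_i(tau) - Gbar(tau))^2), after normalizing each
#' curve to amplitude one (division by its fitted zero-lag amplitude).
#' Applied to groups of curves computed from increasingly longer
#' stretches of data, this traces how precision improves with total
#' acquisition time.
#'
#' @param curveSets named list (one element per duration) of lists of
#'   curves, each a data.frame with \code{tau} and \code{G} on a common
#'   lag grid within a group
#' @param normalize divide each curve by its fitted amplitude first
#' @return data.frame with \code{duration}, \code{sd} (ensemble mean of
#'   SD_i) and \code{sdSD} (ensemble SD)
#' @export
sdVsTime <- function(curveSets, normalize = TRUE) {
  res <- lapply(names(curveSets), function(nm) {
    curves <- curveSets[[nm]]
    if (length(curves) < 2L) stop("need >= 2 curves per duration")
    tau0 <- curves[[1L]]$tau
    mat <- vapply(curves, function(cv) {
      if (length(cv$tau) != length(tau0) || any(abs(cv$tau - tau0) > 1e-12))
        stop("mismatched lag grids")
      g <- cv$G
      if (normalize) {
        f <- fitCircular(cv$tau, g)
        g <- g / f@G0
      }
      g
    }, numeric(length(tau0)))
    avg <- rowMeans(mat)
    sdi <- sqrt(colMeans((mat - avg)^2))
    data.frame(duration = as.numeric(nm), sd = mean(sdi),
               sdSD = stats::sd(sdi))
  })
  do.call(rbind, res)
}
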