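#' @include AllClasses.R
NULL

## bin-average (t, y) down to about nOut points for curve fitting
.decimate <- function(t, y, nOut = 300L) {
  n <- length(t)
  if (n <= nOut) return(list(t = t, y = y))
  idx <- pmin(floor((seq_len(n) - 1L) / (n / nOut)) + 1L, nOut)
  list(t = as.numeric(tapply(t, idx, mean)),
       y = as.numeric(tapply(y, idx, mean)))
}

## linear LS for amplitudes/phases at fixed frequencies; returns par vector
.sineLinear <- function(t, y, freq, w = NULL) {
  X <- do.call(cbind, lapply(freq, function(b) cbind(sin(b * t), cos(b * t))))
  if (!is.null(w)) { X <- X * sqrt(w); y <- y * sqrt(w) }
  cf <- tryCatch(qr.coef(qr(X), y), error = function(e) rep(0, 2 * length(freq)))
  cf[is.na(cf)] <- 0
  al <- cf[seq(1, length(cf), 2)]
  be <- cf[seq(2, length(cf), 2)]
  c(sqrt(al^2 + be^2), freq, atan2(be, al))
}

.sineEval <- function(par, t) {
  k <- length(par) / 3
  amp <- par[seq_len(k)]; freq <- par[k + seq_len(k)]; ph <- par[2 * k + seq_len(k)]
  out <- numeric(length(t))
  for (i in seq_len(k)) out <- out + amp[i] * sin(freq[i] * t + ph[i])
  out
}

#' Fit a sum of six sine functions
#'
#' Least-squares fit of y(t) by a_1 sin(b_1 t + c_1) + ... +
#' a_6 sin(b_6 t + c_6), the heuristic smooth-curve model used for noise
#' filtering of background traces and for the photobleaching correction
#' function. Frequencies are initialized from the largest
#' discrete-spectrum components of y (plus a quasi-DC term capturing the
#' mean and slow trends) and refined by Levenberg-Marquardt; the best of
#' several starts is returned. Frequencies are bounded to
#' [0, 2 pi maxFreqCycles / T]. If no start converges, a monotone spline
#' through the decimated data is substituted and flagged.
#'
#' @param t sample times (s), at least 50
#' @param y values
#' @param weights optional least-squares weights
#' @param maxFreqCycles frequency bound in oscillation cycles over the
#'   fitted domain
#' @return a \linkS4class{SixSineCurve}; evaluate with
#'   \code{\link{evalCurve}}
#' @examples
#' t <- seq(0, 200, by = 0.5)
#' y <- 0.7 * sin(0.1 * t + 0.2) + 0.3 * sin(0.5 * t + 1.0)
#' fit <- fitSixSines(t, y)
#' fit@residualRMS   # ~0 (model lies in the model class)
#' @export
fitSixSines <- function(t, y, weights = NULL, maxFreqCycles = 20) {
  if (length(t) < 50L) stop("need at least 50 samples")
  if (length(t) != length(y)) stop("t and y must align")
  T <- max(t) - min(t)
  if (T <= 0) stop("degenerate time range")
  w0 <- 2 * pi / T
  bmax <- max(maxFreqCycles, 0.5) * w0
  ## the first term is pinned at frequency zero, making it a pure DC
  ## term a sin(c); the other frequencies are kept away from zero, where
  ## a near-zero-frequency sine with free amplitude degenerates into an
  ## unbounded polynomial
  bmin <- 0.25 * w0

  ## spectral peaks of the demeaned signal on a uniform grid
  ns <- min(length(y), 2048L)
  ug <- seq(min(t), max(t), length.out = ns)
  uy <- stats::approx(t, y, xout = ug, rule = 2)$y
  sp <- Mod(stats::fft(uy - mean(uy)))[2:(ns %/% 2)]
  fr <- (seq_along(sp)) * 2 * pi / T
  ord <- order(sp, decreasing = TRUE)
  peaks <- fr[ord[seq_len(min(5L, length(ord)))]]

  starts <- list(
    c(peaks, rep(w0 * c(2, 3, 4), length.out = max(0, 5 - length(peaks)))),
    w0 * c(0.25, 0.5, 0.75, 1, 1.25),
    w0 * c(0.5, 1, 2, 4, 8)
  )
  starts <- lapply(starts, function(b)
    c(0, sort(pmin(pmax(b[1:5], bmin), bmax))))

  obj <- function(par) {
    r <- y - .sineEval(par, t)
    if (is.null(weights)) r else r * sqrt(weights)
  }
  lower <- c(rep(-Inf, 6), 0, rep(bmin, 5), rep(-Inf, 6))
  upper <- c(rep(Inf, 6), 0, rep(bmax, 5), rep(Inf, 6))

  best <- NULL; bestSSR <- Inf
  for (b in starts) {
    p0 <- .sineLinear(t, y, b, weights)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = obj, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ptol = 1e-12, ftol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(obj(fit$par)^2)
    if (is.finite(ssr) && ssr < bestSSR) { bestSSR <- ssr; best <- fit$par }
  }

  if (is.null(best)) {
    d <- .decimate(t, y, 100L)
    f <- stats::splinefun(d$t, d$y, method = "monoH.FC")
    warning("six-sine fit did not converge; monotone spline fallback in use")
    return(new("SixSineCurve", amp = rep(0, 6), freq = rep(0, 6),
               phase = rep(0, 6), domain = range(t),
               residualRMS = sqrt(mean((y - f(t))^2)),
               fallback = TRUE, spline = f))
  }
  new("SixSineCurve", amp = best[1:6], freq = best[7:12], phase = best[13:18],
      domain = range(t), residualRMS = sqrt(bestSSR / length(y)),
      fallback = FALSE, spline = NULL)
}

#' @rdname evalCurve
#' @aliases evalCurve,SixSineCurve-method
setMethod("evalCurve", "SixSineCurve", function(x, t) {
  if (x@fallback) x@spline(t)
  else .sineEval(c(x@amp, x@freq, x@phase), t)
})

## scale a fitted curve by a constant (the model is linear in amplitudes)
.scaleCurve <- function(curve, s) {
  if (curve@fallback) {
    f <- curve@spline
    curve@spline <- function(t) s * f(t)
  } else curve@amp <- curve@amp * s
  curve
}

#' Background subtraction
#'
#' Subtracts the background from the raw membrane signal,
#' I'(t) = I_raw(t) - I_bg(t). By default the background trace is
#' smoothed by the six-sine fit before subtraction (noise filtering), so
#' that background shot noise is not injected into the corrected trace.
#' Corrected values are clipped at zero; a clip fraction above 10%
#' indicates over-subtraction and raises a warning flag.
#'
#' @param iRaw raw signal trace
#' @param iBg scaled background trace of equal length
#' @param t sample times (required when \code{smooth = TRUE})
#' @param smooth smooth the background with a six-sine fit before
#'   subtracting
#' @param maxFreqCycles frequency bound of the smoothing fit, in cycles
#'   over the trace; kept low so that the fit follows only slow drifts,
#'   not the millisecond-scale diffusion fluctuations the correlation
#'   analysis lives on
#' @return list: \code{corrected}, \code{clipFraction}, \code{flags},
#'   and \code{bgCurve} (the fitted background, or NULL)
#' @export
subtractBackground <- function(iRaw, iBg, t = NULL, smooth = TRUE,
                               maxFreqCycles = 3) {
  if (length(iRaw) != length(iBg)) stop("traces must have equal length")
  bgCurve <- NULL
  if (smooth && length(iBg) >= 50L && any(iBg > 0)) {
    if (is.null(t)) t <- seq_along(iRaw)
    d <- .decimate(t, iBg)
    bgCurve <- fitSixSines(d$t, d$y, maxFreqCycles = maxFreqCycles)
    bgv <- evalCurve(bgCurve, t)
  } else bgv <- iBg
  corr <- iRaw - bgv
  clip <- mean(corr < 0)
  corr[corr < 0] <- 0
  flags <- if (clip > 0.1) "over_subtraction" else character()
  list(corrected = corr, clipFraction = clip, flags = flags,
       bgCurve = bgCurve)
}

#' Photobleaching correction of an intensity trace
#'
#' Compensates the signal loss caused by photobleaching: the
#' background-corrected trace is smoothed by a six-sine fit, the ratio
#' gamma(t) = I'(0)/I'(t) of the smooth trace is itself fitted with the
#' six-sine model, normalized so gamma(0) = 1, and the trace is rescaled,
#' I(t) = I'(t) gamma(t). I'(0) is read from the smooth fit at t = 0
#' rather than from the noisy first bin. The time average <gamma(t)>,
#' which rescales autocorrelation amplitudes, is returned alongside; it
#' equals 1 for a stationary trace and grows with the fraction of signal
#' lost.
#'
#' @param iPrime background-corrected trace (non-negative, nonzero mean)
#' @param t sample times (s)
#' @param maxFreqCycles frequency bound of the smoothing fits (cycles
#'   over the trace); photobleaching is slow, and a tight bound keeps the
#'   correction from following genuine diffusion fluctuations
#' @param minDecline minimum fractional net intensity loss (from a
#'   linear trend) required before the correction engages; below it
#'   gamma is identically 1 and the scan is flagged
#'   \code{no_bleach_detected}
#' @return list: \code{corrected} (= I' gamma), \code{gamma} (a
#'   \linkS4class{SixSineCurve}, normalized), \code{gammaMean}, and
#'   \code{flags}
#' @export
bleachCorrect <- function(iPrime, t, maxFreqCycles = 3,
                          minDecline = 0.1) {
  if (any(iPrime < 0)) stop("corrected trace must be non-negative")
  if (mean(iPrime) <= 0) stop("degenerate trace: zero mean")
  d <- .decimate(t, iPrime)
  if (mean(d$y <= 0.05 * mean(d$y)) > 0.3)
    stop("degenerate trace: intensity collapses to zero")

  ## engage the correction only when the trace shows a genuine net
  ## decline; on a stationary trace the right correction is gamma = 1,
  ## and fitting gamma to slow diffusion fluctuations would distort the
  ## correlations instead of cleaning them. Significance is judged from
  ## block means, whose scatter reflects the slow fluctuations the gate
  ## must not mistake for bleaching.
  nb <- 8L
  bi <- pmin(floor((d$t - min(d$t)) / (diff(range(d$t)) + 1e-12) * nb) + 1L, nb)
  bm <- as.numeric(tapply(d$y, bi, mean))
  bt <- as.numeric(tapply(d$t, bi, mean))
  lf <- stats::lm(bm ~ bt)
  T <- max(t) - min(t)
  decline <- -stats::coef(lf)[[2L]] * T / mean(d$y)
  declSE <- summary(lf)$coefficients[2L, 2L] * T / mean(d$y)
  if (!is.finite(decline) ||
      decline < max(minDecline, 3 * declSE)) {
    unit <- new("SixSineCurve", amp = c(1, rep(0, 5)), freq = rep(0, 6),
                phase = c(pi / 2, rep(0, 5)), domain = range(t),
                residualRMS = 0, fallback = FALSE, spline = NULL)
    return(list(corrected = iPrime, gamma = unit, gammaMean = 1,
                flags = "no_bleach_detected"))
  }
  smoothFit <- fitSixSines(d$t, d$y, maxFreqCycles = maxFreqCycles)
  sm <- evalCurve(smoothFit, d$t)
  ## a noisy trace may let the smooth fit graze zero; floor it at a
  ## fraction of the mean rather than fail, but give up when the smooth
  ## really collapses (the trace decayed to nothing)
  floorVal <- 0.2 * mean(d$y)
  flags <- character()
  if (mean(sm <= floorVal) > 0.3)
    stop("degenerate trace: smoothed intensity reaches zero")
  if (any(sm <= floorVal)) flags <- c(flags, "gamma_floored")
  sm <- pmax(sm, floorVal)
  i0 <- max(evalCurve(smoothFit, min(t)), floorVal)
  ratio <- i0 / sm
  gammaFit <- fitSixSines(d$t, ratio, maxFreqCycles = maxFreqCycles)
  g0 <- evalCurve(gammaFit, min(t))
  if (!is.finite(g0) || g0 <= 0)
    stop("degenerate bleaching ratio at t = 0")
  gammaFit <- .scaleCurve(gammaFit, 1 / g0)
  gammaFine <- pmin(pmax(evalCurve(gammaFit, t), 0.2), 5)
  if (gammaFit@fallback) flags <- c(flags, "gamma_spline_fallback")
  list(corrected = iPrime * gammaFine, gamma = gammaFit,
       gammaMean = mean(gammaFine), flags = flags)
}

#' Background and bleaching correction of a scan
#'
#' Applies \code{\link{subtractBackground}} and \code{\link{bleachCorrect}}
#' per channel and collects the per-channel correction functions gamma(t)
#' and their time averages into a \linkS4class{CorrectionState}.
#'
#' @param traces an \linkS4class{IntensityTraces}
#' @param subtractBg logical; disable to quantify the background
#'   robustness of downstream statistics
#' @param smoothBg smooth the background trace before subtraction
#' @param bleach logical; disable the photobleaching correction (gamma
#'   is then identically 1), e.g. for calibration runs known to be free
#'   of bleaching
#' @return a \linkS4class{CorrectionState}
#' @export
correctTraces <- function(traces, subtractBg = TRUE, smoothBg = TRUE,
                          bleach = TRUE) {
  chans <- names(traces@raw)
  gamma <- corrected <- list()
  gm <- clip <- stats::setNames(numeric(length(chans)), chans)
  flags <- character()
  unitGamma <- new("SixSineCurve", amp = c(1, rep(0, 5)), freq = rep(0, 6),
                   phase = c(pi / 2, rep(0, 5)), domain = range(traces@t),
                   residualRMS = 0, fallback = FALSE, spline = NULL)
  for (ch in chans) {
    if (subtractBg) {
      sb <- subtractBackground(traces@raw[[ch]], traces@bg[[ch]],
                               t = traces@t, smooth = smoothBg)
      ip <- sb$corrected
      clip[ch] <- sb$clipFraction
      if (length(sb$flags)) flags <- c(flags, paste0(sb$flags, "_", ch))
    } else {
      ip <- traces@raw[[ch]]
      clip[ch] <- 0
    }
    if (bleach) {
      bc <- bleachCorrect(ip, traces@t)
      gamma[[ch]] <- bc$gamma
      corrected[[ch]] <- bc$corrected
      gm[ch] <- bc$gammaMean
      if (length(bc$flags)) flags <- c(flags, paste0(bc$flags, "_", ch))
    } else {
      gamma[[ch]] <- unitGamma
      corrected[[ch]] <- ip
      gm[ch] <- 1
    }
  }
  new("CorrectionState", gamma = gamma, gammaMean = gm,
      corrected = corrected, t = traces@t, sampleTime = traces@sampleTime,
      clipFraction = clip, flags = flags)
}
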