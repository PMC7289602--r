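#' @include binding.R
NULL

## weighted linear estimate of the cross-correlation zero-lag amplitude
## with the decay time tied to the autocorrelation fits
.crossAmplitude <- function(corr, fits, calib) {
  tdG <- fits$G@par[["tauD"]]; tdR <- fits$R@par[["tauD"]]
  if (!is.finite(tdG) || !is.finite(tdR) || tdG <= 0 || tdR <= 0)
    return(c(amplitude = NA_real_, variance = NA_real_))
  om <- calib@omega0 * 1e-3
  dBar <- mean(c(om[["G"]]^2 / (4 * tdG), om[["R"]]^2 / (4 * tdR)))
  tauDx <- mean(om^2) / 2 / (2 * dBar)   # omega_eff^2 / (4 D)
  tau <- corr@tau
  m <- 1 / (1 + tau / tauDx)
  e <- corr@err$x
  ok <- is.finite(e) & e > 0
  w <- if (any(ok)) {
    e[!ok] <- 3 * max(e[ok]); 1 / e^2
  } else rep(1, length(tau))
  X <- cbind(m, 1)
  cf <- tryCatch(stats::lm.wfit(X, corr@G$x, w)$coefficients,
                 error = function(e) c(NA_real_, NA_real_))
  amp <- cf[[1L]]

  ## variance of the amplitude estimate from per-segment amplitudes;
  ## used to debias the squared amplitude entering Gamma
  v <- NA_real_
  seg <- corr@meta$segments$x
  if (!is.null(seg)) {
    segAmp <- apply(seg, 1L, function(g) {
      ok2 <- is.finite(g)
      if (sum(ok2) < 5L) return(NA_real_)
      tryCatch(stats::lm.wfit(X[ok2, , drop = FALSE], g[ok2],
                              w[ok2])$coefficients[[1L]],
               error = function(e) NA_real_)
    })
    segAmp <- segAmp[is.finite(segAmp)]
    if (length(segAmp) >= 3L)
      v <- stats::var(segAmp) / length(segAmp)
  }
  c(amplitude = amp, variance = v)
}

#' Process a single axial lsFCS scan
#'
#' Runs the full per-scan analysis chain: PIE channel gating, kymograph
#' construction, membrane tracking and quality control, signal and
#' background extraction, background subtraction and photobleaching
#' correction, multi-tau correlation, diffusion-model fits of the three
#' correlation curves, and the Gamma amplitude statistic.
#'
#' @param stream a \linkS4class{PhotonStream} (or a path readable by
#'   \code{\link{readPhotonStream}})
#' @param calib an \linkS4class{OpticsCalibration} for densities and
#'   diffusion coefficients
#' @param nPixels z pixels of the kymograph
#' @param coarseLineTime tracking kymograph binning (s)
#' @param binWidth correlation time base (s)
#' @param halfwidth signal window half width (pixels)
#' @param offset background region offset (pixels)
#' @param nRidges membranes in view
#' @param subtractBg,smoothBg background handling switches
#' @param bleachCorrection apply the photobleaching correction (gamma)
#' @param maxLag largest correlation lag (s)
#' @param minLag drop lags below this in fits (s)
#' @param fitOffset include a constant baseline in the diffusion-model
#'   fits (absorbs the small normalization bias of finite recordings; see
#'   \code{\link{fitCircular}})
#' @param scanId identifier carried through the outputs
#' @return list: \code{traces}, \code{state}, \code{corr}, \code{fits}
#'   (G/R/x \linkS4class{FitResult}s), \code{amplitudes}, \code{gamma},
#'   \code{qc}, \code{density} (per-channel um^-2), \code{diffusion}
#'   (per-channel um^2/s), \code{gammaMean}
#' @export
processScan <- function(stream, calib = waistCalibration(207, 251),
                        nPixels = 26L, coarseLineTime = 0.5,
                        binWidth = 1e-4, halfwidth = 2L, offset = 10L,
                        nRidges = 1L, subtractBg = TRUE, smoothBg = TRUE,
                        bleachCorrection = TRUE,
                        maxLag = NULL, minLag = 0, fitOffset = TRUE,
                        scanId = NA_character_) {
  if (is.character(stream)) stream <- readPhotonStream(stream)
  mapping <- zMapping(stream@optics, nPixels = nPixels)
  traces <- extractIntensityTraces(stream, mapping,
                                   coarseLineTime = coarseLineTime,
                                   binWidth = binWidth,
                                   halfwidth = halfwidth, offset = offset,
                                   nRidges = nRidges)
  state <- correctTraces(traces, subtractBg = subtractBg,
                         smoothBg = smoothBg, bleach = bleachCorrection)
  corr <- correlateTraces(state, maxLag = maxLag, scanId = scanId)

  fits <- list(
    G = fitCircular(corr@tau, corr@G$G, corr@err$G, minLag = minLag,
                    fitOffset = fitOffset),
    R = fitCircular(corr@tau, corr@G$R, corr@err$R, minLag = minLag,
                    fitOffset = fitOffset),
    x = fitCircular(corr@tau, corr@G$x, corr@err$x, minLag = minLag,
                    fitOffset = fitOffset))

  gG0 <- fits$G@G0; gR0 <- fits$R@G0
  ## Cross amplitude for Gamma: a free fit of a dim cross-correlation
  ## tends to lock onto noise excursions and biases the amplitude up.
  ## All species share the membrane diffusion coefficient, so the cross
  ## decay time follows from the autocorrelation fits and the waist
  ## ratio (tauD = omega^2/4D); with the shape fixed, the amplitude is a
  ## linear, symmetric-noise estimate.
  xa <- .crossAmplitude(corr, fits, calib)
  gX0 <- xa[["amplitude"]]
  if (!is.finite(gX0))
    gX0 <- mean(corr@G$x[seq_len(min(3L, length(corr@tau)))])
  gX0 <- max(gX0, 0)
  gamma <- if (is.finite(gG0) && is.finite(gR0) && gG0 > 0 && gR0 > 0)
    gammaStatistic(gG0, gR0, gX0) else NA_real_
  ## squaring a noisy amplitude biases Gamma upward by Var(Gx0)/(GG0 GR0);
  ## subtract the segment-based variance estimate (clamped at zero)
  gXvar <- xa[["variance"]]
  if (is.finite(gamma) && is.finite(gXvar))
    gamma <- max(gamma - gXvar / (gG0 * gR0), 0)

  om <- calib@omega0 * 1e-3   # um
  density <- c(
    G = if (is.finite(gG0) && gG0 > 0) densityFromAmplitude(gG0, om[["G"]])
        else NA_real_,
    R = if (is.finite(gR0) && gR0 > 0) densityFromAmplitude(gR0, om[["R"]])
        else NA_real_)
  diffusion <- c(
    G = if (is.finite(fits$G@par[["tauD"]]))
      diffusionFromTau(fits$G@par[["tauD"]], om[["G"]]) else NA_real_,
    R = if (is.finite(fits$R@par[["tauD"]]))
      diffusionFromTau(fits$R@par[["tauD"]], om[["R"]]) else NA_real_)

  list(traces = traces, state = state, corr = corr, fits = fits,
       amplitudes = c(GG0 = gG0, GR0 = gR0, Gx0 = gX0), gamma = gamma,
       qc = traces@qc, density = density, diffusion = diffusion,
       gammaMean = state@gammaMean, scanId = scanId)
}

## average CorrelationSets on a common lag grid (independent scans)
.poolCorr <- function(corrs) {
  tau <- corrs[[1L]]@tau
  n <- length(corrs)
  G <- err <- list()
  segs <- list()
  for (ch in c("G", "R", "x")) {
    gm <- vapply(corrs, function(cs) cs@G[[ch]], numeric(length(tau)))
    if (is.null(dim(gm))) gm <- matrix(gm, ncol = n)
    G[[ch]] <- rowMeans(gm)
    em <- vapply(corrs, function(cs) cs@err[[ch]], numeric(length(tau)))
    if (is.null(dim(em))) em <- matrix(em, ncol = n)
    err[[ch]] <- sqrt(rowMeans(em^2)) / sqrt(n)
    sg <- lapply(corrs, function(cs) cs@meta$segments[[ch]])
    segs[[ch]] <- if (all(!vapply(sg, is.null, TRUE)))
      do.call(rbind, sg) else NULL
  }
  new("CorrelationSet", tau = tau, G = G, err = err,
      meta = list(binWidth = corrs[[1L]]@meta$binWidth,
                  gammaMean = corrs[[1L]]@meta$gammaMean,
                  nSegments = corrs[[1L]]@meta$nSegments * n,
                  scanId = "pooled", segments = segs))
}

## Gamma from a (pooled) CorrelationSet: amplitude fits, constrained
## cross amplitude, and the squaring-bias correction
.gammaFromCorr <- function(corr, calib, minLag = 0, fitOffset = TRUE) {
  fits <- list(
    G = fitCircular(corr@tau, corr@G$G, corr@err$G, minLag = minLag,
                    fitOffset = fitOffset),
    R = fitCircular(corr@tau, corr@G$R, corr@err$R, minLag = minLag,
                    fitOffset = fitOffset))
  gG0 <- fits$G@G0; gR0 <- fits$R@G0
  if (!is.finite(gG0) || !is.finite(gR0) || gG0 <= 0 || gR0 <= 0)
    return(NA_real_)
  xa <- .crossAmplitude(corr, fits, calib)
  gX0 <- xa[["amplitude"]]
  if (!is.finite(gX0))
    gX0 <- mean(corr@G$x[seq_len(min(3L, length(corr@tau)))])
  g <- gammaStatistic(gG0, gR0, max(gX0, 0))
  if (is.finite(xa[["variance"]]))
    g <- max(g - xa[["variance"]] / (gG0 * gR0), 0)
  g
}

#' Pooled-curve binding statistics per concentration
#'
#' Variance-reduced alternative to per-scan Gamma values: the correlation
#' curves of all surviving scans at one concentration are averaged before
#' the amplitudes are fitted, and the uncertainty of the pooled Gamma is
#' estimated by a leave-one-scan-out jackknife. Pooling reduces both the
#' noise of the nonlinear amplitude fits and the upward bias that
#' squaring a noisy cross amplitude produces at low occupancy.
#'
#' @param corrs list of \linkS4class{CorrelationSet}s of one
#'   concentration (surviving scans only)
#' @param calib an \linkS4class{OpticsCalibration}
#' @param ... passed to the amplitude fits
#' @return c(gamma, sem)
#' @export
pooledGamma <- function(corrs, calib, ...) {
  n <- length(corrs)
  g <- .gammaFromCorr(.poolCorr(corrs), calib, ...)
  sem <- NA_real_
  if (n >= 3L) {
    jk <- vapply(seq_len(n), function(i)
      .gammaFromCorr(.poolCorr(corrs[-i]), calib, ...), 0)
    jk <- jk[is.finite(jk)]
    if (length(jk) >= 2L)
      sem <- sqrt((length(jk) - 1) / length(jk) *
                    sum((jk - mean(jk))^2))
  }
  c(gamma = g, sem = sem)
}

#' Run the end-to-end binding analysis pipeline
#'
#' Processes every scan of a ligand concentration series, aggregates the
#' per-scan Gamma values into a binding curve (excluding scans that fail
#' quality control or show deviant correlation times) and fits the
#' scaled binding isotherm for K_D and beta. A failing scan never aborts
#' the run; it is excluded with its reason logged. The run errors only
#' when fewer than three scans survive at every concentration.
#'
#' @param datasets list of datasets, each a list with \code{stream} (a
#'   \linkS4class{PhotonStream} or a file path) and \code{cL} (nM)
#' @param calib an \linkS4class{OpticsCalibration}
#' @param etaLigand maturation yield of the ligand tag; used to report
#'   the maturation-corrected K_D alongside the fitted one
#' @param bootstrap bootstrap resamples for the K_D interval (0 = off)
#' @param poolScans aggregate by pooling correlation curves across the
#'   surviving scans of each concentration (see \code{\link{pooledGamma}})
#'   instead of averaging per-scan Gamma values
#' @param verbose print progress
#' @param ... per-scan options passed to \code{\link{processScan}}
#' @return list: \code{scans} (per-scan results), \code{table} (per-scan
#'   summary data.frame), \code{curve} (\linkS4class{BindingCurve}),
#'   \code{fit} (\linkS4class{IsothermFit}), \code{kDcorrected},
#'   \code{excluded} (scan ids with failure reasons)
#' @export
runPipeline <- function(datasets, calib = waistCalibration(207, 251),
                        etaLigand = 1, bootstrap = 0L, poolScans = FALSE,
                        verbose = FALSE, ...) {
  if (!length(datasets)) stop("no datasets supplied")
  rows <- list(); scans <- list(); excluded <- list()
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    id <- if (!is.null(d$id)) d$id else sprintf("scan%03d", i)
    if (verbose) message("processing ", id, " (C_L = ", d$cL, " nM)")
    res <- tryCatch(
      processScan(d$stream, calib = calib, scanId = id, ...),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      excluded[[id]] <- res
      rows[[id]] <- data.frame(cL = d$cL, gamma = NA_real_,
                               tauDG = NA_real_, tauDR = NA_real_,
                               qcPass = FALSE, id = id)
      next
    }
    scans[[id]] <- res
    rows[[id]] <- data.frame(
      cL = d$cL, gamma = res$gamma,
      tauDG = res$fits$G@par[["tauD"]], tauDR = res$fits$R@par[["tauD"]],
      qcPass = is.null(res$qc) || res$qc@pass, id = id)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  curve <- bindingCurve(tab, aFactor = calib@aFactor)
  if (poolScans) {
    det <- curve@details
    pooled <- lapply(curve@cL, function(cc) {
      ids <- det$id[det$kept & det$cL == cc]
      pooledGamma(lapply(scans[ids], `[[`, "corr"), calib)
    })
    curve@gamma <- vapply(pooled, `[[`, 0, "gamma")
    curve@sem <- vapply(pooled, `[[`, 0, "sem")
  }
  fit <- fitIsotherm(curve, bootstrap = bootstrap)
  list(scans = scans, table = tab, curve = curve, fit = fit,
       kDcorrected = correctLigandMaturation(fit@kD, etaLigand),
       excluded = excluded)
}

#' Summarize a pipeline run as a serializable report
#'
#' @param run output of \code{\link{runPipeline}}
#' @return a plain list suitable for \code{\link{writeRunReport}}
#' @export
summarizeRun <- function(run) {
  list(
    kD_nM = run$fit@kD, kD_se = run$fit@kDse,
    kD_maturation_corrected_nM = run$kDcorrected,
    beta = run$fit@beta, beta_se = run$fit@betaSE,
    A_factor = run$fit@aFactor, flags = run$fit@flags,
    curve = data.frame(cL = run$curve@cL, gamma = run$curve@gamma,
                       sem = run$curve@sem, n = run$curve@nScans),
    excluded = run$excluded,
    gammaMean = lapply(run$scans, function(s) as.list(s$gammaMean)))
}
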