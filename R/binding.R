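#' @include optics.R
NULL

#' The Gamma cross-correlation amplitude statistic
#'
#' Gamma = G_x(0)^2 / (G_G(0) G_R(0)). For a ligand concentration series
#' this combination of amplitudes traces a scaled binding isotherm,
#' Gamma(C_L) = A beta / (1 + K_D/C_L), and is robust against
#' uncorrelated background because the background correction factors of
#' the three amplitudes cancel.
#'
#' @param gG0,gR0 autocorrelation amplitudes (> 0)
#' @param gX0 cross-correlation amplitude (>= 0; small negative estimates
#'   from noise are clamped to 0)
#' @return Gamma, dimensionless
#' @examples
#' gammaStatistic(0.05, 0.02, 0.02)   # 0.4
#' @export
gammaStatistic <- function(gG0, gR0, gX0) {
  if (any(!is.finite(c(gG0, gR0, gX0))) || gG0 <= 0 || gR0 <= 0)
    stop("autocorrelation amplitudes must be positive")
  gX0 <- max(gX0, 0)
  gX0^2 / (gG0 * gR0)
}

#' Species-resolved model amplitudes
#'
#' Noiseless zero-lag amplitudes of the two autocorrelations and the
#' cross-correlation for given area densities of red-only receptors
#' (C_R), dual-label complexes (C_RL) and green-only complexes on
#' unlabeled receptors (C_rL):
#' G_G(0) = 1/(A_G (C_rL + C_RL)),
#' G_R(0) = 1/(A_R (C_R + C_RL)),
#' G_x(0) = C_RL / (A_eff (C_R + C_RL)(C_rL + C_RL)).
#' Serves as the forward oracle against which correlation amplitudes of
#' simulated data are validated.
#'
#' @param cR,cRL,crL area densities (um^-2)
#' @param calib an \linkS4class{OpticsCalibration}
#' @return named numeric: GG0, GR0, Gx0
#' @export
modelAmplitudes <- function(cR, cRL, crL, calib) {
  green <- crL + cRL
  red <- cR + cRL
  if (green <= 0 || red <= 0)
    stop("each channel needs a nonzero fluorescent density")
  ar <- calib@areas
  c(GG0 = 1 / (ar[["AG"]] * green),
    GR0 = 1 / (ar[["AR"]] * red),
    Gx0 = cRL / (ar[["Aeff"]] * red * green))
}

#' Aggregate per-scan Gamma values into a binding curve
#'
#' Pools repeated 60-s scans per ligand concentration into mean +- SEM,
#' after excluding scans that failed quality control or whose diffusion
#' fits are untrustworthy: deviant correlation times between the color
#' channels (|log(tauD_G/tauD_R)| > log maxTauDRatio) or a correlation
#' time outside [tauDRange[1], tauDRange[2]]. At least three surviving
#' scans are required per concentration; concentrations with fewer are
#' dropped with a message.
#'
#' @param scans data.frame with one row per scan: \code{cL}, \code{gamma},
#'   \code{tauDG}, \code{tauDR}, \code{qcPass}
#' @param aFactor geometric factor A of the optics calibration
#' @param maxTauDRatio,tauDRange exclusion thresholds
#' @param minScans minimum surviving scans per concentration
#' @return a \linkS4class{BindingCurve}
#' @export
bindingCurve <- function(scans, aFactor, maxTauDRatio = 3,
                         tauDRange = c(1e-3, 1), minScans = 3L) {
  need <- c("cL", "gamma", "tauDG", "tauDR", "qcPass")
  if (!all(need %in% names(scans)))
    stop("scans must have columns ", paste(need, collapse = ", "))
  reason <- rep("", nrow(scans))
  bad <- !scans$qcPass
  reason[bad] <- "qc"
  devTau <- abs(log(scans$tauDG / scans$tauDR)) > log(maxTauDRatio)
  outTau <- scans$tauDG < tauDRange[1] | scans$tauDG > tauDRange[2] |
            scans$tauDR < tauDRange[1] | scans$tauDR > tauDRange[2]
  devTau[is.na(devTau)] <- TRUE; outTau[is.na(outTau)] <- TRUE
  reason[!bad & (devTau | outTau)] <- "tauD"
  ## Gamma is bounded by A <= 1; values far above are fit artifacts
  kept <- reason == "" & is.finite(scans$gamma) & scans$gamma <= 1.5
  reason[!kept & reason == ""] <- "gamma"

  scans$kept <- kept; scans$reason <- reason
  agg <- lapply(split(scans, scans$cL), function(d) {
    k <- d[d$kept, ]
    data.frame(cL = d$cL[1L], n = nrow(k),
               gamma = if (nrow(k)) mean(k$gamma) else NA_real_,
               sem = if (nrow(k) >= 2L) stats::sd(k$gamma) / sqrt(nrow(k))
                     else NA_real_)
  })
  agg <- do.call(rbind, agg)
  agg <- agg[order(agg$cL), ]
  drop <- agg$n < minScans
  if (all(drop)) stop("fewer than ", minScans, " surviving scans at every concentration")
  if (any(drop))
    message("dropping ", sum(drop), " concentration(s) with < ", minScans,
            " surviving scans")
  agg <- agg[!drop, ]
  new("BindingCurve", cL = agg$cL, gamma = agg$gamma, sem = agg$sem,
      nScans = as.integer(agg$n), aFactor = aFactor, details = scans)
}

#' Fit the scaled binding isotherm
#'
#' Weighted (1/SEM^2) nonlinear least-squares fit of
#' Gamma(C_L) = A beta / (1 + K_D/C_L) for K_D and beta, with the
#' geometric factor A fixed from the optics calibration. Standard errors
#' come from the parameter covariance; an optional bootstrap over scans
#' within each concentration gives resampling-based intervals. The fit is
#' flagged ill-conditioned when the fitted K_D lies outside the sampled
#' concentration range (beta and K_D are then degenerate), and beta above
#' 0.6 is flagged as a hint of complexes carrying more than one labeled
#' receptor.
#'
#' @param curve a \linkS4class{BindingCurve}
#' @param bootstrap number of bootstrap resamples (0 disables)
#' @return an \linkS4class{IsothermFit}
#' @export
fitIsotherm <- function(curve, bootstrap = 0L) {
  cL <- curve@cL
  if (length(cL) < 4L || max(cL) / min(cL[cL > 0]) < 10)
    stop("need >= 4 concentrations spanning at least a decade")
  A <- curve@aFactor

  fitOnce <- function(gamma, sem) {
    ## SEMs from a handful of scans are noisy estimates themselves;
    ## floor them at half the median and at 20% of the value so no
    ## single lucky point dominates the fit
    w <- if (all(is.finite(sem) & sem > 0))
      1 / pmax(sem, 0.5 * stats::median(sem), 0.2 * abs(gamma)) else
      rep(1, length(gamma))
    obj <- function(par)
      (gamma - A * par[2L] / (1 + exp(par[1L]) / cL)) * w
    best <- NULL; bestSSR <- Inf
    for (k0 in stats::quantile(log(cL[cL > 0]), c(0.1, 0.5, 0.9))) {
      fit <- tryCatch(
        minpack.lm::nls.lm(par = c(k0, min(max(gamma) / A, 1)),
                           fn = obj,
                           lower = c(-Inf, 1e-3), upper = c(Inf, 1),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ptol = 1e-14, ftol = 1e-14)),
        error = function(e) NULL)
      if (is.null(fit)) next
      ssr <- sum(obj(fit$par)^2)
      if (is.finite(ssr) && ssr < bestSSR) { bestSSR <- ssr; best <- fit }
    }
    list(fit = best, ssr = bestSSR)
  }

  r <- fitOnce(curve@gamma, curve@sem)
  if (is.null(r$fit)) stop("isotherm fit failed")
  p <- r$fit$par
  kd <- exp(p[1L]); beta <- p[2L]
  cv <- .fcsCov(r$fit, r$ssr, length(cL), 2L)
  kdSE <- kd * sqrt(abs(cv[1L, 1L]))
  betaSE <- sqrt(abs(cv[2L, 2L]))
  if (!is.finite(kdSE) || beta >= 1 - 1e-8) {
    ## beta pinned at its physical bound: profile K_D with beta fixed
    w1 <- if (all(is.finite(curve@sem) & curve@sem > 0))
      1 / pmax(curve@sem, 0.5 * stats::median(curve@sem)) else
      rep(1, length(cL))
    obj1 <- function(par)
      (curve@gamma - A * beta / (1 + exp(par[1L]) / cL)) * w1
    f1 <- tryCatch(minpack.lm::nls.lm(par = p[1L], fn = obj1),
                   error = function(e) NULL)
    if (!is.null(f1)) {
      cv1 <- .fcsCov(f1, sum(obj1(f1$par)^2), length(cL), 1L)
      kdSE <- kd * sqrt(abs(cv1[1L, 1L]))
    }
  }

  if (bootstrap > 0L && nrow(curve@details)) {
    det <- curve@details[curve@details$kept, ]
    kds <- replicate(bootstrap, {
      g <- vapply(split(det, det$cL), function(d)
        mean(sample(d$gamma, nrow(d), replace = TRUE)), 0)
      g <- g[match(as.character(cL), names(g))]
      rb <- fitOnce(g, curve@sem)
      if (is.null(rb$fit)) NA_real_ else exp(rb$fit$par[1L])
    })
    kdSE <- max(kdSE, stats::sd(kds, na.rm = TRUE), na.rm = TRUE)
  }

  flags <- character()
  if (kd < min(cL) || kd > max(cL)) flags <- c(flags, "ill_conditioned")
  if (is.finite(beta) && beta > 0.6) flags <- c(flags, "beta_gt_0.6")
  new("IsothermFit", kD = kd, kDse = kdSE, beta = beta, betaSE = betaSE,
      aFactor = A, cov = cv, flags = flags)
}

#' Fractional occupancy curve of an isotherm fit
#'
#' F(C_L) = 1/(1 + K_D/C_L), and the scaled data Gamma/(A beta) for
#' plotting alongside.
#'
#' @param fit an \linkS4class{IsothermFit}
#' @param curve optional \linkS4class{BindingCurve} to scale
#' @return data.frame with \code{cL}, \code{F}, and (when \code{curve} is
#'   given) \code{Fdata}, \code{FdataSEM}
#' @export
occupancy <- function(fit, curve = NULL) {
  if (is.null(curve))
    return(data.frame(cL = numeric(), F = numeric()))
  sc <- fit@aFactor * fit@beta
  data.frame(cL = curve@cL, F = boundFraction(fit@kD, curve@cL),
             Fdata = curve@gamma / sc, FdataSEM = curve@sem / sc)
}

#' Ligand-maturation correction of a fitted K_D
#'
#' When the ligand's fluorescent tag matures incompletely (yield eta < 1),
#' the measured ligand concentration counts only fluorescent ligands while
#' binding is driven by all of them; the midpoint of the isotherm then
#' sits at eta K_D, so the fitted value must be replaced by K_D/eta. The
#' isotherm amplitude correspondingly reads A beta eta.
#'
#' @param kDfit K_D from the isotherm fit (nM)
#' @param eta ligand-tag maturation yield in (0, 1]
#' @return corrected K_D (nM)
#' @examples
#' correctLigandMaturation(0.09, 0.9)   # 0.1
#' @export
correctLigandMaturation <- function(kDfit, eta) {
  if (any(eta <= 0 | eta > 1)) stop("eta must lie in (0, 1]")
  kDfit / eta
}

#' Maturation-corrected bound fraction
#'
#' Converts an area-weighted amplitude ratio F' into the true bound
#' fraction F = 1 / (1/F' + 1 - 1/eta), correcting for the partner
#' label's maturation yield eta. F' equals the bound fraction only for
#' complete maturation.
#'
#' @param fPrime area-weighted amplitude ratio
#' @param eta maturation yield of the partner's label
#' @return bound fraction in [0, 1]
#' @examples
#' maturationCorrectedFraction(0.25, 0.9)   # 0.257 -> rounds to 0.26
#' @export
maturationCorrectedFraction <- function(fPrime, eta) {
  if (any(eta <= 0 | eta > 1)) stop("eta must lie in (0, 1]")
  den <- 1 / fPrime + 1 - 1 / eta
  if (any(den <= 0))
    stop("undefined bound fraction: F' too small for the given eta")
  1 / den
}

#' Heterodimer bound fractions from correlation amplitudes
#'
#' For two co-diffusing receptor species labeled in different colors, the
#' area-weighted amplitude ratios
#' F_R' = (A_eff/A_G) G_x(0)/G_G(0) and
#' F_G' = (A_eff/A_R) G_x(0)/G_R(0)
#' estimate the fractions of red- and green-labeled receptors bound in
#' dual-label heterodimers; the maturation-yield correction then gives
#' the true bound fractions F_R and F_G.
#'
#' @param gG0,gR0,gX0 correlation amplitudes (autocorrelations > 0)
#' @param calib an \linkS4class{OpticsCalibration}
#' @param etaG,etaR maturation yields of the green and red labels
#' @return a \linkS4class{HeterodimerResult}
#' @examples
#' cal <- waistCalibration(207, 251)
#' boundFractions(0.05, 0.04, 0.0101, cal, etaG = 0.9, etaR = 0.5)
#' @export
boundFractions <- function(gG0, gR0, gX0, calib, etaG = 1, etaR = 1) {
  if (gG0 <= 0 || gR0 <= 0) stop("autocorrelation amplitudes must be positive")
  fRp <- calib@ratios[["AeffAG"]] * gX0 / gG0
  fGp <- calib@ratios[["AeffAR"]] * gX0 / gR0
  new("HeterodimerResult",
      fRprime = fRp, fGprime = fGp,
      fR = maturationCorrectedFraction(fRp, etaG),
      fG = maturationCorrectedFraction(fGp, etaR),
      etaG = etaG, etaR = etaR)
}

#' Equilibration time before a measurement
#'
#' Ligand-receptor association is bimolecular, so the time to reach
#' equilibrium scales inversely with the ligand concentration. Anchored
#' at 5 minutes for C_L = 3.5 nM, the advisory incubation time is
#' t = 5 min x 3.5 nM / C_L, optionally capped.
#'
#' @param cL ligand concentration (nM, > 0)
#' @param maxMinutes cap on the advisory time (minutes)
#' @return incubation time in minutes
#' @examples
#' incubationTime(3.5)    # 5
#' incubationTime(0.35)   # 50
#' @export
incubationTime <- function(cL, maxMinutes = Inf) {
  if (any(cL <= 0)) stop("cL must be > 0")
  pmin(5 * 3.5 / cL, maxMinutes)
}
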