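#' @include AllClasses.R
NULL

## weighted Levenberg-Marquardt with multi-start over tauD decades;
## modelFun(par, tau) -> values; par = c(G0, log(tauD), extra...)
.fcsFit <- function(tau, G, err, modelFun, extraInit = NULL,
                    tauDGrid = 10^seq(-3.5, 0.5, by = 1), minLag = 0,
                    offsetInit = NULL) {
  keep <- tau >= minLag & is.finite(G)
  tau <- tau[keep]; G <- G[keep]
  w <- if (is.null(err)) rep(1, length(tau)) else {
    e <- err[keep]
    ok <- is.finite(e) & e > 0
    if (!any(ok)) rep(1, length(tau)) else {
      ## lags without a segment-based error get three times the largest
      ## observed one (long lags, where segment estimates run out)
      e[!ok] <- 3 * max(e[ok])
      1 / e
    }
  }
  if (length(tau) < 10L) stop("need at least 10 lags spanning the decay")
  obj <- function(par) (G - modelFun(par, tau)) * w

  nPar <- 2L + length(extraInit) + length(offsetInit)
  lower <- rep(-Inf, nPar); upper <- rep(Inf, nPar)
  if (length(offsetInit)) {
    ## the baseline absorbs only the small normalization bias of finite
    ## recordings; keep it from trading off against the amplitude
    offCap <- max(0.25 * abs(G[1L]), 1e-4)
    lower[nPar] <- -offCap; upper[nPar] <- offCap
  }
  best <- NULL; bestSSR <- Inf
  for (td in tauDGrid) {
    g0 <- G[1L]
    p0 <- c(g0, log(td), extraInit, offsetInit)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = obj, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ptol = 1e-14, ftol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(obj(fit$par)^2)
    if (is.finite(ssr) && ssr < bestSSR) { bestSSR <- ssr; best <- fit }
  }
  if (is.null(best)) return(NULL)
  list(fit = best, ssr = bestSSR, n = length(tau), w = w)
}

## covariance of the transformed parameters from the LM hessian
.fcsCov <- function(fit, ssr, n, nPar) {
  dof <- max(n - nPar, 1L)
  s2 <- ssr / dof
  h <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  if (is.null(h)) matrix(NA_real_, nPar, nPar) else 2 * s2 * h
}

#' Fit the circular-area 2D diffusion model
#'
#' Fits G(tau) = G0 (1 + tau/tauD)^(-1), the autocorrelation of 2D
#' diffusion through a circular Gaussian observation area — the model for
#' axial line scanning, where the observation area on the membrane is the
#' lateral focus cross-section. Weighted (1/err^2) Levenberg-Marquardt
#' with multi-start over tauD decades. The amplitude G0 equals 1/N with N
#' the mean number of fluorescent molecules in the observation area.
#'
#' @param tau lag times (s)
#' @param G correlation values
#' @param err optional per-lag uncertainties (weights 1/err^2)
#' @param minLag drop lags below this (s); sub-ms photophysics is not in
#'   the model
#' @param fitOffset add a constant baseline term to the model. On short
#'   recordings the normalization of the correlation estimator biases all
#'   lags by a small common constant (of order
#'   -2 G0 (tauD/T) log(T/tauD)); the offset absorbs it so the amplitude
#'   stays unbiased.
#' @return a \linkS4class{FitResult} with parameters N and tauD
#' @export
fitCircular <- function(tau, G, err = NULL, minLag = 0, fitOffset = FALSE) {
  model <- if (fitOffset)
    function(par, x) par[1L] / (1 + x / exp(par[2L])) + par[3L]
  else
    function(par, x) par[1L] / (1 + x / exp(par[2L]))
  nPar <- if (fitOffset) 3L else 2L
  r <- .fcsFit(tau, G, err, model, minLag = minLag,
               offsetInit = if (fitOffset) 0 else NULL)
  flags <- character()
  if (is.null(r) || r$fit$par[1L] <= 0) {
    g0 <- if (is.null(r)) NA_real_ else r$fit$par[1L]
    return(new("FitResult", model = "circular",
               par = c(N = NA_real_, tauD = NA_real_),
               se = c(N = NA_real_, tauD = NA_real_),
               G0 = g0, cov = matrix(NA_real_, nPar, nPar),
               redChiSq = NA_real_,
               converged = FALSE, flags = "fit_failed"))
  }
  p <- r$fit$par
  G0 <- p[1L]; tauD <- exp(p[2L])
  cv <- .fcsCov(r$fit, r$ssr, r$n, nPar)
  seG0 <- sqrt(abs(cv[1L, 1L])); seLt <- sqrt(abs(cv[2L, 2L]))
  new("FitResult", model = "circular",
      par = c(N = 1 / G0, tauD = tauD),
      se = c(N = seG0 / G0^2, tauD = tauD * seLt),
      G0 = G0, cov = cv, redChiSq = r$ssr / max(r$n - nPar, 1L),
      converged = TRUE, flags = flags)
}

#' Fit the elongated-area 2D diffusion model
#'
#' Fits G(tau) = G0 (1 + tau/tauD)^(-1/2) (1 + S^2 tau/tauD)^(-1/2), the
#' model for lateral line scanning where the observation area is
#' elongated along the optical axis; S = omega0/z0 >= 1 is the anisotropy
#' of the area. S is bounded at 1 (the circular limit); a fit pinned at
#' the bound is flagged, as the extra parameter makes fitting more
#' ambiguous.
#'
#' @inheritParams fitCircular
#' @return a \linkS4class{FitResult} with parameters N, tauD and S
#' @export
fitElongated <- function(tau, G, err = NULL, minLag = 0,
                         fitOffset = FALSE) {
  ## S^2 = 1 + exp(par[3]) keeps S > 1 smoothly
  base <- function(par, x) {
    s2 <- 1 + exp(par[3L])
    par[1L] / sqrt((1 + x / exp(par[2L])) * (1 + s2 * x / exp(par[2L])))
  }
  model <- if (fitOffset) function(par, x) base(par, x) + par[4L] else base
  nPar <- if (fitOffset) 4L else 3L
  r <- .fcsFit(tau, G, err, model, extraInit = log(15), minLag = minLag,
               offsetInit = if (fitOffset) 0 else NULL)
  flags <- character()
  if (is.null(r) || r$fit$par[1L] <= 0)
    return(new("FitResult", model = "elongated",
               par = c(N = NA_real_, tauD = NA_real_, S = NA_real_),
               se = c(N = NA_real_, tauD = NA_real_, S = NA_real_),
               G0 = NA_real_, cov = matrix(NA_real_, nPar, nPar),
               redChiSq = NA_real_, converged = FALSE,
               flags = "fit_failed"))
  p <- r$fit$par
  G0 <- p[1L]; tauD <- exp(p[2L]); S <- sqrt(1 + exp(p[3L]))
  if (p[3L] < log(1e-3)) flags <- c(flags, "S_at_bound")
  cv <- .fcsCov(r$fit, r$ssr, r$n, nPar)
  dSdp <- exp(p[3L]) / (2 * S)
  new("FitResult", model = "elongated",
      par = c(N = 1 / G0, tauD = tauD, S = S),
      se = c(N = sqrt(abs(cv[1, 1])) / G0^2,
             tauD = tauD * sqrt(abs(cv[2, 2])),
             S = dSdp * sqrt(abs(cv[3, 3]))),
      G0 = G0, cov = cv, redChiSq = r$ssr / max(r$n - nPar, 1L),
      converged = TRUE, flags = flags)
}

#' Area density from a correlation amplitude
#'
#' The amplitude G(0) equals 1/N with N = C pi omega0^2 the mean number
#' of fluorescent molecules in the observation area, so the area density
#' is C = 1/(G(0) pi omega0^2). Only molecules carrying a functional
#' fluorophore are counted.
#'
#' @param G0 zero-lag amplitude (> 0)
#' @param omega0um 1/e^2 waist (um)
#' @return density in um^-2
#' @examples
#' densityFromAmplitude(1, 0.25)   # 5.09 um^-2
#' @export
densityFromAmplitude <- function(G0, omega0um) {
  if (any(G0 <= 0)) stop("G0 must be > 0")
  1 / (G0 * observationArea(omega0um))
}

#' Diffusion coefficient from the correlation decay time
#'
#' D = omega0^2 / (4 tauD) for 2D diffusion through a circular Gaussian
#' observation area.
#'
#' @param tauD diffusion time (s, > 0)
#' @param omega0um 1/e^2 waist (um)
#' @return D in um^2 s^-1
#' @examples
#' diffusionFromTau(0.036, 0.25)   # 0.434 um^2/s
#' @export
diffusionFromTau <- function(tauD, omega0um) {
  if (any(tauD <= 0)) stop("tauD must be > 0")
  omega0um^2 / (4 * tauD)
}

#' Circular-model correlation function
#'
#' Forward evaluation of G(tau) = (1/N)(1 + tau/tauD)^(-1), handy for
#' constructing synthetic curves.
#'
#' @param tau lag times (s)
#' @param N mean occupancy
#' @param tauD diffusion time (s)
#' @return correlation values
#' @export
circularModel <- function(tau, N, tauD) (1 / N) / (1 + tau / tauD)

#' @rdname circularModel
#' @param S anisotropy ratio omega0/z0 of the elongated model
#' @export
elongatedModel <- function(tau, N, tauD, S)
  (1 / N) / sqrt((1 + tau / tauD) * (1 + S^2 * tau / tauD))
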