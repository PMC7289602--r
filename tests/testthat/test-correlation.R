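# Multi-tau correlator, oracle equivalence, cross-correlation behavior,
# and the SD-vs-acquisition-time precision metric.

test_that("a constant trace has zero correlation at every lag", {
  mt <- multiTauCorrelate(rep(5, 4000), binWidth = 1e-3)
  expect_true(all(mt$G == 0))
  expect_true(all(diff(mt$tau) > 0))
  expect_gte(mt$tau[1L], 1e-3)
  expect_error(multiTauCorrelate(rep(0, 1000), binWidth = 1e-3), "zero-mean")
})

test_that("multi-tau agrees with the brute-force direct sum", {
  set.seed(3)
  n <- 3000
  y <- stats::rpois(n, 4) * exp(stats::rnorm(n, 0, 0.1))
  mt <- multiTauCorrelate(y, binWidth = 1e-4)
  dr <- directCorrelate(y, binWidth = 1e-4,
                        lagBins = round(mt$tau / (mt$binFactor * 1e-4)),
                        binFactor = mt$binFactor)
  expect_equal(dr$tau, mt$tau, tolerance = 1e-12)
  expect_lt(max(abs(mt$G - dr$G)), 1e-12)

  # cross-correlation path
  z <- y + stats::rpois(n, 2)
  mtx <- multiTauCorrelate(y, z, binWidth = 1e-4)
  drx <- directCorrelate(y, z, binWidth = 1e-4,
                         lagBins = round(mtx$tau / (mtx$binFactor * 1e-4)),
                         binFactor = mtx$binFactor)
  expect_lt(max(abs(mtx$G - drx$G)), 1e-12)
})

test_that("independent traces cross-correlate to zero within noise", {
  set.seed(5)
  n <- 5e4
  g <- stats::rpois(n, 6); r <- stats::rpois(n, 4)
  cx <- crosscorrelate(g, r, binWidth = 1e-4)
  # at the first lags the estimator SD is ~1/(mu_g mu_r sqrt(n))
  expect_lt(abs(cx$G[1L]), 5 / (6 * 4 * sqrt(n)) * 24)
  expect_lt(mean(abs(cx$G[1:10])), 3e-3)
})

test_that("identical channels reduce the cross to the unrescaled auto", {
  set.seed(6)
  y <- stats::rpois(2000, 5) + rep(c(0, 2), 1000)
  a <- autocorrelate(y, gammaMean = 1, binWidth = 1e-4)
  x <- crosscorrelate(y, y, binWidth = 1e-4)
  expect_equal(x$G, a$G, tolerance = 1e-14)
  # the gamma prefactor rescales autocorrelations only
  a2 <- autocorrelate(y, gammaMean = 1.25, binWidth = 1e-4)
  expect_equal(a2$G * 1.25, a$G, tolerance = 1e-14)
})

test_that("particle loss inflates uncorrected autocorrelation amplitudes
           but leaves the cross-correlation amplitude unchanged", {
  amp <- function(seed, sigma) {
    cfg <- quickConfig(seed = seed, duration = 3, densities = c(RL = 60),
                       background = 0)
    cfg@bleachCrossSection[] <- sigma
    st <- quickStream(cfg)
    tr <- extractIntensityTraces(st)
    state <- correctTraces(tr, subtractBg = FALSE, bleach = FALSE)
    cs <- correlateTraces(state)
    # short-lag average as a fit-free amplitude proxy
    c(G = mean(corrValues(cs, "G")[1:5]),
      x = mean(corrValues(cs, "x")[1:5]))
  }
  ## mild bleaching (~20% of emitters): the autocorrelation amplitude
  ## inflates to first order in the lost fraction, while the cross is
  ## only touched at second order by the common decay envelope
  a0 <- rowMeans(vapply(23:26, amp, numeric(2), sigma = 0))
  aB <- rowMeans(vapply(23:26, amp, numeric(2), sigma = 1e-5))
  expect_gt(aB[["G"]] / a0[["G"]], 1.1)            # auto inflates
  expect_lt(abs(aB[["x"]] / a0[["x"]] - 1), 0.15)  # cross stays put
})

test_that("segment-split errors shrink as 1/sqrt(segments) at fixed
           segment length", {
  set.seed(11)
  mkErr <- function(n, nSeg) {
    y <- stats::rpois(n, 5)
    tr <- new("IntensityTraces", t = seq_len(n) * 1e-3, sampleTime = 1e-3,
              raw = list(G = y, R = y), bg = list(G = y * 0, R = y * 0),
              qc = NULL, meta = list())
    st <- correctTraces(tr, subtractBg = FALSE, bleach = FALSE)
    cs <- correlateTraces(st, nSegments = nSeg, maxLag = 0.05)
    mean(corrErrors(cs, "G")[1:10], na.rm = TRUE)
  }
  e4 <- mkErr(48000, 4L)
  e16 <- mkErr(192000, 16L)
  expect_lt(abs(e16 / e4 - 0.5), 0.25)
})

test_that("curve scatter: identical curves give zero, offsets give
           delta/2, and shorter acquisitions scatter more", {
  tau <- 10^seq(-3, -1, length.out = 20)
  base <- circularModel(tau, N = 5, tauD = 0.02)
  cs <- list("1" = list(data.frame(tau = tau, G = base),
                        data.frame(tau = tau, G = base)))
  expect_equal(sdVsTime(cs, normalize = FALSE)$sd, 0)

  delta <- 0.04
  cs2 <- list("1" = list(data.frame(tau = tau, G = base),
                         data.frame(tau = tau, G = base + delta)))
  expect_equal(sdVsTime(cs2, normalize = FALSE)$sd, delta / 2,
               tolerance = 1e-12)
  expect_error(
    sdVsTime(list("1" = list(data.frame(tau = tau, G = base),
                             data.frame(tau = tau[-1], G = base[-1])))),
    "mismatched")
})

test_that("axial (circular) scanning reaches a given precision faster
           than lateral (elongated) scanning", {
  curveFor <- function(aspect, seed, dur) {
    cfg <- quickConfig(seed = seed, duration = dur, boxSide = 2,
                       densities = c(RL = 40), background = 0)
    cfg@lateralAspect <- aspect
    if (aspect > 1) cfg@brightness <- cfg@brightness / aspect  # match rates
    st <- quickStream(cfg)
    tr <- extractIntensityTraces(st)
    state <- correctTraces(tr, subtractBg = FALSE, bleach = FALSE)
    cs <- correlateTraces(state, maxLag = 0.3)
    data.frame(tau = lagTimes(cs), G = corrValues(cs, "G"))
  }
  sets <- list()
  for (dur in c(1, 2)) {
    ax <- lapply(1:4, function(s) curveFor(1, 100 + s, dur))
    lt <- lapply(1:4, function(s) curveFor(5, 200 + s, dur))
    sets[[as.character(dur)]] <- list(axial = ax, lateral = lt)
  }
  for (dur in names(sets)) {
    sdA <- sdVsTime(stats::setNames(list(sets[[dur]]$axial), dur))$sd
    sdL <- sdVsTime(stats::setNames(list(sets[[dur]]$lateral), dur))$sd
    expect_lt(sdA, sdL)
  }
})

test_that("correlation of a corrected scan is reversal-symmetric within
           estimator noise", {
  cfg <- quickConfig(seed = 29, duration = 2, densities = c(RL = 50),
                     background = 0)
  st <- quickStream(cfg)
  tr <- extractIntensityTraces(st)
  state <- correctTraces(tr, subtractBg = FALSE, bleach = FALSE)
  cs <- correlateTraces(state)
  iRev <- lapply(state@corrected, rev)
  stateRev <- state; stateRev@corrected <- iRev
  csRev <- correlateTraces(stateRev)
  err <- corrErrors(cs, "G")
  ok <- is.finite(err) & err > 0
  z <- (corrValues(cs, "G") - corrValues(csRev, "G"))[ok] / err[ok]
  expect_lt(stats::median(abs(z)), 4)
})
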