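# Diffusion-model fits, unit conversions, and the focus-size calibration.

test_that("the circular model is an exact interpolant of its own curves", {
  tau <- 10^seq(-4, 0, length.out = 40)
  G <- circularModel(tau, N = 5, tauD = 0.010)
  f <- fitCircular(tau, G)
  expect_true(f@converged)
  expect_equal(f@par[["N"]], 5, tolerance = 1e-9)
  expect_equal(f@par[["tauD"]], 0.010, tolerance = 1e-9)
  expect_lt(f@redChiSq, 1e-16)
})

test_that("the elongated model recovers (N, tauD, S) and its limits", {
  tau <- 10^seq(-4, 0.5, length.out = 60)
  G <- elongatedModel(tau, N = 10, tauD = 0.046, S = 4)
  f <- fitElongated(tau, G)
  expect_equal(f@par[["N"]], 10, tolerance = 1e-6)
  expect_equal(f@par[["tauD"]], 0.046, tolerance = 1e-6)
  expect_equal(f@par[["S"]], 4, tolerance = 1e-5)

  # a circular-model curve pushes S to its lower limit of 1
  Gc <- circularModel(tau, N = 5, tauD = 0.02)
  fc <- fitElongated(tau, Gc)
  expect_lt(fc@par[["S"]], 1.2)
  # S = 1 makes both models identical
  expect_equal(elongatedModel(tau, 5, 0.02, 1), Gc, tolerance = 1e-14)
})

test_that("fits tolerate noise and flag non-decaying input", {
  set.seed(14)
  tau <- 10^seq(-3.5, -0.5, length.out = 40)
  G <- circularModel(tau, N = 8, tauD = 0.03)
  f <- fitCircular(tau, G + stats::rnorm(40, 0, 0.01 * G[1L]))
  expect_lt(abs(f@par[["N"]] / 8 - 1), 0.05)

  flat <- fitCircular(tau, stats::rnorm(40, 0, 1e-4))
  expect_true(!flat@converged || flat@G0 < 1e-3)
  expect_error(fitCircular(tau[1:5], G[1:5]), "10 lags")
})

test_that("density and diffusion conversions follow the observation-area
           relations", {
  expect_equal(observationArea(0.25), pi * 0.0625, tolerance = 1e-12)
  expect_equal(round(observationArea(0.25), 2), 0.20)
  expect_equal(densityFromAmplitude(1, 0.25), 1 / (pi * 0.0625),
               tolerance = 1e-12)
  expect_equal(round(densityFromAmplitude(1, 0.25), 2), 5.09)
  expect_equal(densityFromAmplitude(1e6, 0.25), 5.09e-6, tolerance = 1e-3)

  expect_equal(diffusionFromTau(0.036, 0.25), 0.25^2 / (4 * 0.036),
               tolerance = 1e-12)
  expect_equal(round(diffusionFromTau(0.036, 0.25), 3), 0.434)
  expect_equal(diffusionFromTau(0.072, 0.25),
               diffusionFromTau(0.036, 0.25) / 2)
  # round trip through the fitted diffusion time
  tauD <- 0.25^2 / (4 * 0.4)
  expect_equal(diffusionFromTau(tauD, 0.25), 0.4, tolerance = 1e-12)
  expect_error(diffusionFromTau(-1, 0.25), "tauD")
  expect_error(densityFromAmplitude(0, 0.25), "G0")
})

test_that("focus calibration: bead correction, waist conversion, areas", {
  cal <- calibrateFocus(c(G = 242, R = 295), beadDiameter = 0)
  expect_equal(unname(omega0(cal)[["R"]]), 295 / sqrt(2 * log(2)),
               tolerance = 1e-12)
  expect_equal(round(omega0(cal)[["R"]]), 251)
  # bead-size correction shrinks the measured width
  calB <- calibrateFocus(c(G = 242, R = 295), beadDiameter = 100)
  expect_lt(calB@fwhm[["G"]], 242)
  expect_equal(calB@fwhm[["G"]], sqrt(242^2 - 100^2), tolerance = 1e-12)
  expect_error(calibrateFocus(c(G = 90, R = 295), beadDiameter = 100),
               "exceed")

  wc <- waistCalibration(207, 251)
  expect_equal(unname(wc@ratios[["AeffAG"]]), (207^2 + 251^2) / (2 * 207^2),
               tolerance = 1e-12)
  expect_lt(abs(wc@ratios[["AeffAG"]] - 1.23), 0.01)
  expect_lt(abs(wc@ratios[["AeffAR"]] - 0.84), 0.01)
  expect_gt(aFactor(wc), 0.95)

  # identical waists collapse all ratios to one
  eq <- waistCalibration(230, 230)
  expect_equal(unname(eq@ratios), c(1, 1), tolerance = 1e-12)
  expect_equal(aFactor(eq), 1, tolerance = 1e-12)
})

test_that("the area factor decreases monotonically as waists diverge", {
  as <- vapply(seq(1, 2, by = 0.1),
               function(k) aFactor(waistCalibration(200, 200 * k)), 0)
  expect_true(all(diff(as) < 0))
  expect_true(all(as > 0 & as <= 1))
})

test_that("fitted diffusion times match omega^2/(4D) on simulated scans", {
  opt <- testOptics(omegaG = 250, omegaR = 250)
  tauDs <- vapply(1:4, function(s) {
    cfg <- quickConfig(seed = 50 + s, duration = 6, boxSide = 2.4,
                       densities = c(RL = 40), background = 0, D = 0.4,
                       timeStep = 2e-4)
    st <- quickStream(cfg, opt)
    sc <- processScan(st, calib = waistCalibration(250, 250),
                      binWidth = 2e-4, bleachCorrection = FALSE)
    sc$fits$R@par[["tauD"]]
  }, 0)
  expected <- 0.25^2 / (4 * 0.4)   # 39.06 ms
  se <- stats::sd(tauDs) / sqrt(length(tauDs))
  expect_lt(abs(mean(tauDs) - expected), 3 * se + 0.15 * expected)
})
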