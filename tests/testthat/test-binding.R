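# The Gamma statistic, amplitude models, isotherm fitting, maturation
# corrections, heterodimer bound fractions, and protocol helpers.

test_that("the Gamma statistic combines amplitudes as Gx^2/(GG GR)", {
  expect_equal(gammaStatistic(0.05, 0.02, 0.02), 0.4, tolerance = 1e-12)
  expect_equal(gammaStatistic(0.1, 0.1, 0), 0)
  expect_equal(gammaStatistic(0.1, 0.1, -1e-4), 0)   # noise clamped
  expect_error(gammaStatistic(0, 0.1, 0.05), "positive")
})

test_that("model amplitudes obey the binding algebra Gamma = A b F", {
  cal <- testCalib()
  A <- aFactor(cal)
  for (Fb in c(0.1, 0.4, 0.8)) {
    for (bl in c(0.3, 0.7, 1)) {
      Ct <- 50
      cRL <- Fb * bl * Ct       # bound, receptor labeled
      crL <- Fb * (1 - bl) * Ct # bound, receptor dark
      cR <- (1 - Fb) * bl * Ct  # free labeled receptors
      m <- modelAmplitudes(cR, cRL, crL, cal)
      gam <- gammaStatistic(m[["GG0"]], m[["GR0"]], m[["Gx0"]])
      expect_equal(gam, A * bl * Fb, tolerance = 1e-12)
    }
  }
  # equal species densities: Gamma = A/4
  m <- modelAmplitudes(10, 10, 10, cal)
  expect_equal(gammaStatistic(m[["GG0"]], m[["GR0"]], m[["Gx0"]]),
               A * 0.25, tolerance = 1e-12)
  expect_equal(round(0.967 * 0.25, 3), 0.242)  # with the rounded A in use
  expect_equal(modelAmplitudes(5, 0, 3, cal)[["Gx0"]], 0)
  expect_error(modelAmplitudes(0, 0, 5, cal), "nonzero")
})

test_that("Gamma is monotone in concentration with supremum A beta", {
  cal <- testCalib()
  A <- aFactor(cal)
  cL <- 10^seq(-3, 3, by = 0.25)
  for (beta in c(0.3, 0.9)) {
    g <- A * beta * boundFraction(0.5, cL)
    expect_true(all(diff(g) > 0))
    expect_true(all(g < A * beta))
    expect_lt(A * beta - max(g), 1e-3 * A)
  }
})

test_that("isotherm fits recover parameters exactly without noise and
           within error with noise", {
  cal <- testCalib()
  A <- aFactor(cal)
  cL <- c(0.01, 0.0316, 0.1, 0.316, 1, 3.16)
  kd <- 0.08; beta <- 0.44
  gam <- A * beta / (1 + kd / cL)
  cv <- new("BindingCurve", cL = cL, gamma = gam,
            sem = rep(1e-4, 6), nScans = rep(3L, 6), aFactor = A,
            details = data.frame())
  f <- fitIsotherm(cv)
  expect_equal(kD(f), kd, tolerance = 1e-6)
  expect_equal(bindingBeta(f), beta, tolerance = 1e-6)
  expect_equal(occupancy(f, cv)$F, boundFraction(kd, cL), tolerance = 1e-6)
  # at cL = K_D the model passes through A beta / 2
  expect_equal(A * beta / (1 + kd / kd), A * beta / 2)

  set.seed(12)
  cover <- 0; relerr <- NULL
  for (i in 1:60) {
    g <- gam * (1 + stats::rnorm(6, 0, 0.05))
    cvN <- new("BindingCurve", cL = cL, gamma = g, sem = 0.05 * gam,
               nScans = rep(3L, 6), aFactor = A, details = data.frame())
    fN <- fitIsotherm(cvN)
    relerr <- c(relerr, kD(fN) / kd - 1)
    cover <- cover + (abs(kD(fN) - kd) < 2 * fN@kDse)
  }
  expect_gt(cover / 60, 0.8)
  expect_lt(abs(stats::median(relerr)), 0.1)
  expect_error(fitIsotherm(new("BindingCurve", cL = c(1, 2, 3),
                               gamma = rep(0.1, 3), sem = rep(0.01, 3),
                               nScans = rep(3L, 3), aFactor = A,
                               details = data.frame())),
               "concentrations")
})

test_that("ligand maturation rescales the fitted K_D by 1/eta", {
  expect_equal(correctLigandMaturation(0.09, 0.9), 0.1, tolerance = 1e-12)
  expect_equal(correctLigandMaturation(0.5, 1), 0.5)
  expect_error(correctLigandMaturation(0.1, 0), "eta")

  # an isotherm generated with ligand yield eta fits as (eta K_D, beta eta)
  cal <- testCalib()
  A <- aFactor(cal); kd <- 0.5; beta <- 0.8; eta <- 0.7
  cL <- 10^seq(-2, 1.2, length.out = 7)
  gam <- A * beta * eta / (1 + eta * kd / cL)
  cv <- new("BindingCurve", cL = cL, gamma = gam, sem = rep(1e-4, 7),
            nScans = rep(3L, 7), aFactor = A, details = data.frame())
  f <- fitIsotherm(cv)
  expect_equal(kD(f), eta * kd, tolerance = 1e-6)
  expect_equal(correctLigandMaturation(kD(f), eta), kd, tolerance = 1e-6)
  expect_equal(bindingBeta(f), beta * eta, tolerance = 1e-6)
})

test_that("heterodimer bound fractions apply the maturation correction", {
  expect_equal(maturationCorrectedFraction(0.25, 0.9), 1 / (4 + 1 - 1 / 0.9),
               tolerance = 1e-12)
  expect_equal(round(maturationCorrectedFraction(0.25, 0.9), 2), 0.26)
  expect_equal(round(maturationCorrectedFraction(0.15, 0.5), 2), 0.18)
  expect_equal(maturationCorrectedFraction(0.3, 1), 0.3)
  # F' incompatible with the yield: denominator 1/F' + 1 - 1/eta <= 0
  expect_error(maturationCorrectedFraction(1.2, 0.5), "undefined")

  cal <- testCalib()
  # amplitudes chosen so the area-weighted ratios hit 0.25 and 0.15
  gG0 <- 0.05
  gX0 <- 0.25 * gG0 / cal@ratios[["AeffAG"]]
  gR0 <- cal@ratios[["AeffAR"]] * gX0 / 0.15
  hd <- boundFractions(gG0, gR0, gX0, cal, etaG = 0.9, etaR = 0.5)
  expect_equal(hd@fRprime, 0.25, tolerance = 1e-12)
  expect_equal(hd@fGprime, 0.15, tolerance = 1e-12)
  expect_equal(round(hd@fR, 2), 0.26)
  expect_equal(round(hd@fG, 2), 0.18)
  hd1 <- boundFractions(gG0, gR0, gX0, cal, etaG = 1, etaR = 1)
  expect_equal(hd1@fR, hd1@fRprime)
  expect_equal(hd1@fG, hd1@fGprime)
})

test_that("incubation times scale inversely with concentration", {
  expect_equal(incubationTime(3.5), 5)
  expect_equal(incubationTime(0.35), 50)
  expect_equal(incubationTime(7), 2.5)
  expect_equal(incubationTime(0.01, maxMinutes = 120), 120)
  expect_error(incubationTime(0), "cL")
})

test_that("scan aggregation enforces the discard rules and n >= 3", {
  scans <- data.frame(
    cL = rep(c(0.1, 1), each = 4),
    gamma = c(0.11, 0.12, 0.10, 0.50, 0.40, 0.42, 0.38, 0.41),
    tauDG = c(0.03, 0.03, 0.03, 0.03, 0.03, 0.2, 0.03, 0.03),
    tauDR = c(0.04, 0.04, 0.04, 0.04, 0.04, 0.04, 0.04, 2.0),
    qcPass = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_message(cv <- bindingCurve(scans, aFactor = 0.964), "dropping")
  # scan 4: qc; scan 6: tauD ratio > 3; scan 8: tauD out of range
  det <- cv@details
  expect_equal(det$reason[4L], "qc")
  expect_equal(det$reason[6L], "tauD")
  expect_equal(det$reason[8L], "tauD")
  expect_equal(cv@cL, 0.1)   # the 1 nM point fell below three scans
  expect_equal(cv@nScans, 3L)
  expect_equal(cv@gamma, mean(c(0.11, 0.12, 0.10)))

  scans$qcPass <- FALSE
  expect_error(bindingCurve(scans, aFactor = 0.964), "surviving")
})
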