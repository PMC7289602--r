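# Photon-level simulator: particle statistics, Brownian scaling, photon
# budgets, and the seeded determinism contract.

test_that("particle numbers are Poisson with mean density x area", {
  counts <- vapply(1:40, function(s) {
    cfg <- quickConfig(seed = s, duration = 0.01, boxSide = 4,
                       densities = c(RL = 5))
    nrow(simulateTrajectories(cfg)@particles)
  }, 0)
  mu <- 5 * 16
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / 40))
  expect_gt(stats::var(counts), mu / 3)   # genuinely dispersed
})

test_that("ensemble MSD grows as 4 D dt (and D = 0 freezes particles)", {
  cfg <- quickConfig(seed = 11, duration = 0.3, boxSide = 10,
                     densities = c(RL = 12), D = 0.4)
  traj <- simulateTrajectories(cfg)
  p <- trajectoryChunk(traj, 1L)
  lags <- c(100L, 400L, 800L, 1600L, 2400L)
  n <- nrow(p$x)
  msd <- vapply(lags, function(d) {
    dx <- p$x[seq_len(n - d), ] - p$x[seq_len(n - d) + d, ]
    dy <- p$y[seq_len(n - d), ] - p$y[seq_len(n - d) + d, ]
    mean(dx^2 + dy^2)
  }, 0)
  fit <- stats::lm(msd ~ 0 + I(lags * cfg@timeStep))
  slope <- stats::coef(fit)[[1L]]
  se <- summary(fit)$coefficients[1L, 2L]
  expect_lt(abs(slope - 4 * 0.4), 3 * max(se, 0.02 * 4 * 0.4))

  cfg0 <- quickConfig(seed = 11, duration = 0.05, densities = c(RL = 10),
                      D = 0)
  tr0 <- simulateTrajectories(cfg0)
  p0 <- trajectoryChunk(tr0, 1L)
  expect_equal(max(abs(sweep(p0$x, 2L, p0$x[1L, ]))), 0)
  expect_equal(max(abs(sweep(p0$y, 2L, p0$y[1L, ]))), 0)
})

test_that("zero brightness leaves pure Poisson background in both gates", {
  cfg <- quickConfig(seed = 3, duration = 1, densities = c(RL = 30),
                     background = 2)
  cfg@brightness[] <- 0
  st <- quickStream(cfg)
  ev <- photonEvents(st)
  mu <- 2e3 * 1   # 2 kHz x 1 s per channel
  ng <- sum(ev$micro_time_ns < 12.5)
  nr <- nrow(ev) - ng
  expect_lt(abs(ng - mu), 4 * sqrt(mu))
  expect_lt(abs(nr - mu), 4 * sqrt(mu))
  expect_true(all(diff(ev$macro_time_ns) >= 0))
})

test_that("one immobile fluorophore at the focus center emits the
           numerically integrated Gaussian transit dose per cycle", {
  opt <- testOptics()
  cfg <- quickConfig(seed = 5, duration = 4, boxSide = 2,
                     densities = c(RL = 1), background = 0)
  traj <- immobileTrajectories(cfg, x = 1, y = 1)   # patch center = focus
  st <- simulatePhotons(traj, opt, cfg)
  ev <- photonEvents(st)
  nCycles <- cfg@duration * opt@tagFrequency * 1e3
  doseG <- axialDosePerCycle(opt, opt@z0G)
  doseR <- axialDosePerCycle(opt, opt@z0R)
  expG <- cfg@brightness[["G"]] * doseG * nCycles
  expR <- cfg@brightness[["R"]] * doseR * nCycles
  ng <- sum(ev$micro_time_ns < 12.5)
  nr <- nrow(ev) - ng
  expect_lt(abs(ng - expG), 4 * sqrt(expG))
  expect_lt(abs(nr - expR), 4 * sqrt(expR))
})

test_that("without bleaching the photon rate is wide-sense stationary", {
  cfg <- quickConfig(seed = 9, duration = 2, densities = c(RL = 60))
  st <- quickStream(cfg)
  tn <- photonEvents(st)$macro_time_ns
  half <- cfg@duration * 5e8
  n1 <- sum(tn < half); n2 <- sum(tn >= half)
  ## half-trace counts fluctuate through occupancy, not just shot noise:
  ## relative SD per half ~ sqrt(G0 * 2 tauD / T_half) ~ 5-7%
  mu <- (n1 + n2) / 2
  expect_lt(abs(n1 - n2), 3 * (0.07 * mu + sqrt(n1 + n2)))
})

test_that("bleaching removes emitters and is disabled at zero cross-section", {
  cfg <- quickConfig(seed = 21, duration = 3, densities = c(RL = 60))
  st0 <- quickStream(cfg)
  expect_identical(unname(st0@info$bleached), c(0L, 0L))
  cfgB <- cfg
  cfgB@bleachCrossSection[] <- 5e-5
  stB <- quickStream(cfgB)
  expect_gt(sum(stB@info$bleached), 0L)
  # photon total drops when emitters die
  expect_lt(nrow(photonEvents(stB)), nrow(photonEvents(st0)))
})

test_that("maturation yields control the fluorophore label states", {
  cfg <- quickConfig(seed = 31, duration = 0.01, boxSide = 6,
                     densities = c(RL = 30))
  cfg@etaG <- 0.6; cfg@etaR <- 0.4
  prt <- simulateTrajectories(cfg)@particles
  n <- nrow(prt)
  expect_lt(abs(mean(prt$fluorG) - 0.6), 3 * sqrt(0.24 / n))
  expect_lt(abs(mean(prt$fluorR) - 0.4), 3 * sqrt(0.24 / n))
})

test_that("binding series splits receptors by the isotherm and conserves totals", {
  expect_equal(boundFraction(0.08, 0.4), 1 / 1.2, tolerance = 1e-12)
  expect_equal(boundFraction(2, 2), 0.5)
  expect_equal(boundFraction(2, 0), 0)
  cfg <- quickConfig(seed = 41, duration = 0.01, boxSide = 4,
                     densities = c(R = 30, RL = 0))
  cfg@kD <- 1; cfg@cLSeries <- c(0, 1, 9)
  ser <- makeBindingSeries(cfg, testOptics())
  expect_length(ser, 3L)
  expect_equal(vapply(ser, `[[`, 0, "boundFraction"), c(0, 0.5, 0.9))
  # at cL = 0 nothing is bound: no dual or green-only species
  expect_identical(ser[[1L]]$truth[["dual"]], 0)
  expect_identical(ser[[1L]]$truth[["greenOnly"]], 0)
  # total receptor density conserved across the series (Poisson means)
  expect_error(makeBindingSeries(quickConfig(), testOptics()), "kD")
})

test_that("identical seeds reproduce bit-identical photon streams", {
  cfg <- quickConfig(seed = 77, duration = 0.5, densities = c(RL = 25))
  s1 <- quickStream(cfg)
  s2 <- quickStream(cfg)
  expect_identical(photonEvents(s1), photonEvents(s2))
  cfg2 <- cfg; cfg2@seed <- 78L
  expect_false(identical(photonEvents(quickStream(cfg2)),
                         photonEvents(s1)))
})

test_that("configuration validation rejects non-physical values", {
  expect_error(simConfig(boxSide = -1), "boxSide")
  expect_error(simConfig(etaG = 0), "etaG")
  expect_error(simConfig(densities = c(bogus = 1)), "unknown")
  expect_error(opticsConfig(pieWindow = 30), "pieWindow")
  expect_error(opticsConfig(z0G = 10), "z0")
})
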