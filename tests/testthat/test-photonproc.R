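# Channel gating, phase-to-z mapping, and kymograph construction.

fakeStream <- function(micro, macro = seq_along(micro) * 1e3,
                       phase = rep(0.1, length(micro))) {
  new("PhotonStream",
      events = data.frame(macro_time_ns = macro, micro_time_ns = micro,
                          tag_cycle = floor(macro / 6802.7),
                          tag_phase = phase),
      optics = testOptics(), info = list(duration = max(macro) * 1e-9))
}

test_that("PIE gates partition photons with a half-open boundary", {
  st <- fakeStream(c(5, 15, 12.5, 0, 24.9))
  gg <- gateChannels(st)
  expect_equal(gg$G$micro_time_ns, c(5, 0))
  expect_equal(gg$R$micro_time_ns, c(15, 12.5, 24.9))  # 12.5 ns -> red
  expect_equal(nrow(gg$G) + nrow(gg$R), nrow(photonEvents(st)))
  expect_error(gateChannels(st, pieWindow = 25), "pieWindow")

  cfg <- quickConfig(seed = 2, duration = 0.5, densities = c(RL = 30))
  sim <- quickStream(cfg)
  g2 <- gateChannels(sim)
  expect_equal(nrow(g2$G) + nrow(g2$R), nrow(photonEvents(sim)))
})

test_that("phase maps to a sinusoidal z with correct turning points", {
  opt <- testOptics()
  a <- sweepAmplitude(opt)
  expect_equal(scanPeriod(opt), 1e3 / 147, tolerance = 1e-12)  # ~6.8 us
  m <- mapPhaseToZ(c(0, 0.25, 0.5, 0.75), opt)
  expect_equal(m$z, c(0, a, 0, -a), tolerance = 1e-9)
  expect_equal(m$direction, c("up", "down", "down", "up"))
  expect_error(mapPhaseToZ(1, opt), "phase")
  # antisymmetric about the sweep center and periodic
  ph <- seq(0, 0.499, by = 0.013)
  expect_equal(mapPhaseToZ(ph, opt)$z,
               -mapPhaseToZ(0.5 + ph, opt)$z, tolerance = 1e-12)
})

test_that("dwell weights reflect the sinusoidal speed profile", {
  mp <- zMapping(testOptics(), nPixels = 26L)
  dw <- dwellWeights(mp)
  expect_length(dw, 26L)
  expect_true(all(dw > 0))
  # slowest near the turning points (after capping), fastest at center
  expect_gt(dw[1L], dw[13L])
  expect_lte(max(dw) / min(dw), 5 + 1e-9)
  expect_equal(mean(dw), 1, tolerance = 1e-12)
  # user calibration override
  a <- sweepAmplitude(testOptics())
  mpLin <- zMapping(testOptics(), nPixels = 10L,
                    calibration = function(phi) a * (2 * phi - 1))
  expect_equal(max(dwellWeights(mpLin)) / min(dwellWeights(mpLin)), 1,
               tolerance = 0.05)   # linear sweep -> uniform dwell
})

test_that("kymograph binning conserves photons and inverts dwell rescaling", {
  cfg <- quickConfig(seed = 6, duration = 1, densities = c(RL = 40))
  st <- quickStream(cfg)
  mp <- zMapping(st@optics)
  km <- buildKymograph(st, mp, lineTime = 0.1)
  expect_equal(nLines(km), 10L)
  expect_equal(sum(kymoRawCounts(km, "G")) + sum(kymoRawCounts(km, "R")),
               nrow(photonEvents(st)))
  for (ch in c("G", "R"))
    expect_equal(sweep(kymoCounts(km, ch), 2L, dwellWeights(mp), "*"),
                 kymoRawCounts(km, ch) + 0, tolerance = 1e-12)
  # 60 s at 0.5 s lines -> 120 lines (synthetic, cheap)
  ev <- data.frame(macro_time_ns = c(1, 59.9e9), micro_time_ns = c(1, 1),
                   tag_cycle = c(0, 1), tag_phase = c(0.1, 0.2))
  km2 <- buildKymograph(ev, mp, lineTime = 0.5, duration = 60)
  expect_equal(nLines(km2), 120L)
  # empty photon set -> all-zero kymograph, flagged
  km0 <- buildKymograph(ev[0, ], mp, lineTime = 0.5, duration = 10)
  expect_true(all(kymoRawCounts(km0, "G") == 0))
  expect_true(km0@empty[["G"]])
})

test_that("a temporally uniform emitter gives flat rescaled counts and
           raw counts peaked at the turning points", {
  set.seed(42)
  n <- 2e5
  ev <- data.frame(macro_time_ns = sort(stats::runif(n, 0, 1e9)),
                   micro_time_ns = rep(5, n), tag_cycle = 0,
                   tag_phase = stats::runif(n))
  mp <- zMapping(testOptics(), nPixels = 26L)
  km <- buildKymograph(ev, mp, lineTime = 1, duration = 1, channel = "G")
  raw <- colSums(kymoRawCounts(km, "G"))
  resc <- colSums(kymoCounts(km, "G"))
  expect_gt(raw[1L], 2 * raw[13L])          # turning points pile up
  inner <- 3:24                             # clear of the capped edges
  expected <- n * diff(asin(mp@pixelEdges / mp@amplitude)) / pi
  z <- (resc[inner] - expected[inner] / dwellWeights(mp)[inner]) /
    sqrt(expected[inner]) * dwellWeights(mp)[inner]
  expect_lt(max(abs(z)), 4)                 # flat within counting noise
})
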