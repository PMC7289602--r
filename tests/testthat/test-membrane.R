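# Membrane tracking, signal/background extraction, quality control.

test_that("a static ridge is tracked exactly", {
  m <- matrix(0, 20, 26); m[, 13] <- 50
  km <- flatKymograph(m)
  tr <- trackMembrane(km)
  expect_true(all(ridgePositions(tr) == 13))
  expect_equal(tr@smoothness, 0)
})

test_that("two delta ridges are returned sorted and non-adjacent", {
  m <- matrix(0, 10, 26); m[, 5] <- 30; m[, 20] <- 40
  tr <- trackMembrane(flatKymograph(m), nRidges = 2L)
  expect_true(all(ridgePositions(tr)[, 1L] == 5))
  expect_true(all(ridgePositions(tr)[, 2L] == 20))
})

test_that("a drifting membrane is recovered within a pixel RMS", {
  set.seed(7)
  nl <- 60
  truth <- 13 + 2 * sin(2 * pi * seq_len(nl) / 30)
  m <- matrix(stats::rpois(nl * 26, 0.5), nl, 26)
  for (l in seq_len(nl))
    m[l, round(truth[l])] <- m[l, round(truth[l])] + 60
  tr <- trackMembrane(flatKymograph(m))
  rms <- sqrt(mean((ridgePositions(tr)[, 1L] - truth)^2))
  expect_lt(rms, 1)
})

test_that("empty lines carry the previous position and flag low signal", {
  # lines 3-5 are dark, so line 4 stays empty even after 3-line smoothing
  m <- matrix(0, 7, 26); m[c(1, 2, 6, 7), 10] <- 20
  tr <- trackMembrane(flatKymograph(m))
  expect_true(all(ridgePositions(tr) == 10))
  expect_true(tr@lowSignal)
  expect_error(trackMembrane(flatKymograph(matrix(0, 4, 26))), "all-zero")
})

test_that("signal extraction sums the 5-pixel window around the ridge", {
  line <- c(0, 1, 3, 9, 3, 1, 0, rep(0, 19))
  km <- flatKymograph(matrix(line, 1, 26, byrow = TRUE), lineTime = 1)
  tr <- flatTrace(matrix(4, 1, 1), lineTime = 1)
  s <- extractSignal(km, tr, halfwidth = 2L)
  expect_equal(s$traces$G, 1 + 3 + 9 + 3 + 1)
  s0 <- extractSignal(km, tr, halfwidth = 0L)
  expect_equal(s0$traces$G, 9)
  # window clipped by the edge -> sample dropped
  trEdge <- flatTrace(matrix(1, 1, 1), lineTime = 1)
  sE <- extractSignal(km, trEdge, halfwidth = 2L)
  expect_true(sE$dropped[1L])
})

test_that("background regions are scaled by the pixel-number ratio", {
  m <- matrix(0, 3, 30)
  m[, 12 - 5] <- 1; m[, 12 + 5] <- 2; m[, 18 - 5] <- 1; m[, 18 + 5] <- 2
  km <- flatKymograph(m, lineTime = 1)
  tr <- flatTrace(cbind(rep(12, 3), rep(18, 3)), lineTime = 1, nPixels = 30)
  bg <- extractBackground(km, tr, offset = 5L, halfwidth = 2L)
  # four 1-pixel regions summing to 6, scaled by 10 signal px / 4 bg px
  expect_equal(bg$traces$G, rep(6 * 10 / 4, 3))
  # single membrane, default scaling 5/2
  tr1 <- flatTrace(matrix(12, 3, 1), lineTime = 1, nPixels = 30)
  bg1 <- extractBackground(km, tr1, offset = 5L, halfwidth = 2L)
  expect_equal(bg1$traces$G, rep(3 * 5 / 2, 3))
})

test_that("homogeneous background matches the signal-window expectation", {
  b <- 2.5
  m <- matrix(b, 8, 26)
  km <- flatKymograph(m, lineTime = 1)
  tr <- flatTrace(matrix(13, 8, 1), lineTime = 1)
  bg <- extractBackground(km, tr, offset = 10L, halfwidth = 2L)
  s <- extractSignal(km, tr, halfwidth = 2L)
  expect_equal(bg$traces$G, s$traces$G)   # both equal 5 b
  expect_equal(bg$traces$G, rep(5 * b, 8))
})

test_that("quality control flags the discard conditions", {
  # clean scan passes
  m <- matrix(stats::rpois(40 * 26, 0.2), 40, 26); m[, 13] <- 40
  km <- flatKymograph(m)
  tr <- trackMembrane(km)
  s <- extractSignal(km, tr); b <- extractBackground(km, tr)
  expect_true(qcPass(qcChecks(km, tr, s, b)))

  # membrane near the turning point -> off_center
  mOff <- matrix(stats::rpois(40 * 26, 0.2), 40, 26); mOff[, 3] <- 40
  kmO <- flatKymograph(mOff)
  trO <- trackMembrane(kmO)
  sO <- extractSignal(kmO, trO); bO <- extractBackground(kmO, trO)
  qcO <- qcChecks(kmO, trO, sO, bO)
  expect_true(qcFlags(qcO)[["off_center"]])
  expect_false(qcPass(qcO))

  # transient bright feature -> bright_cluster
  mC <- matrix(0.3, 40, 26); mC[, 13] <- 30
  mC[20:21, 13] <- 400
  kmC <- flatKymograph(mC)
  trC <- trackMembrane(kmC)
  sC <- extractSignal(kmC, trC); bC <- extractBackground(kmC, trC)
  expect_true(qcFlags(qcChecks(kmC, trC, sC, bC))[["bright_cluster"]])

  # fluctuating membrane
  set.seed(2)
  mF <- matrix(0.2, 60, 26)
  pos <- pmin(pmax(round(13 + stats::rnorm(60, 0, 4)), 3), 24)
  for (l in 1:60) mF[l, pos[l]] <- 30
  kmF <- flatKymograph(mF)
  trF <- trackMembrane(kmF)
  sF <- extractSignal(kmF, trF); bF <- extractBackground(kmF, trF)
  expect_true(qcFlags(qcChecks(kmF, trF, sF, bF))[["fluctuating_membrane"]])
})

test_that("the 5-pixel window captures the predicted share of membrane
           photons (axial Gaussian emission profile)", {
  cfg <- quickConfig(seed = 13, duration = 1.5, densities = c(RL = 50),
                     background = 0)
  st <- quickStream(cfg)
  opt <- st@optics
  mp <- zMapping(opt)
  a <- sweepAmplitude(opt)
  zw <- 2.5 * diff(zPixelEdges(mp))[1L]   # half width of the 5-px window
  gates <- gateChannels(st)
  for (ch in c("G", "R")) {
    z0 <- slot(opt, paste0("z0", ch)) * 1e-3
    # photons are emitted in time with rate following the axial profile
    prof <- function(phi) exp(-2 * (a * sin(2 * pi * phi))^2 / z0^2)
    inWin <- function(phi) prof(phi) * (abs(a * sin(2 * pi * phi)) <= zw)
    predicted <- stats::integrate(inWin, 0, 1, subdivisions = 500L,
                                  stop.on.error = FALSE)$value /
      stats::integrate(prof, 0, 1)$value
    z <- a * sin(2 * pi * gates[[ch]]$tag_phase)
    measured <- mean(abs(z) <= zw)
    n <- nrow(gates[[ch]])
    expect_lt(abs(measured - predicted),
              4 * sqrt(predicted * (1 - predicted) / n) + 0.01)
  }
})
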