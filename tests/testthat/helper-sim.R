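# Shared fixtures: small, fast simulation configurations used across the
# suite. Problem sizes are deliberately modest (seconds of scan time,
# micrometer-scale patches) so the whole suite stays quick; the scaling
# rationale lives in the methods vignette.

testOptics <- function(...) opticsConfig(...)

testCalib <- function() waistCalibration(207, 251)

# small clean scan: no bleaching, mild background, full maturation
quickConfig <- function(seed = 1L, duration = 1.5, boxSide = 2,
                        densities = c(RL = 40), background = 0.5,
                        D = 0.35, ...) {
  simConfig(boxSide = boxSide, densities = densities, dCoef = D,
            duration = duration, etaG = 1, etaR = 1,
            brightness = c(G = 0.03, R = 0.024),
            backgroundRate = c(G = background, R = background),
            bleachCrossSection = 0, seed = seed, ...)
}

quickStream <- function(cfg, optics = testOptics()) {
  simulatePhotons(simulateTrajectories(cfg), optics, cfg)
}

# hand-built single-particle trajectories (deterministic, immobile)
immobileTrajectories <- function(cfg, x, y) {
  nSteps <- as.integer(round(cfg@duration / cfg@timeStep))
  particles <- data.frame(species = "RL", fluorG = TRUE, fluorR = TRUE)
  b <- array(0, dim = c(2L, 1L, 2L))
  b[, 1L, 1L] <- x; b[, 1L, 2L] <- y
  new("Trajectories", particles = particles, boundaries = b,
      chunkSeeds = axialFCS:::.childSeed(cfg@seed, 1001L),
      chunkSize = nSteps, nSteps = nSteps, timeStep = cfg@timeStep,
      boxSide = cfg@boxSide, dPart = 0, seed = cfg@seed)
}

# kymograph with uniform dwell weights, built from a counts matrix
flatKymograph <- function(m, lineTime = 0.5, amplitude = 2.65,
                          channels = c("G", "R")) {
  np <- ncol(m)
  mapping <- new("ZMapping", amplitude = amplitude,
                 pixelEdges = seq(-amplitude, amplitude,
                                  length.out = np + 1L),
                 dwellWeight = rep(1, np), calibration = NULL)
  counts <- stats::setNames(rep(list(m), length(channels)), channels)
  new("Kymograph", counts = counts, raw = counts, lineTime = lineTime,
      mapping = mapping, empty = vapply(counts, function(x) sum(x) == 0, TRUE))
}

flatTrace <- function(positions, lineTime = 0.5, nPixels = 26L) {
  pos <- as.matrix(positions)
  new("MembraneTrace", positions = pos, lineTime = lineTime,
      nPixels = as.integer(nPixels),
      smoothness = apply(pos, 2L, stats::sd),
      centering = mean(abs(pos - (nPixels + 1) / 2)),
      lowSignal = FALSE)
}

# axial Gaussian transit dose per oscillation cycle (us), by quadrature;
# independent of the grid-based computation inside the simulator
axialDosePerCycle <- function(optics, z0nm, zMem = 0) {
  a <- sweepAmplitude(optics)
  periodUs <- scanPeriod(optics)
  f <- function(phi) exp(-2 * (a * sin(2 * pi * phi) - zMem)^2 /
                           (z0nm * 1e-3)^2)
  periodUs * stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
}
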