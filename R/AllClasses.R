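#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## Configuration classes
## ---------------------------------------------------------------------------

#' OpticsConfig: optical and scan geometry of the axial lsFCS instrument
#'
#' Describes the two-color confocal observation volume and the resonant
#' axial scan. Waists are 1/e^2 radii. The focus is swept along z as
#' z(t) = a sin(2 pi f t) with a = \code{tagAmplitude * driveFraction}.
#'
#' @slot omegaG,omegaR lateral 1/e^2 waists (nm) of the green and red channel
#' @slot z0G,z0R axial 1/e^2 half-lengths (nm)
#' @slot tagFrequency resonance frequency of the axial scanner (kHz)
#' @slot tagAmplitude peak axial excursion at full drive (um)
#' @slot driveFraction fraction of the maximum drive amplitude in use
#' @slot pieWindow micro-time gate boundary between the two color
#'   channels (ns); photons with micro time below the boundary belong to
#'   the green channel, all others to the red channel
#' @exportClass OpticsConfig
setClass("OpticsConfig", representation(
  omegaG = "numeric", omegaR = "numeric",
  z0G = "numeric", z0R = "numeric",
  tagFrequency = "numeric", tagAmplitude = "numeric",
  driveFraction = "numeric", pieWindow = "numeric"
))

setValidity("OpticsConfig", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L && is.finite(x)
  for (s in c("omegaG", "omegaR", "z0G", "z0R", "tagFrequency",
              "tagAmplitude", "driveFraction", "pieWindow"))
    if (!num1(slot(object, s))) msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  if (length(msg)) return(msg)
  if (object@omegaG <= 0 || object@omegaR <= 0) msg <- c(msg, "waists must be > 0")
  if (object@z0G < object@omegaG || object@z0R < object@omegaR)
    msg <- c(msg, "z0 must be >= omega for a confocal volume")
  if (object@tagFrequency <= 0) msg <- c(msg, "tagFrequency must be > 0")
  if (object@tagAmplitude <= 0) msg <- c(msg, "tagAmplitude must be > 0")
  if (object@driveFraction <= 0 || object@driveFraction > 1)
    msg <- c(msg, "driveFraction must be in (0, 1]")
  if (object@pieWindow <= 0 || object@pieWindow >= 25)
    msg <- c(msg, "pieWindow must lie strictly inside (0, 25) ns")
  if (length(msg)) msg else TRUE
})

#' SimConfig: parameters of the photon-level membrane simulation
#'
#' Defines a periodic square membrane patch populated with diffusing
#' fluorescent species, the photophysics of their labels and the
#' acquisition duration. Species names: \code{"R"} receptor carrying a red
#' tag only, \code{"G"} a green-only species, \code{"RL"} a dual-label
#' ligand-receptor complex, \code{"rL"} a complex on an unlabeled receptor
#' (green only), \code{"dark"} unlabeled receptors. Fluorophore maturation
#' is drawn per label with yields \code{etaG}, \code{etaR}.
#'
#' @slot boxSide side length of the periodic membrane patch (um)
#' @slot densities named per-species area densities (um^-2)
#' @slot dCoef diffusion coefficient(s) (um^2 s^-1); a single value or a
#'   value per species
#' @slot kD equilibrium dissociation coefficient (nM), used by
#'   \code{\link{makeBindingSeries}}; \code{NA} when unused
#' @slot cLSeries ligand concentrations (nM) for a binding series
#' @slot etaG,etaR fluorophore maturation yields in (0, 1]
#' @slot brightness mean detected photons per fluorophore per us at the
#'   focus center, named per channel (G, R)
#' @slot backgroundRate uncorrelated background count rate per channel (kHz)
#' @slot bleachCrossSection per-fluorophore bleaching probability per us of
#'   center-equivalent excitation exposure, named per channel
#' @slot duration scan duration (s)
#' @slot timeStep trajectory update interval (s); photon phases inside a
#'   step are drawn from the exact axial sweep profile
#' @slot driftAmplitude,driftPeriod optional slow sinusoidal membrane drift
#'   along z (um, s); amplitude 0 disables drift
#' @slot crosstalk fraction of green-emitter photons leaking into the red
#'   gate (0 by default; PIE suppresses crosstalk)
#' @slot lateralAspect aspect ratio of the lateral observation area
#'   (1 = circular; > 1 emulates the elongated area of lateral line
#'   scanning)
#' @slot seed integer RNG seed; all stochastic draws derive from it
#' @exportClass SimConfig
setClass("SimConfig", representation(
  boxSide = "numeric", densities = "numeric", dCoef = "numeric",
  kD = "numeric", cLSeries = "numeric",
  etaG = "numeric", etaR = "numeric",
  brightness = "numeric", backgroundRate = "numeric",
  bleachCrossSection = "numeric",
  duration = "numeric", timeStep = "numeric",
  driftAmplitude = "numeric", driftPeriod = "numeric",
  crosstalk = "numeric", lateralAspect = "numeric", seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (!(length(object@boxSide) == 1L && is.finite(object@boxSide) && object@boxSide > 0))
    msg <- c(msg, "boxSide must be a single positive number")
  if (length(object@densities) &&
      (!all(is.finite(object@densities)) || any(object@densities < 0)))
    msg <- c(msg, "densities must be finite and >= 0")
  bad <- setdiff(names(object@densities), c("R", "G", "RL", "rL", "dark"))
  if (length(bad)) msg <- c(msg, paste("unknown species:", paste(bad, collapse = ", ")))
  if (any(!is.finite(object@dCoef)) || any(object@dCoef < 0))
    msg <- c(msg, "dCoef must be finite and >= 0")
  for (s in c("etaG", "etaR")) {
    v <- slot(object, s)
    if (!(length(v) == 1L && is.finite(v) && v > 0 && v <= 1))
      msg <- c(msg, sprintf("'%s' must lie in (0, 1]", s))
  }
  if (any(!is.finite(object@brightness)) || any(object@brightness < 0))
    msg <- c(msg, "brightness must be finite and >= 0")
  if (any(!is.finite(object@backgroundRate)) || any(object@backgroundRate < 0))
    msg <- c(msg, "backgroundRate must be finite and >= 0")
  if (any(!is.finite(object@bleachCrossSection)) || any(object@bleachCrossSection < 0))
    msg <- c(msg, "bleachCrossSection must be finite and >= 0")
  if (!(length(object@duration) == 1L && is.finite(object@duration) && object@duration > 0))
    msg <- c(msg, "duration must be a single positive number")
  if (!(length(object@timeStep) == 1L && is.finite(object@timeStep) && object@timeStep > 0))
    msg <- c(msg, "timeStep must be a single positive number")
  if (!is.na(object@kD) && object@kD <= 0) msg <- c(msg, "kD must be > 0 when set")
  if (length(object@cLSeries) && (any(!is.finite(object@cLSeries)) || any(object@cLSeries < 0)))
    msg <- c(msg, "cLSeries must be finite and >= 0")
  if (object@crosstalk < 0 || object@crosstalk >= 1)
    msg <- c(msg, "crosstalk must lie in [0, 1)")
  if (object@lateralAspect < 1) msg <- c(msg, "lateralAspect must be >= 1")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' Trajectories: Brownian particle paths on the membrane patch
#'
#' Particle positions are stored as chunk boundary snapshots plus
#' per-chunk RNG sub-seeds, so that any chunk can be re-materialized
#' exactly (see \code{\link{trajectoryChunk}}) without holding the full
#' step-by-step path of every particle in memory. Positions are unwrapped;
#' periodic wrapping is applied when distances to the focus are computed.
#'
#' @slot particles data.frame with one row per particle: species, fluorG,
#'   fluorR (logical label states drawn with the maturation yields)
#' @slot boundaries numeric array (nChunks + 1) x nParticles x 2 of
#'   unwrapped positions (um) at chunk boundaries
#' @slot chunkSeeds integer seeds regenerating the within-chunk increments
#' @slot chunkSize steps per chunk
#' @slot nSteps total number of trajectory steps
#' @slot timeStep step duration (s)
#' @slot boxSide patch side (um)
#' @slot dPart per-particle diffusion coefficient (um^2 s^-1)
#' @slot seed the SimConfig seed the trajectories derive from
#' @exportClass Trajectories
setClass("Trajectories", representation(
  particles = "data.frame", boundaries = "array", chunkSeeds = "integer",
  chunkSize = "integer", nSteps = "integer", timeStep = "numeric",
  boxSide = "numeric", dPart = "numeric", seed = "integer"
))

#' PhotonStream: time-tagged photon events
#'
#' The raw output of the instrument or of \code{\link{simulatePhotons}}.
#' Each record carries the macro time (ns since acquisition start), the
#' micro time (ns since the last laser pulse, in [0, 25)), the index of
#' the axial oscillation cycle and the phase within the cycle in [0, 1).
#' Channel identity is encoded in the micro time via the PIE gates.
#'
#' @slot events data.frame with columns macro_time_ns, micro_time_ns,
#'   tag_cycle, tag_phase
#' @slot optics the \linkS4class{OpticsConfig} in force during acquisition
#' @slot info list of acquisition metadata (seed, duration, realized
#'   particle numbers per fluorophore category for simulated streams)
#' @exportClass PhotonStream
setClass("PhotonStream", representation(
  events = "data.frame", optics = "OpticsConfig", info = "list"
))

setValidity("PhotonStream", function(object) {
  ev <- object@events
  need <- c("macro_time_ns", "micro_time_ns", "tag_cycle", "tag_phase")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns", paste(need, collapse = ", ")))
  if (nrow(ev)) {
    if (is.unsorted(ev$macro_time_ns)) return("macro_time_ns must be non-decreasing")
    if (any(ev$micro_time_ns < 0 | ev$micro_time_ns >= 25))
      return("micro_time_ns must lie in [0, 25) ns")
    if (any(ev$tag_phase < 0 | ev$tag_phase >= 1))
      return("tag_phase must lie in [0, 1)")
  }
  TRUE
})

#' ZMapping: phase-to-z calibration of the axial sweep
#'
#' Maps the oscillation phase to an axial position and carries the z pixel
#' grid together with per-pixel relative dwell times. For the ideal
#' resonant scanner the mapping is sinusoidal; a measured calibration can
#' be supplied as a function phase -> z (um).
#'
#' @slot amplitude sweep amplitude a (um); z spans [-a, a]
#' @slot pixelEdges strictly increasing z bin edges (um)
#' @slot dwellWeight per-pixel relative dwell time (mean 1 over covered
#'   pixels, capped near the turning points)
#' @slot calibration optional function(phase) -> z (um) overriding the
#'   sinusoid
#' @exportClass ZMapping
setClass("ZMapping", representation(
  amplitude = "numeric", pixelEdges = "numeric", dwellWeight = "numeric",
  calibration = "ANY"
))

setValidity("ZMapping", function(object) {
  if (is.unsorted(object@pixelEdges, strictly = TRUE))
    return("pixelEdges must be strictly increasing")
  if (length(object@dwellWeight) != length(object@pixelEdges) - 1L)
    return("dwellWeight must have one value per pixel")
  if (any(object@dwellWeight <= 0)) return("dwellWeight must be > 0")
  TRUE
})

#' Kymograph: scan line x z-pixel count matrices
#'
#' Per-channel matrices of photon counts collected during repeated axial
#' sweeps, binned into scan lines of \code{lineTime} seconds and z pixels
#' of the associated \linkS4class{ZMapping}. \code{counts} are rescaled by
#' the per-pixel dwell weights; \code{raw} are the plain histogram counts,
#' so that \code{counts * dwellWeight == raw} pixelwise.
#'
#' @slot counts named list of dwell-rescaled matrices (lines x pixels)
#' @slot raw named list of raw count matrices
#' @slot lineTime line duration (s)
#' @slot mapping the \linkS4class{ZMapping} used for binning
#' @slot empty logical flag raised when a channel received no photons
#' @exportClass Kymograph
setClass("Kymograph", representation(
  counts = "list", raw = "list", lineTime = "numeric",
  mapping = "ZMapping", empty = "logical"
))

setValidity("Kymograph", function(object) {
  if (!length(object@counts)) return("at least one channel required")
  if (!identical(names(object@counts), names(object@raw)))
    return("counts and raw must have the same channels")
  np <- length(object@mapping@pixelEdges) - 1L
  for (ch in names(object@counts)) {
    if (!identical(dim(object@counts[[ch]]), dim(object@raw[[ch]])))
      return("counts and raw dimensions differ")
    if (ncol(object@counts[[ch]]) != np)
      return("column count must match the z pixel grid")
  }
  TRUE
})

#' MembraneTrace: tracked membrane crossing positions
#'
#' @slot positions matrix (lines x nRidges) of z-pixel indices (1-based,
#'   possibly fractional after smoothing); ridges sorted by z per line
#' @slot lineTime line duration (s) of the kymograph the trace came from
#' @slot nPixels pixel count of that kymograph
#' @slot smoothness per-ridge SD of the position (pixels)
#' @slot centering mean distance of the ridges from the sweep center
#'   (pixels)
#' @slot lowSignal logical; TRUE when empty lines forced carry-forward
#' @exportClass MembraneTrace
setClass("MembraneTrace", representation(
  positions = "matrix", lineTime = "numeric", nPixels = "integer",
  smoothness = "numeric", centering = "numeric", lowSignal = "logical"
))

#' QCReport: automated scan quality control
#'
#' Automation of the discard rules applied to recorded kymographs: scans
#' with bright clusters near the membrane, strongly fluctuating membrane
#' positions, a membrane far from the sweep center, or too little signal
#' over background are flagged. \code{pass} is TRUE iff no flag is raised.
#'
#' @slot flags named logical vector: bright_cluster, fluctuating_membrane,
#'   off_center, low_signal
#' @slot evidence named numeric vector backing each flag
#' @slot pass logical
#' @exportClass QCReport
setClass("QCReport", representation(
  flags = "logical", evidence = "numeric", pass = "logical"
))

setValidity("QCReport", function(object) {
  if (!identical(object@pass, !any(object@flags)))
    return("pass must be TRUE iff no flag is raised")
  TRUE
})

#' IntensityTraces: membrane signal and background time series
#'
#' Raw membrane intensity and scaled background per channel on a common
#' fine time grid, the input of the correction stage.
#'
#' @slot t sample times (s), bin centers
#' @slot sampleTime bin width (s)
#' @slot raw named list (G, R) of raw signal traces (counts per bin,
#'   dwell-rescaled)
#' @slot bg named list (G, R) of background traces scaled to the signal
#'   window
#' @slot qc the scan's \linkS4class{QCReport} (or NULL before QC)
#' @slot meta list (window half width, background offset, scan id, ...)
#' @exportClass IntensityTraces
setClass("IntensityTraces", representation(
  t = "numeric", sampleTime = "numeric", raw = "list", bg = "list",
  qc = "ANY", meta = "list"
))

setValidity("IntensityTraces", function(object) {
  ln <- vapply(c(object@raw, object@bg), length, 1L)
  if (length(unique(c(ln, length(object@t)))) != 1L)
    return("all traces must share the time grid")
  if (any(vapply(object@raw, function(v) any(v < 0), TRUE)))
    return("raw intensities must be >= 0")
  TRUE
})

#' SixSineCurve: smooth curve model used for noise filtering
#'
#' A sum of six sine terms a_k sin(b_k t + c_k) fitted by least squares,
#' used to smooth background traces and to model the photobleaching
#' correction function gamma(t).
#'
#' @slot amp,freq,phase the 6 amplitudes, angular frequencies (rad/s) and
#'   phases
#' @slot domain fitted domain c(0, T) (s)
#' @slot residualRMS root-mean-square residual of the fit
#' @slot fallback TRUE when the sine fit failed to converge and a monotone
#'   spline was substituted
#' @slot spline the fallback spline function (or NULL)
#' @exportClass SixSineCurve
setClass("SixSineCurve", representation(
  amp = "numeric", freq = "numeric", phase = "numeric",
  domain = "numeric", residualRMS = "numeric", fallback = "logical",
  spline = "ANY"
))

#' CorrectionState: background/bleaching correction of one scan
#'
#' @slot gamma named list (G, R) of \linkS4class{SixSineCurve} objects
#'   describing gamma(t), normalized so gamma(0) = 1
#' @slot gammaMean named numeric; the time average of gamma(t) that
#'   rescales the autocorrelation amplitudes
#' @slot corrected named list (G, R) of fully corrected traces
#'   I(t) = I'(t) gamma(t)
#' @slot t sample times (s)
#' @slot sampleTime bin width (s)
#' @slot clipFraction named numeric; fraction of samples clipped at zero
#'   during background subtraction
#' @slot flags character vector of warnings raised during correction
#' @exportClass CorrectionState
setClass("CorrectionState", representation(
  gamma = "list", gammaMean = "numeric", corrected = "list",
  t = "numeric", sampleTime = "numeric", clipFraction = "numeric",
  flags = "character"
))

#' CorrelationSet: correlation curves of one scan
#'
#' Auto- and cross-correlation on a quasi-logarithmic lag grid, with
#' per-lag uncertainties from segment splitting.
#'
#' @slot tau lag times (s), strictly increasing
#' @slot G named list (G, R, x) of correlation values
#' @slot err named list of per-lag SDs of the mean over trace segments
#' @slot meta list: binWidth, gammaMean, nSegments, scanId
#' @exportClass CorrelationSet
setClass("CorrelationSet", representation(
  tau = "numeric", G = "list", err = "list", meta = "list"
))

setValidity("CorrelationSet", function(object) {
  if (is.unsorted(object@tau, strictly = TRUE))
    return("tau must be strictly increasing")
  for (g in object@G) {
    if (length(g) != length(object@tau)) return("curve length must match tau")
    if (any(!is.finite(g))) return("G values must be finite")
  }
  for (e in object@err)
    if (any(e[is.finite(e)] < 0)) return("err must be >= 0")
  TRUE
})

#' FitResult: diffusion-model fit of a correlation curve
#'
#' @slot model "circular" or "elongated"
#' @slot par named estimates: N (occupancy), tauD (s), and S for the
#'   elongated model
#' @slot se standard errors of the parameters
#' @slot G0 fitted amplitude 1/N
#' @slot cov parameter covariance matrix
#' @slot redChiSq reduced chi-square (weighted fits)
#' @slot converged logical
#' @slot flags character ("fit_failed", "S_at_bound", ...)
#' @exportClass FitResult
setClass("FitResult", representation(
  model = "character", par = "numeric", se = "numeric", G0 = "numeric",
  cov = "matrix", redChiSq = "numeric", converged = "logical",
  flags = "character"
))

#' OpticsCalibration: observation areas of the dual-color experiment
#'
#' Calibrated waists and observation areas, the effective dual-color area
#' A_eff = pi omega_eff^2 with omega_eff^2 = (omega_G^2 + omega_R^2)/2,
#' and the geometric factor A = A_G A_R / A_eff^2 entering the binding
#' isotherm amplitude.
#'
#' @slot fwhmMeasured named (G, R) measured FWHM (nm); NA when the
#'   calibration was supplied as waists directly
#' @slot beadDiameter calibration bead diameter (nm)
#' @slot fwhm bead-size-corrected FWHM (nm)
#' @slot omega0 named 1/e^2 waists (nm)
#' @slot areas named observation areas (um^2): AG, AR, Aeff
#' @slot ratios named: AeffAG = A_eff/A_G, AeffAR = A_eff/A_R
#' @slot aFactor the dimensionless factor A in (0, 1]
#' @exportClass OpticsCalibration
setClass("OpticsCalibration", representation(
  fwhmMeasured = "numeric", beadDiameter = "numeric", fwhm = "numeric",
  omega0 = "numeric", areas = "numeric", ratios = "numeric",
  aFactor = "numeric"
))

setValidity("OpticsCalibration", function(object) {
  if (object@aFactor <= 0 || object@aFactor > 1 + 1e-12)
    return("aFactor must lie in (0, 1]")
  if (any(object@omega0 <= 0)) return("waists must be > 0")
  TRUE
})

#' BindingCurve: Gamma(C_L) with uncertainties
#'
#' @slot cL ligand concentrations (nM)
#' @slot gamma mean Gamma per concentration
#' @slot sem SEM across scans
#' @slot nScans scans contributing per point (>= 3 per point)
#' @slot aFactor geometric factor A from the optics calibration
#' @slot details per-scan data.frame (cL, gamma, tauDG, tauDR, kept,
#'   reason)
#' @exportClass BindingCurve
setClass("BindingCurve", representation(
  cL = "numeric", gamma = "numeric", sem = "numeric", nScans = "integer",
  aFactor = "numeric", details = "data.frame"
))

setValidity("BindingCurve", function(object) {
  n <- length(object@cL)
  if (length(object@gamma) != n || length(object@sem) != n ||
      length(object@nScans) != n)
    return("cL, gamma, sem and nScans must align")
  if (any(object@nScans < 3L))
    return("at least three scans are required per concentration")
  if (any(object@sem < 0)) return("sem must be >= 0")
  TRUE
})

#' IsothermFit: K_D and beta from the scaled binding isotherm
#'
#' Fit of Gamma(C_L) = A beta / (1 + K_D/C_L) with A fixed from the optics
#' calibration.
#'
#' @slot kD equilibrium dissociation coefficient (nM)
#' @slot kDse its standard error
#' @slot beta amplitude parameter in (0, 1]
#' @slot betaSE its standard error
#' @slot aFactor the fixed geometric factor A
#' @slot cov parameter covariance
#' @slot flags character ("ill_conditioned", "beta_gt_0.6", ...)
#' @exportClass IsothermFit
setClass("IsothermFit", representation(
  kD = "numeric", kDse = "numeric", beta = "numeric", betaSE = "numeric",
  aFactor = "numeric", cov = "matrix", flags = "character"
))

#' HeterodimerResult: bound fractions of a two-receptor heterodimer
#'
#' Area-weighted amplitude ratios F' and their maturation-corrected bound
#' fractions F for both receptor species.
#'
#' @slot fRprime,fGprime area-weighted ratios
#'   (A_eff/A_G) G_x(0)/G_G(0) and (A_eff/A_R) G_x(0)/G_R(0)
#' @slot fR,fG maturation-corrected bound fractions
#' @slot etaG,etaR maturation yields used for the correction
#' @exportClass HeterodimerResult
setClass("HeterodimerResult", representation(
  fRprime = "numeric", fGprime = "numeric", fR = "numeric", fG = "numeric",
  etaG = "numeric", etaR = "numeric"
))

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' @rdname accessors
#' @aliases photonEvents,PhotonStream-method
setMethod("photonEvents", "PhotonStream", function(x, ...) x@events)

#' @rdname accessors
#' @param channel channel name ("G" or "R"); NULL returns all channels
setMethod("kymoCounts", "Kymograph", function(x, channel = NULL) {
  if (is.null(channel)) x@counts else x@counts[[channel]]
})

#' @rdname accessors
setMethod("kymoRawCounts", "Kymograph", function(x, channel = NULL) {
  if (is.null(channel)) x@raw else x@raw[[channel]]
})

#' @rdname accessors
setMethod("lineTime", "Kymograph", function(x) x@lineTime)

#' @rdname accessors
setMethod("nLines", "Kymograph", function(x) nrow(x@counts[[1L]]))

#' @rdname accessors
setMethod("nPixels", "Kymograph", function(x) ncol(x@counts[[1L]]))

#' @rdname accessors
setMethod("zPixelEdges", "Kymograph", function(x) x@mapping@pixelEdges)

#' @rdname accessors
setMethod("zPixelEdges", "ZMapping", function(x) x@pixelEdges)

#' @rdname accessors
setMethod("dwellWeights", "Kymograph", function(x) x@mapping@dwellWeight)

#' @rdname accessors
setMethod("dwellWeights", "ZMapping", function(x) x@dwellWeight)

#' @rdname accessors
setMethod("ridgePositions", "MembraneTrace", function(x) x@positions)

#' @rdname accessors
setMethod("traceTimes", "IntensityTraces", function(x) x@t)

#' @rdname accessors
setMethod("rawIntensity", "IntensityTraces", function(x, channel = NULL) {
  if (is.null(channel)) x@raw else x@raw[[channel]]
})

#' @rdname accessors
setMethod("backgroundIntensity", "IntensityTraces", function(x, channel = NULL) {
  if (is.null(channel)) x@bg else x@bg[[channel]]
})

#' @rdname accessors
setMethod("correctedIntensity", "CorrectionState", function(x, channel = NULL) {
  if (is.null(channel)) x@corrected else x@corrected[[channel]]
})

#' @rdname accessors
setMethod("gammaMean", "CorrectionState", function(x, channel = NULL) {
  if (is.null(channel)) x@gammaMean else x@gammaMean[[channel]]
})

#' @rdname accessors
setMethod("lagTimes", "CorrelationSet", function(x) x@tau)

#' @rdname accessors
setMethod("corrValues", "CorrelationSet", function(x, channel = NULL) {
  if (is.null(channel)) x@G else x@G[[channel]]
})

#' @rdname accessors
setMethod("corrErrors", "CorrelationSet", function(x, channel = NULL) {
  if (is.null(channel)) x@err else x@err[[channel]]
})

#' @rdname accessors
setMethod("fitParameters", "FitResult", function(x) x@par)

#' @rdname accessors
setMethod("qcPass", "QCReport", function(x) x@pass)

#' @rdname accessors
setMethod("qcFlags", "QCReport", function(x) x@flags)

#' @rdname accessors
setMethod("aFactor", "OpticsCalibration", function(x) x@aFactor)

#' @rdname accessors
setMethod("omega0", "OpticsCalibration", function(x) x@omega0)

#' @rdname accessors
setMethod("obsAreas", "OpticsCalibration", function(x) x@areas)

#' @rdname accessors
setMethod("kD", "IsothermFit", function(x) x@kD)

#' @rdname accessors
setMethod("bindingBeta", "IsothermFit", function(x) x@beta)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "OpticsConfig", function(object) {
  cat("OpticsConfig\n")
  cat(sprintf("  waists (1/e^2): G %.0f nm, R %.0f nm; z0: G %.0f nm, R %.0f nm\n",
              object@omegaG, object@omegaR, object@z0G, object@z0R))
  cat(sprintf("  axial scan: %.1f kHz (period %.2f us), amplitude %.2f um x %.0f%% drive\n",
              object@tagFrequency, 1e3 / object@tagFrequency,
              object@tagAmplitude, 100 * object@driveFraction))
  cat(sprintf("  PIE gate boundary: %.1f ns\n", object@pieWindow))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  patch %.1f x %.1f um, %.0f s at %.3g ms steps, seed %d\n",
              object@boxSide, object@boxSide, object@duration,
              1e3 * object@timeStep, object@seed))
  d <- object@densities[object@densities > 0]
  cat("  densities (um^-2):",
      if (length(d)) paste(sprintf("%s=%.3g", names(d), d), collapse = ", ")
      else "none", "\n")
  cat(sprintf("  D = %s um^2/s, eta G/R = %.2f/%.2f\n",
              paste(signif(object@dCoef, 3), collapse = "/"),
              object@etaG, object@etaR))
})

setMethod("show", "PhotonStream", function(object) {
  ev <- object@events
  cat(sprintf("PhotonStream: %d photons", nrow(ev)))
  if (nrow(ev))
    cat(sprintf(" over %.3g s", max(ev$macro_time_ns) * 1e-9))
  cat("\n")
  gate <- object@optics@pieWindow
  if (nrow(ev)) {
    ng <- sum(ev$micro_time_ns < gate)
    cat(sprintf("  green gate [0, %.1f) ns: %d; red gate [%.1f, 25) ns: %d\n",
                gate, ng, gate, nrow(ev) - ng))
  }
})

setMethod("show", "Kymograph", function(object) {
  cat(sprintf("Kymograph: %d lines x %d z-pixels, line time %.3g s, channels %s\n",
              nLines(object), nPixels(object), object@lineTime,
              paste(names(object@counts), collapse = ", ")))
})

setMethod("show", "CorrelationSet", function(object) {
  cat(sprintf("CorrelationSet: %d lags, %.2g s - %.2g s\n",
              length(object@tau), min(object@tau), max(object@tau)))
  for (ch in names(object@G))
    cat(sprintf("  G_%s(0-) = %.4g\n", ch, object@G[[ch]][1L]))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (%s model)%s\n", object@model,
              if (object@converged) "" else " [not converged]"))
  p <- object@par
  for (nm in names(p))
    cat(sprintf("  %s = %.4g +- %.2g\n", nm, p[[nm]],
                if (nm %in% names(object@se)) object@se[[nm]] else NA))
})

setMethod("show", "OpticsCalibration", function(object) {
  cat("OpticsCalibration\n")
  cat(sprintf("  omega0: G %.1f nm, R %.1f nm\n",
              object@omega0[["G"]], object@omega0[["R"]]))
  cat(sprintf("  areas: A_G %.4f, A_R %.4f, A_eff %.4f um^2\n",
              object@areas[["AG"]], object@areas[["AR"]], object@areas[["Aeff"]]))
  cat(sprintf("  A_eff/A_G = %.3f, A_eff/A_R = %.3f, A = %.4f\n",
              object@ratios[["AeffAG"]], object@ratios[["AeffAR"]],
              object@aFactor))
})

setMethod("show", "BindingCurve", function(object) {
  cat(sprintf("BindingCurve: %d concentrations, %d scans total\n",
              length(object@cL), sum(object@nScans)))
  print(data.frame(cL_nM = object@cL, Gamma = signif(object@gamma, 4),
                   SEM = signif(object@sem, 3), n = object@nScans),
        row.names = FALSE)
})

setMethod("show", "IsothermFit", function(object) {
  cat(sprintf("IsothermFit: K_D = %.3g +- %.2g nM, beta = %.3g +- %.2g (A = %.3f)\n",
              object@kD, object@kDse, object@beta, object@betaSE,
              object@aFactor))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: %s\n", if (object@pass) "PASS" else "FAIL"))
  for (nm in names(object@flags))
    cat(sprintf("  %-20s %-5s (%.3g)\n", nm, object@flags[[nm]],
                object@evidence[[nm]]))
})

setMethod("show", "HeterodimerResult", function(object) {
  cat(sprintf("HeterodimerResult: F_R' = %.3f -> F_R = %.3f (eta_G = %.2f)\n",
              object@fRprime, object@fR, object@etaG))
  cat(sprintf("                   F_G' = %.3f -> F_G = %.3f (eta_R = %.2f)\n",
              object@fGprime, object@fG, object@etaR))
})
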