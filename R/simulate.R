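#' @include config.R
NULL

#' Simulate Brownian membrane trajectories
#'
#' Draws particle numbers per species from a Poisson law with mean
#' density x patch area, assigns fluorophore label states with the
#' maturation yields, and propagates 2D Brownian motion with per-axis step
#' variance 2 D dt on the periodic patch. Positions are sampled on the
#' configured trajectory time grid and stored in re-materializable chunks
#' (see \linkS4class{Trajectories}).
#'
#' @param cfg a \linkS4class{SimConfig}
#' @param chunkSize steps per stored chunk
#' @return a \linkS4class{Trajectories} object
#' @seealso \code{\link{simulatePhotons}}, \code{\link{trajectoryChunk}}
#' @export
simulateTrajectories <- function(cfg, chunkSize = 10000L) {
  validObject(cfg)
  set.seed(cfg@seed)
  area <- cfg@boxSide^2
  dens <- cfg@densities
  specs <- names(dens)[dens > 0]

  rows <- list()
  for (sp in specs) {
    n <- stats::rpois(1L, dens[[sp]] * area)
    if (n == 0L) next
    fluorG <- switch(sp,
      G = , RL = , rL = stats::runif(n) < cfg@etaG,
      rep(FALSE, n))
    fluorR <- switch(sp,
      R = , RL = stats::runif(n) < cfg@etaR,
      rep(FALSE, n))
    rows[[sp]] <- data.frame(species = rep(sp, n), fluorG = fluorG,
                             fluorR = fluorR, stringsAsFactors = FALSE)
  }
  particles <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), fluorG = logical(), fluorR = logical())
  rownames(particles) <- NULL
  nP <- nrow(particles)

  dC <- cfg@dCoef
  dPart <- if (is.null(names(dC))) rep(dC[[1L]], nP) else {
    miss <- setdiff(unique(particles$species), names(dC))
    if (length(miss)) stop("dCoef missing species: ", paste(miss, collapse = ", "))
    unname(dC[particles$species])
  }

  nSteps <- max(1L, as.integer(round(cfg@duration / cfg@timeStep)))
  chunkSize <- as.integer(chunkSize)
  nChunks <- as.integer(ceiling(nSteps / chunkSize))
  start <- matrix(stats::runif(2L * nP, 0, cfg@boxSide), ncol = 2L)
  chunkSeeds <- vapply(seq_len(nChunks), function(k)
    .childSeed(cfg@seed, 1000L + k), integer(1L))

  ## chunk boundary positions are drawn directly (the sum of len steps is
  ## Gaussian); within-chunk paths are reconstructed later as Brownian
  ## bridges between boundaries, so the expensive per-step draws happen
  ## only when a chunk is actually materialized
  boundaries <- array(NA_real_, dim = c(nChunks + 1L, max(nP, 1L), 2L))
  if (nP) {
    boundaries[1L, seq_len(nP), ] <- start
    sdStep <- sqrt(2 * dPart * cfg@timeStep)
    cur <- start
    for (k in seq_len(nChunks)) {
      len <- min(chunkSize, nSteps - (k - 1L) * chunkSize)
      set.seed(.childSeed(cfg@seed, 5000L + k))
      cur <- cur + cbind(stats::rnorm(nP, sd = sqrt(len) * sdStep),
                         stats::rnorm(nP, sd = sqrt(len) * sdStep))
      boundaries[k + 1L, seq_len(nP), ] <- cur
    }
  }

  new("Trajectories", particles = particles, boundaries = boundaries,
      chunkSeeds = chunkSeeds, chunkSize = chunkSize,
      nSteps = nSteps, timeStep = cfg@timeStep, boxSide = cfg@boxSide,
      dPart = dPart, seed = cfg@seed)
}

## fast column-wise cumulative sums (single C-level cumsum pass)
.colCumsums <- function(m) {
  n <- nrow(m); p <- ncol(m)
  v <- cumsum(m)
  out <- matrix(v, n, p)
  if (p > 1L)
    out[, -1L] <- out[, -1L] - matrix(rep(v[n * seq_len(p - 1L)], each = n),
                                      n, p - 1L)
  out
}

#' Materialize one trajectory chunk
#'
#' Reconstructs the within-chunk path as a Brownian bridge between the
#' stored chunk boundary positions: raw increments are re-drawn from the
#' chunk seed and linearly corrected so the path ends exactly at the next
#' boundary. Repeated materialization of the same chunk is bit-identical,
#' and the construction is distributionally exact Brownian motion.
#'
#' @param traj a \linkS4class{Trajectories} object
#' @param k chunk index (1-based)
#' @return list with matrices \code{x}, \code{y} (steps x particles, um)
#'   and \code{steps}, the global step indices covered
#' @export
trajectoryChunk <- function(traj, k) {
  nP <- nrow(traj@particles)
  len <- min(traj@chunkSize, traj@nSteps - (k - 1L) * traj@chunkSize)
  steps <- (k - 1L) * traj@chunkSize + seq_len(len)
  if (nP == 0L)
    return(list(x = matrix(0, len, 0L), y = matrix(0, len, 0L), steps = steps))
  sdStep <- sqrt(2 * traj@dPart * traj@timeStep)
  set.seed(traj@chunkSeeds[k])
  dx <- matrix(stats::rnorm(len * nP, sd = rep(sdStep, each = len)), len, nP)
  dy <- matrix(stats::rnorm(len * nP, sd = rep(sdStep, each = len)), len, nP)
  x0 <- traj@boundaries[k, seq_len(nP), 1L]
  y0 <- traj@boundaries[k, seq_len(nP), 2L]
  dX <- traj@boundaries[k + 1L, seq_len(nP), 1L] - x0
  dY <- traj@boundaries[k + 1L, seq_len(nP), 2L] - y0
  x <- .colCumsums(dx)
  y <- .colCumsums(dy)
  frac <- seq_len(len) / len
  # bridge correction: end exactly at the next boundary
  x <- x + outer(frac, dX - x[len, ])
  y <- y + outer(frac, dY - y[len, ])
  list(x = x + rep(x0, each = len), y = y + rep(y0, each = len),
       steps = steps)
}

## number of stored chunks
.nChunks <- function(traj) length(traj@chunkSeeds)

## minimum-image displacement from the focus at the patch center
.minImage <- function(p, box) {
  d <- (p - box / 2) %% box
  d - box * (d >= box / 2)
}

#' Simulate a photon stream from membrane trajectories
#'
#' Sweeps a 3D Gaussian observation volume sinusoidally along z,
#' z(t) = a sin(2 pi f t), across the membrane plane and emits photons
#' from every live fluorophore with Poisson statistics. The mean detected
#' photons per oscillation cycle per fluorophore are
#' brightness x exp(-2 r^2/omega^2) x (axial Gaussian transit dose),
#' where the transit dose is the numerically integrated axial profile
#' exp(-2 (z(t) - z_mem)^2 / z0^2) over one cycle. Uncorrelated background
#' is added as a homogeneous Poisson process, each fluorophore bleaches
#' memorylessly once its accumulated excitation exposure exceeds an
#' exponentially distributed threshold (mean 1/bleachCrossSection), and
#' channel identity is encoded in the micro time via the PIE gates (green
#' [0, pieWindow), red [pieWindow, 25) ns).
#'
#' Identical configuration and seed reproduce a bit-identical stream.
#'
#' @param traj \linkS4class{Trajectories} from \code{\link{simulateTrajectories}}
#' @param optics an \linkS4class{OpticsConfig}
#' @param cfg the \linkS4class{SimConfig} used for the trajectories
#' @return a \linkS4class{PhotonStream}
#' @export
simulatePhotons <- function(traj, optics, cfg) {
  validObject(optics); validObject(cfg)
  if (abs(traj@timeStep - cfg@timeStep) > 1e-15 || traj@boxSide != cfg@boxSide)
    stop("trajectories and config disagree on time base or patch size")
  set.seed(.childSeed(cfg@seed, 2L))

  a <- sweepAmplitude(optics)            # um
  fHz <- optics@tagFrequency * 1e3
  periodNs <- 1e9 / fHz
  periodUs <- 1e3 / optics@tagFrequency
  cyclesPerStep <- cfg@timeStep * fHz
  nSteps <- traj@nSteps
  totalCycles <- nSteps * cyclesPerStep

  ## axial profile on a phase grid, per channel and membrane z
  ng <- 1024L
  phi <- (seq_len(ng) - 0.5) / ng
  zg <- a * sin(2 * pi * phi)
  z0 <- c(G = optics@z0G, R = optics@z0R) * 1e-3   # um
  om <- c(G = optics@omegaG, R = optics@omegaR) * 1e-3

  stepT <- (seq_len(nSteps) - 0.5) * cfg@timeStep
  zmem <- if (cfg@driftAmplitude > 0)
    cfg@driftAmplitude * sin(2 * pi * stepT / cfg@driftPeriod) else
    rep(0, nSteps)
  zq <- round(zmem, 2L)                  # 10 nm quantization for profiles
  zqLevels <- sort(unique(zq))
  zqIdx <- match(zq, zqLevels)

  profiles <- lapply(c(G = "G", R = "R"), function(ch)
    lapply(zqLevels, function(u) exp(-2 * (zg - u)^2 / z0[[ch]]^2)))
  ## mean photons per cycle at unit lateral weight and unit brightness (us)
  doseCycle <- lapply(c(G = "G", R = "R"), function(ch)
    vapply(profiles[[ch]], function(p) periodUs * mean(p), 0))

  prt <- traj@particles
  nP <- nrow(prt)
  chans <- list(
    G = list(cols = which(prt$fluorG), b = cfg@brightness[["G"]],
             sigma = cfg@bleachCrossSection[["G"]]),
    R = list(cols = which(prt$fluorR), b = cfg@brightness[["R"]],
             sigma = cfg@bleachCrossSection[["R"]]))

  ## bleaching thresholds in center-equivalent exposure (us)
  thr <- lapply(chans, function(ch) {
    n <- length(ch$cols)
    if (ch$sigma > 0) stats::rexp(n) / ch$sigma else rep(Inf, n)
  })
  cumDose <- lapply(chans, function(ch) rep(0, length(ch$cols)))
  alive <- lapply(chans, function(ch) rep(TRUE, length(ch$cols)))

  memSteps <- list(G = list(), R = list())
  nChunks <- .nChunks(traj)
  for (k in seq_len(nChunks)) {
    pos <- trajectoryChunk(traj, k)
    len <- length(pos$steps)
    dx <- .minImage(pos$x, cfg@boxSide)
    dy <- .minImage(pos$y, cfg@boxSide) / cfg@lateralAspect
    r2 <- dx * dx + dy * dy
    gIdx <- zqIdx[pos$steps]
    for (chn in c("G", "R")) {
      ch <- chans[[chn]]
      act <- which(alive[[chn]])
      if (!length(act)) next
      cols <- ch$cols[act]
      ## sparse Gaussian weights: beyond 5 omega^2 the weight is < 5e-5
      ## and contributes neither photons nor bleaching dose
      sub <- r2[, cols, drop = FALSE]
      W <- array(0, dim(sub))
      near <- which(sub < 5 * om[[chn]]^2)
      W[near] <- exp(-2 * sub[near] / om[[chn]]^2)
      doseVec <- doseCycle[[chn]][gIdx] * cyclesPerStep
      if (ch$sigma > 0) {
        thrAct <- thr[[chn]][act]
        colDose <- as.numeric(doseVec %*% W)
        cand <- which(cumDose[[chn]][act] + colDose >= thrAct)
        if (length(cand)) {
          expo <- W[, cand, drop = FALSE] * doseVec
          cum <- .colCumsums(expo)
          cum <- cum + rep(cumDose[[chn]][act][cand], each = len)
          below <- colSums(cum < rep(thrAct[cand], each = len))
          for (jj in seq_along(cand)) {
            fi <- below[jj] + 1L          # bleaches during step fi
            if (fi <= len) {
              if (fi < len) W[(fi + 1L):len, cand[jj]] <- 0
              alive[[chn]][act[cand[jj]]] <- FALSE
            }
          }
        }
        cumDose[[chn]][act] <- cumDose[[chn]][act] +
          as.numeric(doseVec %*% W)
      }
      lam <- ch$b * doseVec * rowSums(W)
      nPh <- stats::rpois(len, lam)
      if (any(nPh > 0))
        memSteps[[chn]][[k]] <- rep(pos$steps, nPh)
    }
  }

  events <- list()
  for (chn in c("G", "R")) {
    mem <- if (length(memSteps[[chn]])) unlist(memSteps[[chn]], use.names = FALSE)
           else integer()
    nBgTot <- stats::rpois(1L, cfg@backgroundRate[[chn]] * 1e3 * cfg@duration)
    bg <- if (nBgTot > 0) sample.int(nSteps, nBgTot, replace = TRUE) else integer()

    nM <- length(mem); nB <- length(bg)
    if (nM + nB == 0L) next
    stepsAll <- c(mem, bg)
    cycPos <- (stepsAll - 1L + stats::runif(nM + nB)) * cyclesPerStep
    cyc <- floor(pmin(cycPos, totalCycles - 1e-9))

    phase <- numeric(nM + nB)
    if (nM) {
      gOfPhoton <- zqIdx[mem]
      for (u in unique(gOfPhoton)) {
        sel <- which(gOfPhoton == u)
        gi <- sample.int(ng, length(sel), replace = TRUE,
                         prob = profiles[[chn]][[u]])
        phase[sel] <- (gi - 1L + stats::runif(length(sel))) / ng
      }
    }
    if (nB) phase[nM + seq_len(nB)] <- stats::runif(nB)

    pie <- optics@pieWindow
    micro <- if (chn == "G") stats::runif(nM + nB, 0, pie)
             else pie + stats::runif(nM + nB, 0, 25 - pie)
    if (chn == "G" && cfg@crosstalk > 0) {
      leak <- stats::runif(nM + nB) < cfg@crosstalk
      micro[leak] <- pie + stats::runif(sum(leak), 0, 25 - pie)
    }
    events[[chn]] <- data.frame(
      macro_time_ns = (cyc + phase) * periodNs,
      micro_time_ns = micro, tag_cycle = cyc, tag_phase = phase)
  }

  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(macro_time_ns = numeric(), micro_time_ns = numeric(),
               tag_cycle = numeric(), tag_phase = numeric())
  ev <- ev[order(ev$macro_time_ns), , drop = FALSE]
  rownames(ev) <- NULL

  area <- cfg@boxSide^2
  categories <- c(
    greenOnly = sum(prt$fluorG & !prt$fluorR),
    redOnly   = sum(prt$fluorR & !prt$fluorG),
    dual      = sum(prt$fluorG & prt$fluorR))
  info <- list(
    seed = cfg@seed, duration = cfg@duration,
    nParticles = nP, categories = categories,
    densities = categories / area,
    bleached = vapply(alive, function(x) sum(!x), 0L),
    boxSide = cfg@boxSide, timeStep = cfg@timeStep)

  new("PhotonStream", events = ev, optics = optics, info = info)
}

#' Bound receptor fraction of the binding isotherm
#'
#' F(C_L) = 1 / (1 + K_D / C_L): the fraction of binding-competent
#' receptors occupied by ligand at free ligand concentration C_L.
#'
#' @param kD dissociation coefficient (nM), > 0
#' @param cL ligand concentration(s) (nM), >= 0
#' @return bound fraction(s) in [0, 1); F(kD) = 0.5 exactly
#' @examples
#' boundFraction(0.08, 0.4)   # 1/1.2 = 0.8333
#' @export
boundFraction <- function(kD, cL) {
  if (any(kD <= 0)) stop("kD must be > 0")
  ifelse(cL > 0, 1 / (1 + kD / cL), 0)
}

#' Simulate a ligand concentration series
#'
#' For every concentration in \code{cLSeries}, the labeled receptor pool
#' (species \code{R} + \code{RL}) and the unlabeled pool (\code{rL} +
#' \code{dark}) are split into ligand-bound and free sub-populations with
#' bound fraction 1/(1 + K_D/C_L); total receptor density is conserved
#' across the series. One photon stream is simulated per concentration
#' with a seed derived from the configuration seed.
#'
#' @param cfg \linkS4class{SimConfig} with \code{kD} set and a non-empty
#'   \code{cLSeries}
#' @param optics an \linkS4class{OpticsConfig}
#' @return list with one element per concentration: \code{cL},
#'   \code{boundFraction}, \code{stream} (a \linkS4class{PhotonStream})
#'   and \code{truth}, the realized per-category fluorophore densities
#' @export
makeBindingSeries <- function(cfg, optics) {
  validObject(cfg)
  if (is.na(cfg@kD) || cfg@kD <= 0) stop("cfg@kD must be a positive K_D (nM)")
  if (!length(cfg@cLSeries)) stop("cfg@cLSeries must be non-empty")
  dens <- cfg@densities
  labeled <- dens[["R"]] + dens[["RL"]]
  unlabeled <- dens[["rL"]] + dens[["dark"]]

  lapply(seq_along(cfg@cLSeries), function(i) {
    cL <- cfg@cLSeries[i]
    fb <- boundFraction(cfg@kD, cL)
    cfgI <- cfg
    cfgI@densities <- c(R = (1 - fb) * labeled, G = dens[["G"]],
                        RL = fb * labeled, rL = fb * unlabeled,
                        dark = (1 - fb) * unlabeled)
    cfgI@seed <- .childSeed(cfg@seed, 100L + i)
    traj <- simulateTrajectories(cfgI)
    stream <- simulatePhotons(traj, optics, cfgI)
    list(cL = cL, boundFraction = fb, stream = stream,
         truth = stream@info$densities)
  })
}
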