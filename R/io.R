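#' @include AllClasses.R
NULL

## "# key=value" header helpers ------------------------------------------------

.writeHeader <- function(con, meta) {
  for (nm in names(meta)) {
    v <- meta[[nm]]
    writeLines(sprintf("# %s=%s", nm, paste(format(v, digits = 17),
                                            collapse = ",")), con)
  }
}

.readHeader <- function(path) {
  lines <- character()
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    l <- readLines(con, n = 1L)
    if (!length(l) || !startsWith(l, "#")) break
    lines <- c(lines, l)
  }
  meta <- list()
  for (l in lines) {
    kv <- sub("^#\\s*", "", l)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) next
    key <- substr(kv, 1L, eq - 1L)
    val <- substr(kv, eq + 1L, nchar(kv))
    num <- suppressWarnings(as.numeric(strsplit(val, ",", fixed = TRUE)[[1L]]))
    meta[[key]] <- if (anyNA(num)) val else num
  }
  list(meta = meta, skip = length(lines))
}

#' Read and write photon streams
#'
#' Photon event tables are serialized either as delimited text (tab
#' separated, with \code{# key=value} header lines carrying the optics
#' configuration and seed) or as a binary container (an R serialization
#' of the same content, bit-exact on round trip). The text body has the
#' columns macro_time_ns, micro_time_ns, tag_cycle, tag_phase.
#'
#' @param stream a \linkS4class{PhotonStream}
#' @param path file path
#' @param format "text" or "binary"
#' @return \code{readPhotonStream} returns a \linkS4class{PhotonStream};
#'   \code{writePhotonStream} returns \code{path} invisibly
#' @export
writePhotonStream <- function(stream, path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (format == "binary") {
    o <- stream@optics
    saveRDS(list(kind = "PhotonStream", events = stream@events,
                 optics = lapply(slotNames(o), function(s) slot(o, s)),
                 opticsSlots = slotNames(o), info = stream@info),
            path)
    return(invisible(path))
  }
  o <- stream@optics
  meta <- stats::setNames(lapply(slotNames(o), function(s) slot(o, s)),
                          paste0("optics.", slotNames(o)))
  meta$seed <- stream@info$seed
  meta$duration <- stream@info$duration
  con <- file(path, "w")
  .writeHeader(con, meta)
  close(con)
  data.table::fwrite(stream@events, path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname writePhotonStream
#' @export
readPhotonStream <- function(path) {
  bin <- tryCatch({
    x <- readRDS(path)
    if (!identical(x$kind, "PhotonStream")) stop("not a stream")
    x
  }, error = function(e) NULL)
  if (!is.null(bin)) {
    o <- do.call(new, c(list("OpticsConfig"),
                        stats::setNames(bin$optics, bin$opticsSlots)))
    return(new("PhotonStream", events = bin$events, optics = o,
               info = bin$info))
  }
  hd <- .readHeader(path)
  ev <- tryCatch(
    as.data.frame(data.table::fread(path, skip = hd$skip, sep = "\t")),
    error = function(e) stop("malformed photon table in ", path, ": ",
                             conditionMessage(e)))
  need <- c("macro_time_ns", "micro_time_ns", "tag_cycle", "tag_phase")
  if (!all(need %in% names(ev)))
    stop("parse error in ", path, ": missing columns ",
         paste(setdiff(need, names(ev)), collapse = ", "))
  om <- hd$meta
  getO <- function(nm, def) {
    v <- om[[paste0("optics.", nm)]]
    if (is.null(v)) def else v
  }
  o <- opticsConfig(
    omegaG = getO("omegaG", 207), omegaR = getO("omegaR", 251),
    z0G = getO("z0G", 1035), z0R = getO("z0R", 1255),
    tagFrequency = getO("tagFrequency", 147),
    tagAmplitude = getO("tagAmplitude", 5.3 / 1.5),
    driveFraction = getO("driveFraction", 0.75),
    pieWindow = getO("pieWindow", 12.5))
  info <- list(seed = om$seed, duration = om$duration)
  new("PhotonStream", events = ev[order(ev$macro_time_ns), , drop = FALSE],
      optics = o, info = info)
}

#' Read and write kymographs
#'
#' A kymograph is stored as one tab-separated count matrix per channel
#' (\code{<base>_<channel>.tsv}, raw counts) plus a sidecar metadata file
#' (\code{<base>_meta.txt}) carrying the line time, z pixel edges and
#' dwell weights, from which the rescaled counts are reconstructed.
#'
#' @param kymo a \linkS4class{Kymograph}
#' @param base base path (without extension)
#' @return \code{readKymograph} returns a \linkS4class{Kymograph};
#'   \code{writeKymograph} returns \code{base} invisibly
#' @export
writeKymograph <- function(kymo, base) {
  con <- file(paste0(base, "_meta.txt"), "w")
  .writeHeader(con, list(lineTime = kymo@lineTime,
                         pixelEdges = kymo@mapping@pixelEdges,
                         dwellWeight = kymo@mapping@dwellWeight,
                         amplitude = kymo@mapping@amplitude,
                         channels = paste(names(kymo@raw), collapse = ";")))
  close(con)
  for (ch in names(kymo@raw))
    data.table::fwrite(as.data.frame(kymo@raw[[ch]]),
                       paste0(base, "_", ch, ".tsv"), sep = "\t")
  invisible(base)
}

#' @rdname writeKymograph
#' @export
readKymograph <- function(base) {
  hd <- .readHeader(paste0(base, "_meta.txt"))$meta
  chans <- strsplit(hd$channels, ";", fixed = TRUE)[[1L]]
  mapping <- new("ZMapping", amplitude = hd$amplitude,
                 pixelEdges = hd$pixelEdges, dwellWeight = hd$dwellWeight,
                 calibration = NULL)
  raw <- counts <- list()
  for (ch in chans) {
    m <- as.matrix(data.table::fread(paste0(base, "_", ch, ".tsv")))
    dimnames(m) <- NULL
    raw[[ch]] <- m
    counts[[ch]] <- sweep(m, 2L, mapping@dwellWeight, "/")
  }
  new("Kymograph", counts = counts, raw = raw, lineTime = hd$lineTime,
      mapping = mapping,
      empty = vapply(raw, function(m) sum(m) == 0, TRUE))
}

#' Read and write intensity traces
#'
#' Delimited table with columns t, I_G_raw, I_R_raw, I_G_bg, I_R_bg.
#'
#' @param traces an \linkS4class{IntensityTraces}
#' @param path file path
#' @return \code{readIntensityTraces} returns an
#'   \linkS4class{IntensityTraces}
#' @export
writeIntensityTraces <- function(traces, path) {
  con <- file(path, "w")
  .writeHeader(con, list(sampleTime = traces@sampleTime))
  close(con)
  data.table::fwrite(
    data.frame(t = traces@t,
               I_G_raw = traces@raw[["G"]], I_R_raw = traces@raw[["R"]],
               I_G_bg = traces@bg[["G"]], I_R_bg = traces@bg[["R"]]),
    path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeIntensityTraces
#' @export
readIntensityTraces <- function(path) {
  hd <- .readHeader(path)
  d <- as.data.frame(data.table::fread(path, skip = hd$skip, sep = "\t"))
  new("IntensityTraces", t = d$t, sampleTime = hd$meta$sampleTime,
      raw = list(G = d$I_G_raw, R = d$I_R_raw),
      bg = list(G = d$I_G_bg, R = d$I_R_bg),
      qc = NULL, meta = list())
}

#' Read and write correlation sets
#'
#' Delimited table (tau, G_G, err_G, G_R, err_R, G_x, err_x) with a
#' metadata header.
#'
#' @param cs a \linkS4class{CorrelationSet}
#' @param path file path
#' @return \code{readCorrelationSet} returns a
#'   \linkS4class{CorrelationSet}
#' @export
writeCorrelationSet <- function(cs, path) {
  con <- file(path, "w")
  .writeHeader(con, list(binWidth = cs@meta$binWidth,
                         gammaMeanG = cs@meta$gammaMean[["G"]],
                         gammaMeanR = cs@meta$gammaMean[["R"]],
                         nSegments = cs@meta$nSegments))
  close(con)
  data.table::fwrite(
    data.frame(tau = cs@tau,
               G_G = cs@G$G, err_G = cs@err$G,
               G_R = cs@G$R, err_R = cs@err$R,
               G_x = cs@G$x, err_x = cs@err$x),
    path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeCorrelationSet
#' @export
readCorrelationSet <- function(path) {
  hd <- .readHeader(path)
  d <- as.data.frame(data.table::fread(path, skip = hd$skip, sep = "\t"))
  new("CorrelationSet", tau = d$tau,
      G = list(G = d$G_G, R = d$G_R, x = d$G_x),
      err = list(G = d$err_G, R = d$err_R, x = d$err_x),
      meta = list(binWidth = hd$meta$binWidth,
                  gammaMean = c(G = hd$meta$gammaMeanG,
                                R = hd$meta$gammaMeanR),
                  nSegments = hd$meta$nSegments))
}

#' Write a structured per-run report
#'
#' @param report a list (per-scan results, binding curve, isotherm fit)
#' @param path JSON file path
#' @export
writeRunReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
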