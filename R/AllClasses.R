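#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
NULL

FARRED_CLASSES <- c("rejected", "1-step", "2-step", "3plus")
GREEN_CLASSES  <- c("rejected", "1-step")

#' Class sets for the two imaging channels
#'
#' Far-red traces are binned into four classes (rejected, 1-step, 2-step and
#' 3-and-higher-step); green traces into two (rejected, 1-step), because the
#' bait is expected to be monomeric and any multi-event green trace is
#' discarded.
#'
#' @param channel `"green"` or `"farred"`.
#' @return Character vector of class labels in canonical order.
#' @examples
#' channelClasses("farred")
#' @export
channelClasses <- function(channel) {
  channel <- match.arg(channel, c("green", "farred"))
  if (channel == "green") GREEN_CLASSES else FARRED_CLASSES
}

## ---------------------------------------------------------------------------
## SimParams
## ---------------------------------------------------------------------------

#' @rdname simParams
#' @export
setClass("SimParams", representation(
  frames            = "integer",
  frameInterval     = "numeric",
  stepHeight        = "numeric",
  baseline          = "numeric",
  noiseSd           = "numeric",
  farredHalfTime    = "numeric",
  greenHalfTime     = "numeric",
  labelingProb      = "numeric",
  greenLabelProb    = "numeric",
  copyNumberDist    = "numeric",
  nBio              = "integer",
  nTech             = "integer",
  spotsPerField     = "integer",
  imageShape        = "integer",
  psfSd             = "numeric",
  registrationShift = "numeric"
))

setValidity("SimParams", function(object) {
  msg <- character(0)
  if (object@frames < 2L) msg <- c(msg, "frames must be >= 2")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@stepHeight <= 0) msg <- c(msg, "stepHeight must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@farredHalfTime <= 0 || object@greenHalfTime <= 0)
    msg <- c(msg, "bleach half-times must be > 0")
  if (object@labelingProb < 0 || object@labelingProb > 1)
    msg <- c(msg, "labelingProb must be in [0, 1]")
  if (object@greenLabelProb < 0 || object@greenLabelProb > 1)
    msg <- c(msg, "greenLabelProb must be in [0, 1]")
  d <- object@copyNumberDist
  if (length(d) < 1L || is.null(names(d)))
    msg <- c(msg, "copyNumberDist must be a named probability vector")
  else {
    if (any(d < 0)) msg <- c(msg, "copyNumberDist entries must be >= 0")
    if (abs(sum(d) - 1) > 1e-9) msg <- c(msg, "copyNumberDist must sum to 1")
    if (anyNA(suppressWarnings(as.integer(names(d)))) ||
        any(as.integer(names(d)) < 0))
      msg <- c(msg, "copyNumberDist names must be non-negative copy numbers")
  }
  if (object@nBio < 1L || object@nTech < 1L || object@spotsPerField < 1L)
    msg <- c(msg, "replicate structure counts must be >= 1")
  if (length(object@imageShape) != 2L)
    msg <- c(msg, "imageShape must have length 2")
  if (object@psfSd <= 0) msg <- c(msg, "psfSd must be > 0")
  if (length(object@registrationShift) != 2L)
    msg <- c(msg, "registrationShift must have length 2 (dx, dy)")
  if (length(msg)) msg else TRUE
})

#' Simulation parameters for synthetic SiMPull acquisitions
#'
#' Bundles every knob of the synthetic-data generator. Defaults mirror the
#' acquisition this package targets: 1000 frames per channel collected
#' continuously at 20 frames/sec (50 s), far-red bleach half-time of one
#' fifth of the imaging time (10 s), green one tenth (5 s), and ~40%
#' far-red (HaloTag dye) labeling efficiency. The default far-red copy-number
#' mixture places complexes at either one or four true phosphatase copies in
#' proportions chosen so that, after 40% binomial labeling, roughly 39% of
#' far-red-visible complexes carry two or more labeled fluorophores --- the
#' observed multimeric fraction the wild-type experiments report.
#'
#' @param frames Frames per channel (default 1000).
#' @param frameInterval Seconds per frame (default 0.05, i.e. 20 frames/sec).
#' @param stepHeight Unitary fluorophore intensity in camera counts.
#' @param baseline Background level of an extracted trace, in counts.
#' @param noiseSd Additive Gaussian noise per frame, in counts.
#' @param farredHalfTime,greenHalfTime Photobleaching half-times in seconds.
#' @param labelingProb Per-fluorophore far-red labeling probability.
#' @param greenLabelProb Probability the (single) green fluorophore is
#'   fluorescent; the green tag is genetically encoded, so near 1.
#' @param copyNumberDist Named probability vector over true far-red copy
#'   numbers (names are copy counts, e.g. `c("1" = .6, "3" = .4)`).
#' @param nBio,nTech Numbers of biological and technical replicates.
#' @param spotsPerField Complexes per technical replicate.
#' @param imageShape Image dimensions (rows, cols) for rendered fields.
#' @param psfSd Gaussian PSF standard deviation in pixels.
#' @param registrationShift Far-red channel offset (dx, dy) in pixels.
#' @return A validated `SimParams` object.
#' @examples
#' p <- simParams(nBio = 2L, nTech = 2L, spotsPerField = 50L)
#' p
#' @export
simParams <- function(frames = 1000L,
                      frameInterval = 0.05,
                      stepHeight = 50,
                      baseline = 200,
                      noiseSd = 10,
                      farredHalfTime = frames * frameInterval / 5,
                      greenHalfTime = frames * frameInterval / 10,
                      labelingProb = 0.4,
                      greenLabelProb = 1,
                      copyNumberDist = defaultCopyNumberDist(),
                      nBio = 10L,
                      nTech = 7L,
                      spotsPerField = 200L,
                      imageShape = c(64L, 64L),
                      psfSd = 1.2,
                      registrationShift = c(0, 0)) {
  new("SimParams",
      frames = as.integer(frames), frameInterval = frameInterval,
      stepHeight = stepHeight, baseline = baseline, noiseSd = noiseSd,
      farredHalfTime = farredHalfTime, greenHalfTime = greenHalfTime,
      labelingProb = labelingProb, greenLabelProb = greenLabelProb,
      copyNumberDist = copyNumberDist,
      nBio = as.integer(nBio), nTech = as.integer(nTech),
      spotsPerField = as.integer(spotsPerField),
      imageShape = as.integer(imageShape), psfSd = psfSd,
      registrationShift = as.numeric(registrationShift))
}

#' Default true copy-number mixture
#'
#' A two-component monomer/tetramer mixture over true far-red copies whose
#' mixing weight is solved (via the forward thinning model) so that the
#' post-labeling multimeric fraction among far-red-visible complexes equals
#' the wild-type observed value of 0.39 at 40% labeling efficiency.
#'
#' @param multimericObserved Target observed multimeric fraction.
#' @param pLabel Labeling probability used when solving the weight.
#' @param copies Copy number of the oligomeric component.
#' @return Named probability vector over copy numbers.
#' @export
defaultCopyNumberDist <- function(multimericObserved = 0.39, pLabel = 0.4,
                                  copies = 4L) {
  f <- function(w) {
    d <- c(w, 1 - w)
    names(d) <- c("1", as.character(copies))
    obs <- expectedObservedClasses(d, pLabel)
    multi <- sum(obs[as.integer(names(obs)) >= 2L])
    vis <- sum(obs[as.integer(names(obs)) >= 1L])
    multi / vis - multimericObserved
  }
  w <- stats::uniroot(f, c(1e-6, 1 - 1e-6), tol = 1e-12)$root
  out <- c(w, 1 - w)
  names(out) <- c("1", as.character(copies))
  out
}

setMethod("show", "SimParams", function(object) {
  cat("SimParams:", object@frames, "frames @", object@frameInterval, "s;",
      "step", object@stepHeight, "counts; noise sd", object@noiseSd, "\n")
  cat("  half-times (s): far-red", object@farredHalfTime,
      "green", object@greenHalfTime,
      "; labeling prob", object@labelingProb, "\n")
  cat("  copy-number dist:",
      paste(sprintf("%s:%.3f", names(object@copyNumberDist),
                    object@copyNumberDist), collapse = " "), "\n")
  cat("  replicates:", object@nBio, "bio x", object@nTech, "tech x",
      object@spotsPerField, "spots\n")
})

#' Read simulation parameters from a YAML or JSON file
#'
#' The file holds a flat mapping whose keys match the arguments of
#' [simParams()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `SimParams` object.
#' @export
readSimParams <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$copyNumberDist))
    cfg$copyNumberDist <- unlist(cfg$copyNumberDist)
  do.call(simParams, cfg)
}

## ---------------------------------------------------------------------------
## TraceSet
## ---------------------------------------------------------------------------

#' @rdname TraceSet
#' @exportClass TraceSet
setClass("TraceSet", contains = "SummarizedExperiment")

setValidity("TraceSet", function(object) {
  msg <- character(0)
  if (!"intensity" %in% assayNames(object) &&
      !"zscore" %in% assayNames(object))
    msg <- c(msg, "TraceSet needs an 'intensity' or 'zscore' assay")
  req <- c("spot_id", "channel", "bio_rep", "tech_rep")
  miss <- setdiff(req, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste("missing colData columns:",
                        paste(miss, collapse = ", ")))
  if ("channel" %in% colnames(colData(object)) &&
      !all(object$channel %in% c("green", "farred")))
    msg <- c(msg, "channel must be 'green' or 'farred'")
  for (a in assayNames(object))
    if (!all(is.finite(assay(object, a))))
      msg <- c(msg, sprintf("assay '%s' contains non-finite values", a))
  if (length(msg)) msg else TRUE
})

#' Container for per-spot fluorescence intensity traces
#'
#' A thin [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment]
#' where columns are spots (traces) and rows are frames. The `intensity`
#' assay holds raw camera counts; a `zscore` assay is added by
#' [zscoreTraces()]. Column metadata records the spot id, channel and
#' replicate provenance, plus any ground-truth or classification columns.
#'
#' @param values Numeric matrix of traces, one trace per row (spots x
#'   frames); it is transposed internally to the frames x spots assay layout.
#' @param info Data frame (or DataFrame) with one row per trace containing at
#'   least `spot_id`, `channel`, `bio_rep`, `tech_rep`.
#' @param assayName Name for the assay, `"intensity"` (raw counts, default)
#'   or `"zscore"`.
#' @return A `TraceSet`.
#' @examples
#' m <- matrix(rnorm(200, 100, 5), nrow = 2)
#' ts <- TraceSet(m, data.frame(spot_id = c("a", "b"), channel = "farred",
#'                              bio_rep = 1L, tech_rep = 1L))
#' ts
#' @export
TraceSet <- function(values, info, assayName = "intensity") {
  info <- as(info, "DataFrame")
  stopifnot(nrow(info) == nrow(values))
  a <- list(t(values))
  names(a) <- assayName
  se <- SummarizedExperiment(assays = a, colData = info)
  colnames(se) <- info$spot_id
  new("TraceSet", se)
}

#' @describeIn TraceSet Traces as a spots x frames matrix.
#' @param x,object A `TraceSet`.
#' @param assay Which assay to return.
#' @export
traceMatrix <- function(x, assay = "intensity") {
  t(SummarizedExperiment::assay(x, assay))
}

#' @describeIn TraceSet Number of frames per trace.
#' @export
nFrames <- function(x) nrow(x)

setMethod("show", "TraceSet", function(object) {
  cat("TraceSet with", ncol(object), "traces x", nrow(object), "frames\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  tab <- table(object$channel)
  cat("  channels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat("  replicates:", length(unique(object$bio_rep)), "bio x",
      length(unique(paste(object$bio_rep, object$tech_rep))), "bio:tech\n")
  extra <- setdiff(colnames(colData(object)),
                   c("spot_id", "channel", "bio_rep", "tech_rep"))
  if (length(extra))
    cat("  extra colData:", paste(extra, collapse = ", "), "\n")
})
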