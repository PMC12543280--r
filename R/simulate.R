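#' Binomial thinning of fluorophore labels
#'
#' Incomplete dye labeling is modeled as independent Bernoulli retention of
#' each fluorophore: a complex with `nTrue` tagged subunits carries a
#' Binomial(`nTrue`, `pLabel`) number of fluorescent ones. HaloTag/Janelia
#' Fluor labeling in lysate reaches roughly 40% efficiency, which is the
#' package default elsewhere.
#'
#' @param nTrue Integer vector of true fluorophore counts (>= 0).
#' @param pLabel Labeling probability in \[0, 1\].
#' @return Integer vector of labeled counts, elementwise `<= nTrue`.
#' @examples
#' set.seed(1)
#' drawLabeledCopies(rep(3L, 5), 0.4)
#' @export
drawLabeledCopies <- function(nTrue, pLabel) {
  if (!is.numeric(pLabel) || length(pLabel) != 1L || is.na(pLabel) ||
      pLabel < 0 || pLabel > 1)
    stop("pLabel must be a single probability in [0, 1]")
  if (any(nTrue < 0)) stop("nTrue must be >= 0")
  stats::rbinom(length(nTrue), as.integer(nTrue), pLabel)
}

## Frames survived by a fluorophore bleaching at time T: it contributes full
## intensity to frame i iff i * frameInterval <= T (partial-frame bleaching
## is not modeled).
framesSurvived <- function(bleachTimes, frameInterval) {
  floor(bleachTimes / frameInterval)
}

#' Simulate one photobleaching trace
#'
#' Each fluorophore photobleaches at an independent exponential time with the
#' channel's half-time; the trace is baseline + stepHeight x (surviving
#' fluorophores) + Gaussian noise per frame.
#'
#' @param nLabeled Number of fluorescent fluorophores on the spot.
#' @param channel `"green"` or `"farred"` (selects the half-time).
#' @param params A [SimParams] object.
#' @return A list with `values` (numeric vector of length `frames`) and
#'   `bleachTimes` (ascending, seconds).
#' @examples
#' set.seed(1)
#' tr <- simulateTrace(2L, "farred", simParams())
#' length(tr$values)
#' @export
simulateTrace <- function(nLabeled, channel, params) {
  out <- simulateTraceMatrix(nLabeled, channel, params)
  list(values = out$values[1L, ], bleachTimes = out$bleachTimes[[1L]])
}

#' Simulate many traces at once
#'
#' Vectorized form of [simulateTrace()]: one trace per element of
#' `nLabeled`.
#'
#' @inheritParams simulateTrace
#' @param nLabeled Integer vector of fluorophore counts, one trace each.
#' @return List with `values` (length(nLabeled) x frames matrix) and
#'   `bleachTimes` (list of ascending numeric vectors).
#' @export
simulateTraceMatrix <- function(nLabeled, channel, params) {
  channel <- match.arg(channel, c("green", "farred"))
  stopifnot(all(nLabeled >= 0))
  nLabeled <- as.integer(nLabeled)
  L <- params@frames
  dt <- params@frameInterval
  half <- if (channel == "green") params@greenHalfTime else params@farredHalfTime
  rate <- log(2) / half
  n <- length(nLabeled)
  total <- sum(nLabeled)

  values <- matrix(stats::rnorm(n * L, 0, params@noiseSd), nrow = n) +
    params@baseline
  bleachTimes <- rep(list(numeric(0)), n)
  if (total > 0L) {
    times <- stats::rexp(total, rate)
    owner <- rep.int(seq_len(n), nLabeled)
    bleachTimes <- split(times, factor(owner, levels = seq_len(n)))
    bleachTimes <- lapply(bleachTimes, sort)
    names(bleachTimes) <- NULL
    ## survivors(frame) per trace via a -step delta at each bleach frame,
    ## cumulated along time
    s <- framesSurvived(times, dt)
    values <- values + outer(nLabeled, rep(1, L)) * params@stepHeight
    drop <- s < L          # bleaches visible inside the recording
    if (any(drop)) {
      r <- owner[drop]
      f <- pmax(s[drop], 0L) + 1L   # first frame without this fluorophore
      key <- (r - 1) * L + f
      agg <- rowsum(rep(params@stepHeight, length(key)), key)
      key <- as.numeric(rownames(agg))
      delta <- matrix(0, n, L)
      fr <- ((key - 1) %% L) + 1
      rw <- ((key - 1) %/% L) + 1
      delta[cbind(rw, fr)] <- agg[, 1L]
      values <- values - t(apply(delta, 1L, cumsum))
    }
  }
  list(values = values, bleachTimes = bleachTimes)
}

#' Ground-truth photobleaching step count visible in a recording
#'
#' A bleach event produces a visible step only if the fluorophore survives at
#' least one full frame and bleaches before the final frame.
#'
#' @param bleachTimes Numeric vector of bleach times (seconds).
#' @param params A [SimParams].
#' @return Integer count of visible steps.
#' @export
visibleSteps <- function(bleachTimes, params) {
  s <- framesSurvived(bleachTimes, params@frameInterval)
  sum(s >= 1L & s < params@frames)
}

#' Simulate a full replicated SiMPull experiment
#'
#' Draws `spotsPerField` complexes for each of `nBio` x `nTech` replicates.
#' Every complex carries one green fluorophore (fluorescent with probability
#' `greenLabelProb`) and a true far-red copy number drawn from
#' `copyNumberDist`, thinned by the labeling probability. A far-red trace is
#' emitted for every complex (a complex with zero labeled far-red copies
#' yields a baseline-only trace, the synthetic analogue of a trace a human
#' annotator would reject); a green trace is emitted only when the green
#' fluorophore is fluorescent.
#'
#' @param params A [SimParams].
#' @return List with `traces` (a [TraceSet] holding both channels) and
#'   `truth` (data.frame of per-complex ground truth: true and labeled
#'   far-red copies, green label state, sub-pixel position, replicate
#'   indices, and bleach-time list columns).
#' @examples
#' set.seed(1)
#' sim <- simulateExperiment(simParams(nBio = 1L, nTech = 1L,
#'                                     spotsPerField = 20L, frames = 100L))
#' sim$traces
#' @export
simulateExperiment <- function(params) {
  validObject(params)
  nC <- params@nBio * params@nTech * params@spotsPerField
  bio <- rep(seq_len(params@nBio), each = params@nTech * params@spotsPerField)
  tech <- rep(rep(seq_len(params@nTech), each = params@spotsPerField),
              times = params@nBio)
  idx <- rep(seq_len(params@spotsPerField), times = params@nBio * params@nTech)
  spotId <- sprintf("b%02d_t%02d_s%05d", bio, tech, idx)

  copies <- as.integer(names(params@copyNumberDist))
  trueCopies <- copies[sample.int(length(copies), nC, replace = TRUE,
                                  prob = params@copyNumberDist)]
  labeled <- drawLabeledCopies(trueCopies, params@labelingProb)
  greenLab <- stats::rbinom(nC, 1L, params@greenLabelProb) == 1L

  margin <- ceiling(4 * params@psfSd) + 1
  x <- stats::runif(nC, margin, params@imageShape[2L] - margin)
  y <- stats::runif(nC, margin, params@imageShape[1L] - margin)

  fr <- simulateTraceMatrix(labeled, "farred", params)
  gr <- simulateTraceMatrix(as.integer(greenLab), "green", params)

  truth <- data.frame(
    spot_id = spotId, bio_rep = bio, tech_rep = tech,
    true_farred_copies = trueCopies, labeled_farred_copies = labeled,
    green_labeled = greenLab, x = x, y = y,
    stringsAsFactors = FALSE)
  truth$farred_bleach_times <- fr$bleachTimes
  truth$green_bleach_times <- gr$bleachTimes

  keepG <- which(greenLab)
  values <- rbind(fr$values, gr$values[keepG, , drop = FALSE])
  info <- data.frame(
    spot_id = c(spotId, spotId[keepG]),
    channel = rep(c("farred", "green"), c(nC, length(keepG))),
    bio_rep = c(bio, bio[keepG]),
    tech_rep = c(tech, tech[keepG]),
    n_labeled = c(labeled, rep(1L, length(keepG))),
    stringsAsFactors = FALSE)
  ts <- TraceSet(values, info)
  colnames(ts) <- make.unique(paste(info$channel, info$spot_id, sep = ":"))
  list(traces = ts, truth = truth)
}

#' Build a labeled training dataset from simulation
#'
#' Simulates single-channel traces with known fluorophore counts, annotates
#' each with the deterministic step-counting rubric ([countStepsReference()])
#' exactly as a human labeler would score the recording, Z-score normalizes
#' the traces, and returns them ready for classifier training. Traces with
#' zero variance (possible at `noiseSd = 0`) cannot be Z-scored and are kept
#' as all-zero normalized traces labeled `rejected`.
#'
#' @param params A [SimParams].
#' @param nTraces Number of traces to generate.
#' @param channel `"farred"` (default) or `"green"`.
#' @param stepThreshold,minPlateau Rubric parameters passed to
#'   [countStepsReference()].
#' @return A [TraceSet] with a `zscore` assay; colData gains `label`,
#'   `reject_reason`, `n_labeled` (ground-truth fluorophores) and
#'   `true_class` (class implied by the visible ground-truth bleach events).
#'   `metadata(x)$classCounts` tabulates the labels.
#' @examples
#' set.seed(1)
#' ds <- makeLabeledDataset(simParams(frames = 200L), nTraces = 20L)
#' S4Vectors::metadata(ds)$classCounts
#' @export
makeLabeledDataset <- function(params, nTraces = 1000L, channel = "farred",
                               stepThreshold = 25, minPlateau = 5L) {
  validObject(params)
  copies <- as.integer(names(params@copyNumberDist))
  if (channel == "green") {
    ## the bait carries a single genetically encoded fluorophore
    nTrue <- rep(1L, nTraces)
    labeled <- drawLabeledCopies(nTrue, params@greenLabelProb)
  } else {
    nTrue <- copies[sample.int(length(copies), nTraces, replace = TRUE,
                               prob = params@copyNumberDist)]
    labeled <- drawLabeledCopies(nTrue, params@labelingProb)
  }
  sim <- simulateTraceMatrix(labeled, channel, params)

  ann <- labelTraces(sim$values, channel, stepThreshold = stepThreshold,
                     minPlateau = minPlateau)
  z <- matrix(0, nrow(sim$values), ncol(sim$values))
  for (i in seq_len(nrow(sim$values))) {
    v <- sim$values[i, ]
    if (stats::sd(v) > 0) z[i, ] <- zscore(v)
  }
  trueClass <- vapply(seq_len(nTraces), function(i) {
    binClass(channel, list(n_steps = visibleSteps(sim$bleachTimes[[i]], params),
                           stopped_early = FALSE, rejected = FALSE))
  }, character(1))

  info <- data.frame(
    spot_id = sprintf("train_%06d", seq_len(nTraces)),
    channel = channel, bio_rep = 1L, tech_rep = 1L,
    n_labeled = labeled, label = ann$label,
    reject_reason = ann$reject_reason, true_class = trueClass,
    stringsAsFactors = FALSE)
  ts <- TraceSet(z, info, assayName = "zscore")
  metadata(ts)$classCounts <- table(factor(ann$label,
                                           levels = channelClasses(channel)))
  metadata(ts)$bleachTimes <- sim$bleachTimes
  ts
}

## ---------------------------------------------------------------------------
## Trace table I/O (spot_id, channel, bio_rep, tech_rep, frame_0..frame_{L-1})
## ---------------------------------------------------------------------------

#' Write / read trace tables
#'
#' Flat CSV/TSV interchange format: one row per trace with columns
#' `spot_id`, `channel`, `bio_rep`, `tech_rep` followed by
#' `frame_0 ... frame_{L-1}`.
#'
#' @param x A [TraceSet].
#' @param path Output (or input) file; `.tsv` extension selects tabs.
#' @param assay Assay to export.
#' @return `readTraceTable` returns a [TraceSet]; `writeTraceTable` returns
#'   `path` invisibly.
#' @export
writeTraceTable <- function(x, path, assay = assayNames(x)[1L]) {
  m <- traceMatrix(x, assay)
  colnames(m) <- sprintf("frame_%d", seq_len(ncol(m)) - 1L)
  df <- cbind(as.data.frame(colData(x)[, c("spot_id", "channel",
                                           "bio_rep", "tech_rep")]),
              as.data.frame(m))
  rownames(df) <- NULL
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}

#' @rdname writeTraceTable
#' @export
readTraceTable <- function(path, assay = "intensity") {
  df <- data.table::fread(path, data.table = FALSE)
  fcols <- grep("^frame_", colnames(df), value = TRUE)
  fcols <- fcols[order(as.integer(sub("frame_", "", fcols)))]
  values <- as.matrix(df[, fcols, drop = FALSE])
  dimnames(values) <- NULL
  info <- df[, c("spot_id", "channel", "bio_rep", "tech_rep")]
  TraceSet(values, info, assayName = assay)
}
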