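#' Changepoint segmentation of a photobleaching trace
#'
#' Recursive binary segmentation for mean shifts: within each segment the
#' split minimizing the residual sum of squares is found, and accepted when
#' both resulting plateaus span at least `minPlateau` frames and their means
#' differ by more than `ampThreshold` counts. Accepted splits are recursed
#' into; the procedure is the mechanical analogue of a human scanning a trace
#' for sustained discrete intensity changes.
#'
#' @param values Numeric vector, one raw trace (camera counts).
#' @param minPlateau Minimum plateau length in frames. At 20 frames/sec the
#'   default 5 frames corresponds to a 0.25 s dwell, the shortest change a
#'   labeler would call "sustained".
#' @param ampThreshold Minimum absolute mean difference between adjacent
#'   plateaus, in counts.
#' @param minZ Statistical guard against spurious splits: a candidate must
#'   also clear `minZ` noise standard errors of the plateau-mean difference
#'   (noise estimated robustly from first differences). The default keeps a
#'   flat pure-noise trace at 0 changepoints while leaving genuine steps,
#'   which are several times the frame noise, untouched.
#' @return Integer vector of changepoints, each the index of the first frame
#'   of a new plateau (sorted; empty if the trace is flat).
#' @examples
#' x <- rep(c(300, 250, 200), each = 50)
#' segmentPlateaus(x)
#' @export
segmentPlateaus <- function(values, minPlateau = 5L, ampThreshold = 25,
                            minZ = 4.5) {
  n <- length(values)
  if (n < 2L * minPlateau)
    stop("trace too short to segment (need >= 2 * minPlateau frames)")
  sigma <- stats::mad(diff(values)) / sqrt(2)
  cps <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    a <- seg[1L]; b <- seg[2L]
    len <- b - a + 1L
    if (len < 2L * minPlateau) next
    x <- values[a:b]
    cs <- cumsum(x)
    tot <- cs[len]
    j <- seq.int(minPlateau, len - minPlateau)   # last index of left plateau
    meanL <- cs[j] / j
    meanR <- (tot - cs[j]) / (len - j)
    ## minimizing RSS over split <=> maximizing j*(len-j)/len * (meanL-meanR)^2
    gain <- j * (len - j) * (meanL - meanR)^2
    k <- which.max(gain)
    guard <- max(ampThreshold,
                 minZ * sigma * sqrt(1 / j[k] + 1 / (len - j[k])))
    if (abs(meanL[k] - meanR[k]) > guard) {
      cp <- a + j[k]                              # first frame of new plateau
      cps <- c(cps, cp)
      stack[[length(stack) + 1L]] <- c(a, cp - 1L)
      stack[[length(stack) + 1L]] <- c(cp, b)
    }
  }
  sort(cps)
}

#' Count photobleaching steps with the manual-labeling rubric
#'
#' Deterministic reference implementation of the trace-scoring rubric used to
#' build training labels: plateaus are walked in time order and every
#' sustained mean decrease greater than `stepThreshold` counts is counted as
#' one photobleaching step. Counting stops early at the first sustained mean
#' increase greater than the threshold (e.g. a second molecule landing in the
#' spot). A trace is rejected when no steps were counted, or when signal
#' variability would prevent a labeler from seeing discrete drops ---
#' operationalized as a pooled within-plateau standard deviation above
#' `stepThreshold / 2`.
#'
#' The thresholds act on raw camera counts; passing a Z-scored trace is a
#' contract violation and raises an error.
#'
#' @inheritParams segmentPlateaus
#' @param stepThreshold Minimum sustained decrease, in counts (default 25).
#' @return List (class `StepAnnotation`) with `n_steps`, `stopped_early`,
#'   `rejected`, `reject_reason` (`NA`, `"no-steps"` or
#'   `"high-variability"`) and the `changepoints` used.
#' @examples
#' x <- rep(c(400, 300, 200, 100), each = 50)
#' countStepsReference(x)$n_steps
#' @export
countStepsReference <- function(values, stepThreshold = 25, minPlateau = 5L) {
  mu <- mean(values)
  sdp <- stats::sd(values) * sqrt((length(values) - 1) / length(values))
  if (abs(mu) < 1e-8 && abs(sdp - 1) < 1e-8)
    stop("trace appears Z-scored; step counting operates on raw counts")

  cps <- segmentPlateaus(values, minPlateau = minPlateau,
                         ampThreshold = stepThreshold)
  bounds <- c(1L, cps, length(values) + 1L)
  nPlat <- length(bounds) - 1L
  means <- vars <- lens <- numeric(nPlat)
  for (i in seq_len(nPlat)) {
    seg <- values[bounds[i]:(bounds[i + 1L] - 1L)]
    means[i] <- mean(seg)
    lens[i] <- length(seg)
    vars[i] <- if (length(seg) > 1L) stats::var(seg) else 0
  }

  nSteps <- 0L
  stopped <- FALSE
  if (nPlat > 1L) {
    for (i in seq_len(nPlat - 1L)) {
      d <- means[i + 1L] - means[i]
      if (d < -stepThreshold) nSteps <- nSteps + 1L
      else if (d > stepThreshold) { stopped <- TRUE; break }
    }
  }
  pooledSd <- sqrt(sum(vars * (lens - 1)) / sum(lens - 1))
  rejected <- FALSE
  reason <- NA_character_
  if (pooledSd > stepThreshold / 2) {
    rejected <- TRUE; reason <- "high-variability"
  } else if (nSteps == 0L) {
    rejected <- TRUE; reason <- "no-steps"
  }
  structure(list(n_steps = nSteps, stopped_early = stopped,
                 rejected = rejected, reject_reason = reason,
                 changepoints = cps),
            class = "StepAnnotation")
}

#' @export
print.StepAnnotation <- function(x, ...) {
  cat("StepAnnotation:", x$n_steps, "step(s)",
      if (x$stopped_early) "(stopped early)" else "",
      if (x$rejected) sprintf("[rejected: %s]", x$reject_reason) else "", "\n")
  invisible(x)
}

#' Bin a step annotation into a channel's trace class
#'
#' Far-red traces fall into four classes --- `rejected`, `1-step`, `2-step`
#' and `3plus` (three-and-higher-step combined) --- while green traces are
#' `1-step` only when exactly one photobleaching event was counted and
#' `rejected` otherwise (a multi-event green trace means the bait was not
#' monomeric).
#'
#' @param channel `"green"` or `"farred"`.
#' @param annotation A `StepAnnotation` (or list with `n_steps` and
#'   `rejected`).
#' @return A single class label from [channelClasses()].
#' @examples
#' binClass("farred", list(n_steps = 5L, rejected = FALSE))
#' binClass("green", list(n_steps = 2L, rejected = FALSE))
#' @export
binClass <- function(channel, annotation) {
  channel <- match.arg(channel, c("green", "farred"))
  n <- annotation$n_steps
  rej <- isTRUE(annotation$rejected)
  if (channel == "farred") {
    if (rej || n == 0L) return("rejected")
    if (n == 1L) return("1-step")
    if (n == 2L) return("2-step")
    return("3plus")
  }
  if (!rej && n == 1L) "1-step" else "rejected"
}

#' Annotate and classify a matrix of raw traces
#'
#' Applies [countStepsReference()] then [binClass()] to every row of a raw
#' trace matrix (or every trace in a [TraceSet]).
#'
#' @param x Numeric matrix (traces in rows, raw counts) or a [TraceSet] with
#'   an `intensity` assay.
#' @param channel Channel whose class set to use (for a `TraceSet` taken
#'   per-trace from its colData when missing).
#' @inheritParams countStepsReference
#' @return data.frame with `label`, `n_steps`, `stopped_early`,
#'   `reject_reason`; for a single-channel matrix one row per input row.
#' @export
labelTraces <- function(x, channel = NULL, stepThreshold = 25,
                        minPlateau = 5L) {
  if (is(x, "TraceSet")) {
    ch <- if (is.null(channel)) x$channel else rep(channel, ncol(x))
    m <- traceMatrix(x, "intensity")
  } else {
    stopifnot(!is.null(channel))
    ch <- rep(channel, nrow(x))
    m <- x
  }
  n <- nrow(m)
  label <- character(n); nst <- integer(n)
  se <- logical(n); rr <- character(n)
  for (i in seq_len(n)) {
    ann <- countStepsReference(m[i, ], stepThreshold = stepThreshold,
                               minPlateau = minPlateau)
    label[i] <- binClass(ch[i], ann)
    if (ch[i] == "green" && label[i] == "rejected" && !ann$rejected &&
        ann$n_steps > 1L)
      ann$reject_reason <- "multi-event-green"
    nst[i] <- ann$n_steps
    se[i] <- ann$stopped_early
    rr[i] <- ann$reject_reason
  }
  data.frame(label = label, n_steps = nst, stopped_early = se,
             reject_reason = rr, stringsAsFactors = FALSE)
}
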