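#' Z-score normalize a trace
#'
#' Centers to zero mean and scales to unit standard deviation using the
#' population (1/n) standard deviation --- the convention under which a
#' fixed-length signal fed to the classifiers has exactly mean 0 and sd 1,
#' and the same convention is applied at training and inference time.
#'
#' @param values Numeric vector with at least 2 frames.
#' @return Numeric vector of Z-scores.
#' @examples
#' zscore(c(1, 2, 3))
#' @export
zscore <- function(values) {
  if (length(values) < 2L) stop("trace needs at least 2 frames")
  mu <- mean(values)
  sdp <- sqrt(mean((values - mu)^2))
  if (sdp == 0) stop("degenerate trace: zero variance, cannot Z-score")
  (values - mu) / sdp
}

#' Z-score normalize every trace in a TraceSet
#'
#' Adds a `zscore` assay computed row-wise (per trace) from the `intensity`
#' assay. Zero-variance traces raise an error unless `onDegenerate =
#' "reject"`, in which case they become all-zero normalized traces and are
#' flagged in a logical `degenerate` colData column (such traces are
#' rejected downstream).
#'
#' @param x A [TraceSet] with an `intensity` assay.
#' @param onDegenerate `"error"` (default) or `"reject"`.
#' @return `x` with a `zscore` assay.
#' @export
zscoreTraces <- function(x, onDegenerate = c("error", "reject")) {
  onDegenerate <- match.arg(onDegenerate)
  m <- traceMatrix(x, "intensity")
  mu <- rowMeans(m)
  sdp <- sqrt(rowMeans((m - mu)^2))
  bad <- sdp == 0
  if (any(bad) && onDegenerate == "error")
    stop("degenerate trace(s) with zero variance: ",
         paste(utils::head(x$spot_id[bad], 3L), collapse = ", "))
  sdp[bad] <- 1
  z <- (m - mu) / sdp
  SummarizedExperiment::assay(x, "zscore") <- t(z)
  x$degenerate <- bad
  x
}

#' Extract an intensity trace from an image stack
#'
#' Sums pixel counts over a square region of interest of half-width
#' `roiRadius` centered on the spot, per frame. The default 2 px radius
#' (a 5 x 5 ROI) comfortably covers a diffraction-limited PSF of ~1 px sd.
#'
#' @param stack Numeric array (rows x cols x frames).
#' @param x,y Spot center in pixels (continuous; rounded to the nearest
#'   pixel for the ROI).
#' @param roiRadius ROI half-width in pixels.
#' @return Numeric vector, one summed count per frame.
#' @export
extractTrace <- function(stack, x, y, roiRadius = 2L) {
  stopifnot(length(dim(stack)) == 3L)
  cx <- round(x); cy <- round(y)
  rows <- (cy - roiRadius):(cy + roiRadius)
  cols <- (cx - roiRadius):(cx + roiRadius)
  if (min(rows) < 1L || min(cols) < 1L ||
      max(rows) > dim(stack)[1L] || max(cols) > dim(stack)[2L])
    stop("ROI extends outside the image")
  apply(stack[rows, cols, , drop = FALSE], 3L, sum)
}

#' Per-frame count of surviving fluorescent spots
#'
#' For an ensemble of raw traces, a spot is deemed still fluorescent in a
#' frame while its intensity exceeds the midpoint between baseline and the
#' single-fluorophore level; the survival curve is the per-frame count of
#' such spots. A short median filter suppresses single-frame noise
#' excursions.
#'
#' @param values Matrix of raw traces (traces in rows).
#' @param threshold Counts above which a spot is alive; defaults to
#'   baseline + stepHeight/2 when `params` is given.
#' @param params Optional [SimParams] supplying the default threshold.
#' @return Integer vector of length `ncol(values)`.
#' @export
survivalCounts <- function(values, threshold = NULL, params = NULL) {
  if (is.null(threshold)) {
    stopifnot(!is.null(params))
    threshold <- params@baseline + params@stepHeight / 2
  }
  sm <- t(apply(values, 1L, stats::runmed, k = 5L))
  alive <- sm > threshold
  ## a spot is counted until its last above-threshold frame
  last <- apply(alive, 1L, function(a) if (any(a)) max(which(a)) else 0L)
  tab <- tabulate(last[last > 0L], nbins = ncol(values))
  rev(cumsum(rev(tab)))
}

#' Photobleaching half-time from a survival curve
#'
#' Fits the exponential decay N(t) = N0 exp(-lambda t) by least squares on
#' the log-linearized counts (zero-count frames excluded) and returns
#' ln(2)/lambda.
#'
#' @param counts Per-frame number of surviving fluorescent spots, or a
#'   matrix of raw traces (then converted via [survivalCounts()], which
#'   requires `params` or `threshold`).
#' @param frameInterval Seconds per frame.
#' @param threshold,params Passed to [survivalCounts()] for matrix input.
#' @return Half-time in seconds.
#' @examples
#' t <- seq(0, 50, by = 0.05)
#' bleachHalfTime(1000 * exp(-0.0693 * t), frameInterval = 0.05)
#' @export
bleachHalfTime <- function(counts, frameInterval = 0.05, threshold = NULL,
                           params = NULL) {
  if (is.matrix(counts))
    counts <- survivalCounts(counts, threshold = threshold, params = params)
  if (length(counts) < 10L) stop("need at least 10 frames of survival counts")
  t <- (seq_along(counts) - 1L) * frameInterval
  keep <- counts > 0
  fit <- stats::lm.fit(cbind(1, t[keep]), log(counts[keep]))
  lambda <- -fit$coefficients[2L]
  if (!is.finite(lambda) || lambda <= 0)
    stop("no bleaching detected: fitted decay rate is not positive")
  unname(log(2) / lambda)
}
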