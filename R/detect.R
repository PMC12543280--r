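## Separable Gaussian smoothing used by the detector (small fixed kernel).
gaussSmooth <- function(img, sd) {
  if (sd <= 0) return(img)
  r <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(-r:r, sd = sd)
  k <- k / sum(k)
  pad <- function(m, n) rbind(m[rep(1L, n), , drop = FALSE], m,
                              m[rep(nrow(m), n), , drop = FALSE])
  conv1 <- function(m) {           # filter along rows (dimension 1)
    mp <- pad(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[j:(j + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img))))
}

#' Detect diffraction-limited spots in a single image
#'
#' Background-subtracted local-maximum detection with sub-pixel centroid
#' refinement. The image background and its spread are estimated robustly
#' (median and MAD); after light Gaussian smoothing, pixels exceeding
#' background + `kSd` x spread that are strict 8-neighborhood maxima become
#' candidates, refined to sub-pixel coordinates by an intensity-weighted
#' centroid over a small window. When more candidates are found than
#' `maxSpots`, only the brightest are kept; the automatic cap follows the
#' upstream acquisition software's convention `floor(imgArea / 3e5 *
#' capScale)`, which is tied to the full sCMOS sensor area --- for small
#' synthetic fields pass an explicit `maxSpots`.
#'
#' @param image Numeric matrix (single frame, camera counts).
#' @param kSd Detection threshold in robust standard deviations above
#'   background (default 5).
#' @param maxSpots Maximum number of spots kept (brightest first);
#'   `NULL` (default) applies the area-based cap, `Inf` disables capping.
#' @param capScale Scale factor for the automatic cap.
#' @param smoothSd Gaussian smoothing sd in pixels applied before maximum
#'   finding.
#' @param window Half-width of the centroid-refinement window.
#' @return data.frame with `x`, `y` (continuous pixel coordinates, x =
#'   column, y = row) and `peak` (smoothed peak intensity), ordered from
#'   brightest down. A flat (zero-variance) image yields zero rows.
#' @examples
#' img <- matrix(0, 32, 32); img[16, 16] <- 100
#' detectSpots(img, maxSpots = Inf)
#' @export
detectSpots <- function(image, kSd = 5, maxSpots = NULL, capScale = 1,
                        smoothSd = 1, window = 3L) {
  stopifnot(is.matrix(image), length(image) > 0L)
  if (is.null(maxSpots))
    maxSpots <- floor(length(image) / 3e5 * capScale)
  empty <- data.frame(x = numeric(0), y = numeric(0), peak = numeric(0))
  bg <- stats::median(image)
  spread <- stats::mad(image)
  if (spread == 0) spread <- stats::sd(image)
  if (!is.finite(spread) || spread == 0) return(empty)

  sm <- gaussSmooth(image, smoothSd)
  thr <- stats::median(sm) + kSd * max(stats::mad(sm), 1e-12)
  nr <- nrow(sm); nc <- ncol(sm)
  if (nr < 3L || nc < 3L) return(empty)
  core <- sm[2:(nr - 1L), 2:(nc - 1L)]
  isMax <- core > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    isMax <- isMax & (core > sm[(2:(nr - 1L)) + dr, (2:(nc - 1L)) + dc])
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  ry <- idx[, 1L] + 1L
  cx <- idx[, 2L] + 1L
  peak <- sm[cbind(ry, cx)]
  ord <- order(peak, decreasing = TRUE)
  if (nrow(idx) > maxSpots) ord <- ord[seq_len(maxSpots)]
  ry <- ry[ord]; cx <- cx[ord]; peak <- peak[ord]

  ## sub-pixel refinement: intensity-weighted centroid on the
  ## background-subtracted raw image
  xs <- ys <- numeric(length(ry))
  for (i in seq_along(ry)) {
    rows <- max(1L, ry[i] - window):min(nr, ry[i] + window)
    cols <- max(1L, cx[i] - window):min(nc, cx[i] + window)
    w <- pmax(image[rows, cols, drop = FALSE] - bg, 0)
    tw <- sum(w)
    if (tw > 0) {
      ys[i] <- sum(rows * rowSums(w)) / tw
      xs[i] <- sum(cols * colSums(w)) / tw
    } else { ys[i] <- ry[i]; xs[i] <- cx[i] }
  }
  data.frame(x = xs, y = ys, peak = peak)
}

#' Estimate the green-to-far-red registration shift from bead images
#'
#' Multicolor beads imaged in both channels provide fiducials: spots are
#' detected in each image, paired by mutual nearest neighbor, and the pure
#' translation minimizing the mean squared distance between matched
#' centroids --- i.e. the mean coordinate difference --- is returned, after
#' one re-matching pass with the provisional shift applied. At least 3
#' consistent matches are required, and the post-fit RMS residual must stay
#' below `residualTol` (beads that cannot be overlaid to ~1 px are not a
#' valid registration pair).
#'
#' @param beadGreen,beadFarred Numeric matrices, one bead image per channel.
#' @param kSd Detection threshold passed to [detectSpots()].
#' @param maxShift Largest plausible shift magnitude in pixels (initial
#'   match radius).
#' @param residualTol Maximum RMS residual (pixels) after registration.
#' @return Named numeric `c(dx, dy)`: the offset such that far-red
#'   coordinates minus `(dx, dy)` land on green coordinates.
#' @export
estimateRegistration <- function(beadGreen, beadFarred, kSd = 5,
                                 maxShift = 5, residualTol = 1) {
  g <- detectSpots(beadGreen, kSd = kSd, maxSpots = Inf)
  f <- detectSpots(beadFarred, kSd = kSd, maxSpots = Inf)
  if (nrow(g) < 3L || nrow(f) < 3L)
    stop("insufficient beads: need at least 3 detections per channel")
  shift <- c(dx = 0, dy = 0)
  for (pass in 1:2) {
    pairs <- mutualNearestPairs(g$x, g$y, f$x - shift[1L], f$y - shift[2L],
                                maxDist = maxShift)
    if (nrow(pairs) < 3L)
      stop("insufficient beads: fewer than 3 mutual matches")
    shift <- c(dx = mean(f$x[pairs$j] - g$x[pairs$i]),
               dy = mean(f$y[pairs$j] - g$y[pairs$i]))
  }
  res <- sqrt(mean((f$x[pairs$j] - shift[1L] - g$x[pairs$i])^2 +
                   (f$y[pairs$j] - shift[2L] - g$y[pairs$i])^2))
  if (res > residualTol)
    stop(sprintf(paste("beads could not be matched consistently",
                       "(RMS residual %.2f px > %.2f px)"), res, residualTol))
  shift
}

## Mutual nearest-neighbor matching with deterministic smallest-index
## tie-break; distances computed on the supplied (already registered)
## coordinates.
mutualNearestPairs <- function(xa, ya, xb, yb, maxDist = Inf) {
  na <- length(xa); nb <- length(xb)
  if (na == 0L || nb == 0L)
    return(data.frame(i = integer(0), j = integer(0), distance = numeric(0)))
  d2 <- outer(xa, xb, "-")^2 + outer(ya, yb, "-")^2
  nnb <- apply(d2, 1L, which.min)   # ties: which.min takes smallest index
  nna <- apply(d2, 2L, which.min)
  i <- seq_len(na)
  mutual <- nna[nnb] == i
  dist <- sqrt(d2[cbind(i, nnb)])
  keep <- mutual & dist <= maxDist
  data.frame(i = i[keep], j = nnb[keep], distance = dist[keep])
}

#' Pair colocalized green and far-red spots
#'
#' Applies the registration shift to the far-red coordinates, then pairs
#' spots across channels by mutual nearest neighbor, keeping pairs whose
#' registered distance is at most `colocDistance` (inclusive; the upstream
#' convention fixes it at 2 pixels). Ties are broken deterministically by
#' smallest spot index; every spot belongs to at most one pair.
#'
#' @param greens,farreds data.frames from [detectSpots()] (columns `x`,
#'   `y`).
#' @param transform Registration shift `c(dx, dy)` from
#'   [estimateRegistration()]; subtracted from far-red coordinates.
#' @param colocDistance Maximum registered separation in pixels.
#' @return data.frame with `green`, `farred` (row indices into the inputs)
#'   and `distance` (pixels, after registration).
#' @export
colocalizeSpots <- function(greens, farreds, transform = c(0, 0),
                            colocDistance = 2) {
  pairs <- mutualNearestPairs(greens$x, greens$y,
                              farreds$x - transform[1L],
                              farreds$y - transform[2L],
                              maxDist = colocDistance)
  data.frame(green = pairs$i, farred = pairs$j, distance = pairs$distance)
}
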