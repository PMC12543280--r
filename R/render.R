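## Peak-normalized Gaussian PSF patch restricted to a local window around
## the spot; returns the patch matrix plus its row/col extent.
psfPatch <- function(x, y, shape, psfSd) {
  H <- shape[1L]; W <- shape[2L]
  r <- ceiling(5 * psfSd)
  rows <- max(1L, floor(y) - r):min(H, ceiling(y) + r)
  cols <- max(1L, floor(x) - r):min(W, ceiling(x) + r)
  gy <- stats::dnorm(rows, mean = y, sd = psfSd)
  gx <- stats::dnorm(cols, mean = x, sd = psfSd)
  list(rows = rows, cols = cols,
       patch = outer(gy, gx) / stats::dnorm(0, sd = psfSd)^2)
}

## Per-frame noiseless amplitudes (counts above background) for a list of
## bleach-time vectors.
amplitudeMatrix <- function(bleachTimes, frames, frameInterval, stepHeight) {
  A <- matrix(0, length(bleachTimes), frames)
  tIdx <- seq_len(frames)
  for (s in seq_along(bleachTimes)) {
    surv <- framesSurvived(bleachTimes[[s]], frameInterval)
    if (length(surv))
      A[s, ] <- stepHeight * colSums(outer(surv, tIdx, ">="))
  }
  A
}

#' Render a synthetic two-channel TIRF field
#'
#' Rasterizes the ground truth of one field into green and far-red image
#' stacks plus a pair of bead registration images. Each spot is drawn as a
#' symmetric 2-D Gaussian of sd `psfSd` whose peak amplitude follows the
#' noiseless part of the spot's photobleaching trace; far-red positions are
#' offset by `registrationShift`, emulating chromatic misalignment between
#' the two camera paths. Per-pixel Gaussian noise of sd `noiseSd` is added
#' to every frame. Bead images contain common bright point sources offset by
#' the same shift.
#'
#' @param truth data.frame of ground-truth complexes as produced by
#'   [simulateExperiment()] (columns `x`, `y`, `green_labeled`, and the
#'   bleach-time list columns); typically one technical replicate's rows.
#' @param params A [SimParams] with `imageShape` and `psfSd` set.
#' @param nBeads Number of registration beads.
#' @param beadAmplitude Peak intensity of a bead.
#' @return List with `green` and `farred` stacks (rows x cols x frames
#'   arrays), `beadGreen`/`beadFarred` single-frame matrices and
#'   `beadPositions`.
#' @export
renderField <- function(truth, params, nBeads = 12L, beadAmplitude = NULL) {
  validObject(params)
  H <- params@imageShape[1L]; W <- params@imageShape[2L]
  L <- params@frames
  shift <- params@registrationShift
  if (nrow(truth)) {
    outside <- truth$x < 1 | truth$x > W | truth$y < 1 | truth$y > H |
      (truth$x + shift[1L]) < 1 | (truth$x + shift[1L]) > W |
      (truth$y + shift[2L]) < 1 | (truth$y + shift[2L]) > H
    if (any(outside)) stop("spot position(s) outside the image")
  }
  if (is.null(beadAmplitude)) beadAmplitude <- 40 * params@stepHeight

  renderStack <- function(xs, ys, A) {
    stack <- array(stats::rnorm(H * W * L, 0, params@noiseSd),
                   dim = c(H, W, L))
    for (i in seq_along(xs)) {
      if (all(A[i, ] == 0)) next
      pp <- psfPatch(xs[i], ys[i], c(H, W), params@psfSd)
      stack[pp$rows, pp$cols, ] <- stack[pp$rows, pp$cols, ] +
        array(outer(pp$patch, A[i, ]),
              dim = c(length(pp$rows), length(pp$cols), L))
    }
    stack
  }

  gbt <- truth$green_bleach_times
  gbt[!truth$green_labeled] <- list(numeric(0))
  Ag <- amplitudeMatrix(gbt, L, params@frameInterval, params@stepHeight)
  Af <- amplitudeMatrix(truth$farred_bleach_times,
                        L, params@frameInterval, params@stepHeight)
  green <- renderStack(truth$x, truth$y, Ag)
  farred <- renderStack(truth$x + shift[1L], truth$y + shift[2L], Af)

  margin <- ceiling(4 * params@psfSd) + 1 + max(abs(shift))
  bx <- stats::runif(nBeads, margin, W - margin)
  by <- stats::runif(nBeads, margin, H - margin)
  beadImage <- function(xs, ys) {
    img <- matrix(stats::rnorm(H * W, 0, params@noiseSd), H, W)
    for (i in seq_along(xs)) {
      pp <- psfPatch(xs[i], ys[i], c(H, W), params@psfSd)
      img[pp$rows, pp$cols] <- img[pp$rows, pp$cols] +
        beadAmplitude * pp$patch
    }
    img
  }
  list(green = green, farred = farred,
       beadGreen = beadImage(bx, by),
       beadFarred = beadImage(bx + shift[1L], by + shift[2L]),
       beadPositions = data.frame(x = bx, y = by))
}

#' Write / read image stacks as multi-page 16-bit TIFF
#'
#' Camera counts are stored as 16-bit unsigned integers (the native sCMOS
#' bit depth); values are clipped to \[0, 65535\] and rounded, so the
#' round-trip is exact for integer counts in range and loses at most half a
#' count otherwise.
#'
#' @param stack Numeric array (rows x cols x frames) or a matrix (single
#'   frame), in camera counts.
#' @param path TIFF file path.
#' @return `readStack` returns a rows x cols x frames array in counts.
#' @export
writeStack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  pages <- lapply(seq_len(dim(stack)[3L]), function(i)
    pmin(pmax(round(stack[, , i]), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' @rdname writeStack
#' @export
readStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  array(round(unlist(pages) * 65535), dim = c(dim(pages[[1L]]), length(pages)))
}
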