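## Shared fixtures: small simulated datasets and memoized trained CNNs so
## that several test files can reuse one training run.

.fixtures <- new.env(parent = emptyenv())

## Balanced, cleanly separable far-red dataset (low noise, full labeling).
separableParams <- function(noiseSd = 5) {
  simParams(copyNumberDist = c("0" = .25, "1" = .25, "2" = .25, "3" = .25),
            labelingProb = 1, noiseSd = noiseSd)
}

separableDataset <- function(n = 2000L, seed = 42L) {
  key <- sprintf("sep_%d_%d", n, seed)
  if (is.null(.fixtures[[key]])) {
    set.seed(seed)
    .fixtures[[key]] <- makeLabeledDataset(separableParams(), nTraces = n)
  }
  .fixtures[[key]]
}

## Far-red CNN trained on data drawn from the default study conditions
## (mixed copy numbers, 40% labeling, default noise); used by the
## quantification recovery tests.
defaultFarredCNN <- function() {
  if (is.null(.fixtures$farredCNN)) {
    set.seed(101)
    ds <- makeLabeledDataset(simParams(), nTraces = 6000L)
    fit <- trainClassifier(ds, ds$label,
                           cnnArchitecture(kernel = 15, filters = 8,
                                           pool = 10, dense = 32,
                                           nClasses = 4),
                           trainConfig(epochs = 15L, seed = 7L))
    .fixtures$farredCNN <- fit$model
  }
  .fixtures$farredCNN
}

defaultGreenCNN <- function() {
  if (is.null(.fixtures$greenCNN)) {
    set.seed(102)
    ds <- makeLabeledDataset(simParams(), nTraces = 3000L, channel = "green")
    fit <- trainClassifier(ds, ds$label,
                           cnnArchitecture(kernel = 15, filters = 8,
                                           pool = 10, dense = 32,
                                           nClasses = 2),
                           trainConfig(epochs = 10L, seed = 7L))
    .fixtures$greenCNN <- fit$model
  }
  .fixtures$greenCNN
}

## Brute-force mutual nearest-neighbor pairing, the independent oracle for
## colocalization.
bruteForcePairs <- function(g, f, transform = c(0, 0), maxDist = 2) {
  fx <- f$x - transform[1L]; fy <- f$y - transform[2L]
  pairs <- data.frame(green = integer(0), farred = integer(0),
                      distance = numeric(0))
  for (i in seq_len(nrow(g))) {
    d <- sqrt((g$x[i] - fx)^2 + (g$y[i] - fy)^2)
    j <- which.min(d)
    dback <- sqrt((g$x - fx[j])^2 + (g$y - fy[j])^2)
    if (which.min(dback) == i && d[j] <= maxDist)
      pairs <- rbind(pairs, data.frame(green = i, farred = j,
                                       distance = d[j]))
  }
  pairs
}

## Ground-truth field for rendering tests: spots on a jittered grid with
## immortal fluorophores (bleach far beyond the recording).
gridTruth <- function(n, params, immortal = TRUE) {
  if (n == 0L) {
    truth <- data.frame(spot_id = character(0), x = numeric(0),
                        y = numeric(0), green_labeled = logical(0))
    truth$farred_bleach_times <- vector("list", 0L)
    truth$green_bleach_times <- vector("list", 0L)
    return(truth)
  }
  side <- ceiling(sqrt(n))
  margin <- ceiling(4 * params@psfSd) + 2 +
    max(abs(params@registrationShift))
  gx <- seq(margin, params@imageShape[2L] - margin, length.out = side)
  gy <- seq(margin, params@imageShape[1L] - margin, length.out = side)
  pos <- expand.grid(x = gx, y = gy)[seq_len(n), ]
  bt <- if (immortal) 1e6 else params@farredHalfTime
  truth <- data.frame(spot_id = sprintf("s%03d", seq_len(n)),
                      x = pos$x + runif(n, -0.4, 0.4),
                      y = pos$y + runif(n, -0.4, 0.4),
                      green_labeled = TRUE)
  truth$farred_bleach_times <- rep(list(bt), n)
  truth$green_bleach_times <- rep(list(bt), n)
  truth
}
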