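#' @useDynLib SiMPullCount, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Describe a 1-D CNN architecture
#'
#' One or more convolution blocks (1-D convolution, ReLU, non-overlapping
#' max pooling) followed by fully connected ReLU layers and a softmax
#' output.
#'
#' @param kernel,filters,pool Vectors of equal length, one entry per conv
#'   block: kernel size in frames, number of filters, pooling width.
#' @param dense Integer vector of hidden dense-layer widths (may be empty).
#' @param nClasses Number of output classes (2 for green, 4 for far-red).
#' @param inputLength Trace length the network accepts (frames).
#' @return Architecture description list (class `cnnArch`).
#' @examples
#' cnnArchitecture(kernel = 15, filters = 8, pool = 10, dense = 32,
#'                 nClasses = 4)
#' @export
cnnArchitecture <- function(kernel = 15L, filters = 8L, pool = 10L,
                            dense = 32L, nClasses = 4L,
                            inputLength = 1000L) {
  stopifnot(length(kernel) == length(filters),
            length(kernel) == length(pool), length(kernel) >= 1L,
            nClasses %in% c(2L, 4L))
  blocks <- lapply(seq_along(kernel), function(i)
    list(kernel = as.integer(kernel[i]), filters = as.integer(filters[i]),
         pool = as.integer(pool[i])))
  arch <- list(blocks = blocks, dense = as.integer(dense),
               nClasses = as.integer(nClasses),
               inputLength = as.integer(inputLength))
  class(arch) <- "cnnArch"
  ## verify the trace length survives the conv/pool pipeline
  archFlatDim(arch)
  arch
}

archFlatDim <- function(arch) {
  L <- arch$inputLength
  f <- 1L
  for (b in arch$blocks) {
    L <- L - b$kernel + 1L
    L <- L %/% b$pool
    f <- b$filters
    if (L < 1L) stop("architecture collapses the trace length")
  }
  L * f
}

#' @export
print.cnnArch <- function(x, ...) {
  bl <- vapply(x$blocks, function(b)
    sprintf("conv(k=%d,f=%d)+pool(%d)", b$kernel, b$filters, b$pool), "")
  cat("cnnArch:", paste(bl, collapse = " -> "), "-> dense[",
      paste(x$dense, collapse = ","), "] ->", x$nClasses, "classes (input",
      x$inputLength, "frames)\n")
  invisible(x)
}

#' Default architecture grid for the model search
#'
#' A compact declarative grid (kernel sizes 5/15/31, 8 or 16 filters, one or
#' two dense layers) standing in for a larger exploratory sweep; extend it
#' by building additional [cnnArchitecture()] entries.
#'
#' @param nClasses,inputLength Passed to every candidate.
#' @return List of `cnnArch` objects.
#' @export
defaultArchGrid <- function(nClasses = 4L, inputLength = 1000L) {
  grid <- expand.grid(kernel = c(5L, 15L, 31L), filters = c(8L, 16L),
                      dense = c("32", "64,32"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    cnnArchitecture(kernel = grid$kernel[i], filters = grid$filters[i],
                    pool = 10L,
                    dense = as.integer(strsplit(grid$dense[i], ",")[[1L]]),
                    nClasses = nClasses, inputLength = inputLength))
}

#' Training hyperparameters
#'
#' @param learningRate Adam learning rate.
#' @param batchSize Minibatch size.
#' @param epochs Number of passes over the training set.
#' @param seed RNG seed fixing initialization and batch order.
#' @param splitFraction Train fraction for validation splits.
#' @param kFolds Folds for cross-validation.
#' @return Named list of settings.
#' @export
trainConfig <- function(learningRate = 1e-3, batchSize = 128L, epochs = 12L,
                        seed = 1L, splitFraction = 0.8, kFolds = 5L) {
  stopifnot(splitFraction > 0, splitFraction < 1, kFolds >= 2L)
  list(learningRate = learningRate, batchSize = as.integer(batchSize),
       epochs = as.integer(epochs), seed = as.integer(seed),
       splitFraction = splitFraction, kFolds = as.integer(kFolds))
}

## ---------------------------------------------------------------------------
## StepClassifier
## ---------------------------------------------------------------------------

#' @rdname StepClassifier
#' @export
setClass("StepClassifier", representation(
  arch = "list", params = "list", classMap = "character",
  channel = "character", provenance = "list"))

setValidity("StepClassifier", function(object) {
  if (length(object@classMap) != object@arch$nClasses)
    return("classMap length must equal the number of output classes")
  TRUE
})

#' Trained 1-D CNN trace classifier
#'
#' Holds the architecture, learned parameters, ordered class labels and
#' training provenance (seed, config, class weights). Built by
#' [trainClassifier()]; apply with [classifyTraces()].
#'
#' @name StepClassifier
#' @aliases StepClassifier-class
NULL

setMethod("show", "StepClassifier", function(object) {
  cat("StepClassifier (", object@channel, "): ", sep = "")
  print(structure(object@arch, class = "cnnArch"))
  cat("  classes:", paste(object@classMap, collapse = ", "), "\n")
  if (length(object@provenance))
    cat("  trained: seed", object@provenance$seed, "epochs",
        object@provenance$epochs, "\n")
})

## ---------------------------------------------------------------------------
## Class weights and splits
## ---------------------------------------------------------------------------

#' Inverse class frequency loss weights
#'
#' Class imbalance is compensated by weighting each class inversely to its
#' abundance: `w_c = N / (K * n_c)` with `N` the total count and `K` the
#' number of classes, so underrepresented classes receive larger weight, the
#' mean weight is 1 and the identity `sum(w_c * n_c) = N` holds exactly.
#'
#' @param classCounts Named (or unnamed) vector of per-class trace counts,
#'   all positive.
#' @return Numeric weights, one per class, same order/names as the input.
#' @examples
#' computeClassWeights(c(12563, 10926, 5053, 1593))
#' @export
computeClassWeights <- function(classCounts) {
  if (any(classCounts <= 0))
    stop("all class counts must be positive to form inverse-frequency weights")
  N <- sum(classCounts)
  K <- length(classCounts)
  N / (K * classCounts)
}

#' Stratified train/validation split
#'
#' Randomized split preserving per-class proportions to within one trace.
#'
#' @param labels Vector of class labels, every class with >= 2 members.
#' @param fraction Fraction assigned to the training set.
#' @param seed RNG seed making the split reproducible.
#' @return List with integer index vectors `train` and `validation`
#'   (disjoint, union = all indices).
#' @export
stratifiedSplit <- function(labels, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  tab <- table(labels)
  if (any(tab < 2L))
    stop("every class needs at least 2 members to stratify")
  set.seed(seed)
  train <- integer(0)
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    nTrain <- round(fraction * length(idx))
    nTrain <- max(1L, min(length(idx) - 1L, nTrain))
    train <- c(train, sample(idx, nTrain))
  }
  train <- sort(train)
  list(train = train, validation = setdiff(seq_along(labels), train))
}

## Stratified k folds: returns a fold id per observation.
stratifiedFolds <- function(labels, k, seed = 1L) {
  tab <- table(labels)
  if (k > min(tab))
    stop("k exceeds the size of the smallest class")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

## ---------------------------------------------------------------------------
## Training
## ---------------------------------------------------------------------------

initParams <- function(arch) {
  params <- list()
  fin <- 1L
  for (b in arch$blocks) {
    fanIn <- b$kernel * fin
    params <- c(params, list(
      matrix(stats::rnorm(fanIn * b$filters, 0, sqrt(2 / fanIn)),
             fanIn, b$filters),
      matrix(0, 1, b$filters)))
    fin <- b$filters
  }
  din <- archFlatDim(arch)
  for (w in c(arch$dense, arch$nClasses)) {
    params <- c(params, list(
      matrix(stats::rnorm(din * w, 0, sqrt(2 / din)), din, w),
      matrix(0, 1, w)))
    din <- w
  }
  params
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamUpdate <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = params, state = state)
}

asTraceInput <- function(x, assay = "zscore") {
  if (is(x, "TraceSet")) traceMatrix(x, assay) else as.matrix(x)
}

#' Train a 1-D CNN trace classifier
#'
#' Minimizes weighted cross-entropy (inverse-class-frequency weights from
#' [computeClassWeights()], computed on the training labels) with Adam over
#' shuffled minibatches. Training is deterministic given `config$seed` on a
#' fixed platform; exact floating-point reproducibility across BLAS builds
#' is not promised.
#'
#' @param x Z-scored traces: matrix (traces in rows) or a [TraceSet] with a
#'   `zscore` assay.
#' @param labels Class labels, one per trace.
#' @param arch A [cnnArchitecture()].
#' @param config A [trainConfig()].
#' @param validation Optional list `list(x =, labels =)` scored after
#'   training.
#' @param classes Class order for the output layer; defaults to
#'   [channelClasses()] order when labels match a channel's class set,
#'   otherwise sorted unique labels.
#' @param channel Stored on the model for bookkeeping.
#' @param classWeights `NULL` (default) for inverse-class-frequency weights
#'   computed from the training labels, `"uniform"` for unweighted
#'   cross-entropy, or a numeric vector of per-class weights in `classes`
#'   order.
#' @return List with `model` (a [StepClassifier]), `history` (per-epoch mean
#'   loss) and, when validation data are given, `metrics` (accuracy,
#'   macro-F1, per-class F1, confusion matrix).
#' @export
trainClassifier <- function(x, labels, arch, config = trainConfig(),
                            validation = NULL, classes = NULL,
                            channel = if (arch$nClasses == 2L) "green"
                                      else "farred",
                            classWeights = NULL) {
  m <- asTraceInput(x)
  if (ncol(m) != arch$inputLength)
    stop("trace length ", ncol(m), " does not match architecture input ",
         arch$inputLength)
  if (is.null(classes)) {
    std <- channelClasses(channel)
    classes <- if (all(labels %in% std)) std else sort(unique(labels))
  }
  if (!all(labels %in% classes)) stop("labels outside the class set")
  y <- as.integer(factor(labels, levels = classes)) - 1L
  counts <- table(factor(labels, levels = classes))
  if (any(counts == 0))
    stop("every class must be represented in the training labels")
  w <- if (is.null(classWeights)) {
    computeClassWeights(as.numeric(counts))
  } else if (identical(classWeights, "uniform")) {
    rep(1, length(classes))
  } else {
    stopifnot(is.numeric(classWeights),
              length(classWeights) == length(classes))
    classWeights
  }

  set.seed(config$seed)
  params <- initParams(arch)
  state <- adamInit(params)
  n <- nrow(m)
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = config$batchSize)) {
      idx <- ord[start:min(start + config$batchSize - 1L, n)]
      out <- cnnBatch(m[idx, , drop = FALSE], y[idx], params,
                      unclass(arch), w, TRUE)
      if (!is.finite(out$loss))
        stop("training diverged: non-finite loss")
      upd <- adamUpdate(params, out$grads, state, config$learningRate)
      params <- upd$params
      state <- upd$state
      losses <- c(losses, out$loss)
    }
    history[ep] <- mean(losses)
  }

  model <- new("StepClassifier", arch = unclass(arch), params = params,
               classMap = classes, channel = channel,
               provenance = list(seed = config$seed, epochs = config$epochs,
                                 learningRate = config$learningRate,
                                 batchSize = config$batchSize,
                                 classWeights = as.numeric(w),
                                 classCounts = as.numeric(counts)))
  res <- list(model = model, history = history)
  if (!is.null(validation)) {
    pred <- classifyTraces(model, validation$x)
    res$metrics <- classificationMetrics(validation$labels, pred$class,
                                         classes)
  }
  res
}

#' Classify Z-scored traces with a trained model
#'
#' @param model A [StepClassifier].
#' @param x Z-scored traces (matrix or [TraceSet] with `zscore` assay) of
#'   the model's input length.
#' @return List with `class` (character vector) and `probs` (matrix of
#'   per-class probabilities, rows summing to 1).
#' @export
classifyTraces <- function(model, x) {
  m <- asTraceInput(x)
  if (ncol(m) != model@arch$inputLength)
    stop("trace length ", ncol(m), " does not match model input length ",
         model@arch$inputLength)
  probs <- cnnPredict(m, model@params, model@arch)
  colnames(probs) <- model@classMap
  cls <- model@classMap[max.col(probs, ties.method = "first")]
  list(class = cls, probs = probs)
}

#' Confusion matrix with row-normalized recall
#'
#' @param true,predicted Equal-length label vectors drawn from `classes`.
#' @param classes Class set defining row/column order.
#' @return List with `counts` (rows = truth) and `recall` (rows normalized
#'   to 1; all-zero rows stay 0).
#' @export
confusionMatrix <- function(true, predicted, classes = sort(unique(true))) {
  if (length(true) != length(predicted))
    stop("label vectors must have equal length")
  if (!all(true %in% classes) || !all(predicted %in% classes))
    stop("label outside the class set")
  counts <- table(factor(true, levels = classes),
                  factor(predicted, levels = classes))
  counts <- unclass(counts)
  names(dimnames(counts)) <- c("true", "predicted")
  rs <- rowSums(counts)
  recall <- counts / ifelse(rs == 0, 1, rs)
  list(counts = counts, recall = recall)
}

classificationMetrics <- function(true, predicted, classes) {
  cm <- confusionMatrix(true, predicted, classes)
  tp <- diag(cm$counts)
  prec <- tp / pmax(colSums(cm$counts), 1)
  rec <- tp / pmax(rowSums(cm$counts), 1)
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  list(accuracy = sum(tp) / length(true), macroF1 = mean(f1),
       perClassF1 = f1, confusion = cm)
}

#' Stratified k-fold cross-validation of an architecture
#'
#' @inheritParams trainClassifier
#' @param k Number of folds (default from `config`).
#' @return List with `folds` (data.frame of per-fold accuracy and macro-F1),
#'   `meanAccuracy`, `sdAccuracy`, `meanMacroF1`, `sdMacroF1`.
#' @export
crossValidate <- function(x, labels, arch, config = trainConfig(),
                          k = config$kFolds, channel = NULL) {
  m <- asTraceInput(x)
  if (is.null(channel)) channel <- if (arch$nClasses == 2L) "green" else "farred"
  fold <- stratifiedFolds(labels, k, seed = config$seed)
  acc <- f1 <- numeric(k)
  for (i in seq_len(k)) {
    tr <- fold != i
    fit <- trainClassifier(m[tr, , drop = FALSE], labels[tr], arch,
                           config = config,
                           validation = list(x = m[!tr, , drop = FALSE],
                                             labels = labels[!tr]),
                           channel = channel)
    acc[i] <- fit$metrics$accuracy
    f1[i] <- fit$metrics$macroF1
  }
  list(folds = data.frame(fold = seq_len(k), accuracy = acc, macroF1 = f1),
       meanAccuracy = mean(acc), sdAccuracy = stats::sd(acc),
       meanMacroF1 = mean(f1), sdMacroF1 = stats::sd(f1))
}

#' Architecture search with validation ranking and CV finalist selection
#'
#' Every candidate is trained on a stratified `splitFraction` split and
#' ranked by validation accuracy; the top five then undergo k-fold
#' cross-validation, and the final pick maximizes mean CV accuracy (macro-F1
#' breaks ties).
#'
#' @param x,labels Training data as in [trainClassifier()].
#' @param candidates List of [cnnArchitecture()] objects (>= 2).
#' @param config A [trainConfig()].
#' @param topK Number of finalists cross-validated.
#' @return List with `leaderboard` (all candidates ranked by validation
#'   accuracy), `cv` (finalist CV summaries) and `best` (index into
#'   `candidates`).
#' @export
searchArchitectures <- function(x, labels, candidates, config = trainConfig(),
                                topK = 5L) {
  if (length(candidates) < 2L) stop("need at least 2 candidate architectures")
  m <- asTraceInput(x)
  sp <- stratifiedSplit(labels, config$splitFraction, seed = config$seed)
  valAcc <- valF1 <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    fit <- trainClassifier(m[sp$train, , drop = FALSE], labels[sp$train],
                           candidates[[i]], config = config,
                           validation = list(
                             x = m[sp$validation, , drop = FALSE],
                             labels = labels[sp$validation]))
    valAcc[i] <- fit$metrics$accuracy
    valF1[i] <- fit$metrics$macroF1
  }
  ord <- order(valAcc, valF1, -seq_along(valAcc), decreasing = TRUE)
  leaderboard <- data.frame(candidate = ord, valAccuracy = valAcc[ord],
                            valMacroF1 = valF1[ord])
  finalists <- leaderboard$candidate[seq_len(min(topK, length(candidates)))]
  cv <- lapply(finalists, function(i)
    crossValidate(m, labels, candidates[[i]], config = config))
  cvAcc <- vapply(cv, `[[`, numeric(1), "meanAccuracy")
  cvF1 <- vapply(cv, `[[`, numeric(1), "meanMacroF1")
  best <- finalists[order(cvAcc, cvF1, decreasing = TRUE)[1L]]
  list(leaderboard = leaderboard,
       cv = data.frame(candidate = finalists, cvMeanAccuracy = cvAcc,
                       cvMeanMacroF1 = cvF1),
       best = best)
}

## ---------------------------------------------------------------------------
## Model serialization (text-only: JSON architecture + weights)
## ---------------------------------------------------------------------------

#' Save / load a trained classifier
#'
#' The model is written as a directory of JSON files: `architecture.json`,
#' `classmap.json` and `weights.json` (full-precision numbers).
#'
#' @param model A [StepClassifier].
#' @param dir Directory to create/read.
#' @return `readClassifier` returns a [StepClassifier].
#' @export
writeClassifier <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(model@arch, file.path(dir, "architecture.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(classes = model@classMap,
                            channel = model@channel,
                            provenance = model@provenance),
                       file.path(dir, "classmap.json"),
                       auto_unbox = TRUE, digits = NA)
  w <- lapply(model@params, function(p)
    list(dim = dim(p), data = as.numeric(p)))
  jsonlite::write_json(w, file.path(dir, "weights.json"), digits = NA)
  invisible(dir)
}

#' @rdname writeClassifier
#' @export
readClassifier <- function(dir) {
  arch <- jsonlite::read_json(file.path(dir, "architecture.json"),
                              simplifyVector = TRUE)
  arch$blocks <- lapply(seq_len(nrow(arch$blocks)), function(i)
    as.list(arch$blocks[i, ]))
  arch$dense <- as.integer(arch$dense)
  arch$nClasses <- as.integer(arch$nClasses)
  arch$inputLength <- as.integer(arch$inputLength)
  cm <- jsonlite::read_json(file.path(dir, "classmap.json"),
                            simplifyVector = TRUE)
  w <- jsonlite::read_json(file.path(dir, "weights.json"),
                           simplifyVector = FALSE)
  params <- lapply(w, function(p)
    matrix(unlist(p$data), unlist(p$dim)[1L], unlist(p$dim)[2L]))
  new("StepClassifier", arch = arch, params = params,
      classMap = cm$classes, channel = cm$channel,
      provenance = as.list(cm$provenance))
}
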