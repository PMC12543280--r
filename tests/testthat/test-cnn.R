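test_that("inverse class frequency weights match independent arithmetic", {
  expect_equal(computeClassWeights(c(10, 10)), c(1, 1))
  ## frozen values computed independently from N/(K n_c) with the published
  ## far-red manifest counts
  w <- computeClassWeights(c(12563, 10926, 5053, 1593))
  expect_equal(w, c(0.59965, 0.68954, 1.49092, 4.72904), tolerance = 1e-4)
  expect_identical(which.max(w), 4L)
  expect_error(computeClassWeights(c(5, 0, 3)), "positive")
})

test_that("the class-weight identity sum(w*n) = N holds for random counts", {
  set.seed(50)
  for (i in 1:50) {
    counts <- sample(1:5000, sample(2:6, 1))
    w <- computeClassWeights(counts)
    expect_equal(sum(w * counts), sum(counts), tolerance = 1e-9)
    expect_identical(order(w), order(counts, decreasing = TRUE))
  }
})

test_that("stratified splits preserve class proportions and are reproducible", {
  labels <- rep(c("a", "b"), each = 50)
  sp <- stratifiedSplit(labels, 0.8, seed = 1)
  expect_identical(sum(labels[sp$train] == "a"), 40L)
  expect_identical(sum(labels[sp$train] == "b"), 40L)
  expect_identical(length(sp$validation), 20L)
  expect_identical(sort(c(sp$train, sp$validation)), seq_along(labels))

  sp2 <- stratifiedSplit(labels, 0.8, seed = 1)
  expect_identical(sp, sp2)

  lab4 <- rep(c("a", "b", "c", "d"), c(40, 30, 20, 10))
  sp4 <- stratifiedSplit(lab4, 0.8, seed = 3)
  expect_identical(as.integer(table(lab4[sp4$train])), c(32L, 24L, 16L, 8L))

  expect_error(stratifiedSplit(c("a", "a", "b"), 0.8), "2 members")
})

test_that("training on separable traces reaches high validation accuracy", {
  ds <- separableDataset(2000L)
  z <- traceMatrix(ds, "zscore")
  lab <- ds$label
  arch <- cnnArchitecture(kernel = 15, filters = 8, pool = 10, dense = 32,
                          nClasses = 4)
  sp <- stratifiedSplit(lab, 0.8, seed = 1)
  fit <- trainClassifier(z[sp$train, ], lab[sp$train], arch,
                         trainConfig(epochs = 15L, seed = 1L),
                         validation = list(x = z[sp$validation, ],
                                           labels = lab[sp$validation]))
  expect_gt(fit$metrics$accuracy, 0.9)
  expect_true(all(diff(fit$history[c(1, 8, 15)]) < 0))

  ## inference contract: probabilities sum to 1, deterministic, length check
  pred1 <- classifyTraces(fit$model, z[sp$validation, ])
  pred2 <- classifyTraces(fit$model, z[sp$validation, ])
  expect_identical(pred1, pred2)
  expect_true(all(abs(rowSums(pred1$probs) - 1) < 1e-6))
  expect_true(all(pred1$class %in% channelClasses("farred")))
  expect_error(classifyTraces(fit$model, z[, 1:500]), "length")
})

test_that("shuffled labels collapse accuracy to the majority frequency", {
  ds <- separableDataset(2000L)
  z <- traceMatrix(ds, "zscore")
  set.seed(51)
  shuffled <- sample(ds$label)
  sp <- stratifiedSplit(shuffled, 0.5, seed = 2)
  ## unweighted loss and a short budget: the null model settles at chance
  ## instead of overfitting the label noise
  fit <- trainClassifier(z[sp$train, ], shuffled[sp$train],
                         cnnArchitecture(nClasses = 4),
                         trainConfig(epochs = 2L, seed = 2L),
                         classWeights = "uniform",
                         validation = list(x = z[sp$validation, ],
                                           labels = shuffled[sp$validation]))
  majority <- max(table(shuffled)) / length(shuffled)
  expect_lt(abs(fit$metrics$accuracy - majority), 0.05)
})

test_that("single-epoch training runs and reports metrics", {
  ds <- separableDataset(2000L)
  z <- traceMatrix(ds, "zscore")
  idx <- seq_len(400)
  fit <- trainClassifier(z[idx, ], ds$label[idx],
                         cnnArchitecture(nClasses = 4),
                         trainConfig(epochs = 1L, seed = 5L),
                         validation = list(x = z[401:600, ],
                                           labels = ds$label[401:600]))
  expect_length(fit$history, 1L)
  expect_true(is.finite(fit$metrics$accuracy))
  expect_length(fit$metrics$perClassF1, 4L)
})

test_that("cross-validation builds disjoint covering folds and aggregates", {
  ds <- separableDataset(2000L)
  z <- traceMatrix(ds, "zscore")[1:1000, ]
  lab <- ds$label[1:1000]
  cv <- crossValidate(z, lab, cnnArchitecture(nClasses = 4),
                      trainConfig(epochs = 4L, seed = 3L), k = 5L)
  expect_identical(nrow(cv$folds), 5L)
  expect_equal(cv$meanAccuracy, mean(cv$folds$accuracy), tolerance = 1e-12)
  expect_error(crossValidate(z[1:20, ], c(rep("1-step", 17),
                                          rep("2-step", 3)),
                             cnnArchitecture(nClasses = 4),
                             trainConfig(), k = 5L),
               "smallest class")
})

test_that("fold assignment is stratified, disjoint and covering", {
  lab <- rep(c("a", "b", "c"), c(50, 30, 20))
  fold <- SiMPullCount:::stratifiedFolds(lab, 5L, seed = 9)
  expect_identical(length(fold), 100L)
  expect_setequal(unique(fold), 1:5)
  for (cl in unique(lab)) {
    perFold <- table(fold[lab == cl])
    expect_lte(diff(range(perFold)), 1)
  }
})

test_that("architecture search ranks candidates deterministically", {
  ds <- separableDataset(2000L)
  z <- traceMatrix(ds, "zscore")[1:600, ]
  lab <- ds$label[1:600]
  good <- cnnArchitecture(kernel = 15, filters = 8, pool = 10, dense = 32,
                          nClasses = 4)
  crippled <- cnnArchitecture(kernel = 3, filters = 1, pool = 300, dense = 2,
                              nClasses = 4)
  res <- searchArchitectures(z, lab, list(crippled, good),
                             trainConfig(epochs = 3L, seed = 4L), topK = 2L)
  expect_identical(nrow(res$leaderboard), 2L)
  expect_identical(res$leaderboard$candidate[1L], 2L)   # the real net wins
  res2 <- searchArchitectures(z, lab, list(crippled, good),
                              trainConfig(epochs = 3L, seed = 4L), topK = 2L)
  expect_identical(res, res2)
  expect_error(searchArchitectures(z, lab, list(good), trainConfig()),
               "2 candidate")
})

test_that("confusion matrices count and normalize correctly", {
  classes <- c("a", "b", "c")
  cm <- confusionMatrix(c("a", "b", "c"), c("a", "b", "c"), classes)
  expect_equal(unname(cm$recall), diag(3))
  expect_identical(sum(cm$counts), 3L)

  set.seed(52)
  true <- sample(classes, 4000, replace = TRUE)
  pred <- sample(classes, 4000, replace = TRUE)
  cm2 <- confusionMatrix(true, pred, classes)
  expect_identical(sum(cm2$counts), 4000L)
  expect_true(all(abs(cm2$recall - 1 / 3) < 0.06))
  expect_true(all(abs(rowSums(cm2$recall) - 1) < 1e-12))
  expect_error(confusionMatrix(c("a", "z"), c("a", "a"), classes),
               "class set")
  expect_error(confusionMatrix(c("a"), c("a", "b"), classes), "equal length")
})

test_that("models survive a text serialization round-trip", {
  ds <- separableDataset(2000L)
  z <- traceMatrix(ds, "zscore")
  fit <- trainClassifier(z[1:300, ], ds$label[1:300],
                         cnnArchitecture(nClasses = 4),
                         trainConfig(epochs = 1L, seed = 6L))
  dir <- tempfile("model")
  writeClassifier(fit$model, dir)
  back <- readClassifier(dir)
  expect_identical(back@classMap, fit$model@classMap)
  p1 <- classifyTraces(fit$model, z[301:320, ])
  p2 <- classifyTraces(back, z[301:320, ])
  expect_equal(p1$probs, p2$probs, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("inverse-frequency weighting protects minority-class recall", {
  ## imbalanced, mildly noisy dataset: across paired seeds, weighted
  ## training recalls the rare 3plus class at least as well on average as
  ## unweighted training
  set.seed(53)
  p <- simParams(copyNumberDist = c("0" = .42, "1" = .42, "2" = .10,
                                    "3" = .06),
                 labelingProb = 1, noiseSd = 10)
  ds <- makeLabeledDataset(p, nTraces = 1500L)
  z <- traceMatrix(ds, "zscore")
  lab <- ds$label
  sp <- stratifiedSplit(lab, 0.8, seed = 1)
  arch <- cnnArchitecture(nClasses = 4)
  recall3 <- function(weights, seed) {
    fit <- trainClassifier(z[sp$train, ], lab[sp$train], arch,
                           trainConfig(epochs = 5L, seed = seed),
                           classWeights = weights)
    pred <- classifyTraces(fit$model, z[sp$validation, ])
    cm <- confusionMatrix(lab[sp$validation], pred$class,
                          channelClasses("farred"))
    cm$recall["3plus", "3plus"]
  }
  seeds <- c(11L, 12L, 13L)
  rw <- vapply(seeds, function(s) recall3(NULL, s), numeric(1))
  ru <- vapply(seeds, function(s) recall3("uniform", s), numeric(1))
  expect_gte(mean(rw), mean(ru) - 1e-9)
})
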