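test_that("binomial thinning matches its closed form and edge cases", {
  set.seed(1)
  expect_true(all(drawLabeledCopies(rep(3L, 100), 1.0) == 3L))
  expect_true(all(drawLabeledCopies(rep(3L, 100), 0.0) == 0L))
  expect_error(drawLabeledCopies(3L, 1.5), "probability")
  expect_error(drawLabeledCopies(-1L, 0.5), ">= 0")

  n <- 1e5
  draws <- drawLabeledCopies(rep(3L, n), 0.4)
  emp <- tabulate(draws + 1L, nbins = 4L) / n
  expected <- dbinom(0:3, 3, 0.4)   # 0.216 0.432 0.288 0.064
  expect_true(all(abs(emp - expected) < 4 * sqrt(expected * (1 - expected) / n)))
})

test_that("thinning composes: p1 then p2 is one thinning by p1*p2", {
  set.seed(2)
  n <- 1e5
  twoStage <- drawLabeledCopies(drawLabeledCopies(rep(4L, n), 0.7), 0.5)
  oneStage <- drawLabeledCopies(rep(4L, n), 0.35)
  tab <- rbind(tabulate(twoStage + 1L, 5L), tabulate(oneStage + 1L, 5L))
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
})

test_that("single traces have the right structure and noise behavior", {
  p <- simParams()
  set.seed(3)
  tr0 <- simulateTrace(0L, "farred", p)
  expect_length(tr0$values, p@frames)
  expect_lt(abs(mean(tr0$values) - p@baseline), 5 * p@noiseSd / sqrt(p@frames) + 2)
  expect_true(countStepsReference(tr0$values)$rejected)
  expect_identical(countStepsReference(tr0$values)$n_steps, 0L)

  pq <- simParams(noiseSd = 0)
  set.seed(4)
  tr1 <- simulateTrace(1L, "farred", pq)
  d <- diff(tr1$values)
  expect_equal(sum(d != 0), 1L)
  expect_equal(d[d != 0], -pq@stepHeight)
  stepFrame <- which(d != 0)
  expect_equal(stepFrame, floor(tr1$bleachTimes / pq@frameInterval))
})

test_that("bleach times follow the exponential law with the set half-time", {
  p <- simParams()
  set.seed(5)
  sim <- simulateTraceMatrix(rep(1L, 1e4), "farred", p)
  times <- unlist(sim$bleachTimes)
  fracByHalf <- mean(times <= p@farredHalfTime)
  se <- sqrt(0.25 / 1e4)
  expect_lt(abs(fracByHalf - 0.5), 3 * se)
  ks <- ks.test(times, pexp, rate = log(2) / p@farredHalfTime)
  expect_gt(ks$p.value, 0.01)
})

test_that("noiseless traces are stepwise non-increasing", {
  p <- simParams(noiseSd = 0)
  set.seed(6)
  sim <- simulateTraceMatrix(sample(0:4, 50, replace = TRUE), "farred", p)
  expect_true(all(apply(sim$values, 1L, function(v) all(diff(v) <= 0))))
})

test_that("simulateExperiment bookkeeping and composition are correct", {
  set.seed(7)
  p <- simParams(nBio = 2L, nTech = 2L, spotsPerField = 100L, frames = 50L)
  sim <- simulateExperiment(p)
  expect_equal(nrow(sim$truth), 400L)
  expect_false(anyDuplicated(sim$truth$spot_id) > 0)
  expect_setequal(unique(sim$truth$bio_rep), 1:2)

  p1 <- simParams(copyNumberDist = c("1" = 1), labelingProb = 1,
                  nBio = 1L, nTech = 1L, spotsPerField = 200L, frames = 50L)
  sim1 <- simulateExperiment(p1)
  expect_true(all(sim1$truth$labeled_farred_copies == 1L))
  expect_true(all(lengths(sim1$truth$farred_bleach_times) == 1L))

  ## observed fraction with >= 2 labeled far-red under {1:.6, 3:.4} at p=.4
  set.seed(8)
  p2 <- simParams(copyNumberDist = c("1" = 0.6, "3" = 0.4),
                  labelingProb = 0.4, nBio = 1L, nTech = 1L,
                  spotsPerField = 20000L, frames = 2L)
  sim2 <- simulateExperiment(p2)
  frac <- mean(sim2$truth$labeled_farred_copies >= 2L)
  expected <- 0.4 * (1 - 0.6^3 - 3 * 0.4 * 0.6^2)  # 0.1408
  expect_lt(abs(frac - expected), 4 * sqrt(expected * (1 - expected) / 20000))
})

test_that("the same seed reproduces the experiment bit for bit", {
  p <- simParams(nBio = 1L, nTech = 2L, spotsPerField = 30L, frames = 40L)
  set.seed(99); a <- simulateExperiment(p)
  set.seed(99); b <- simulateExperiment(p)
  expect_identical(traceMatrix(a$traces), traceMatrix(b$traces))
  expect_identical(a$truth$labeled_farred_copies, b$truth$labeled_farred_copies)
})

test_that("trace tables round-trip through CSV", {
  set.seed(10)
  p <- simParams(nBio = 1L, nTech = 1L, spotsPerField = 5L, frames = 30L)
  sim <- simulateExperiment(p)
  f <- tempfile(fileext = ".csv")
  writeTraceTable(sim$traces, f)
  back <- readTraceTable(f)
  expect_equal(unname(traceMatrix(back)), unname(traceMatrix(sim$traces)),
               tolerance = 1e-12)
  expect_identical(back$spot_id, sim$traces$spot_id)
  expect_identical(back$channel, sim$traces$channel)
  unlink(f)
})

test_that("labeled datasets carry rubric labels consistent with ground truth", {
  ## monomeric complexes, full labeling, no noise: rubric equals truth for
  ## every trace whose bleach event is a plateau-length clear of the
  ## recording edges (an event inside the first/last plateau cannot be a
  ## sustained step for any scorer)
  set.seed(11)
  pm <- simParams(copyNumberDist = c("1" = 1), labelingProb = 1, noiseSd = 0)
  ds <- makeLabeledDataset(pm, nTraces = 200L)
  bt <- S4Vectors::metadata(ds)$bleachTimes
  edgeClear <- vapply(bt, function(b) {
    s <- floor(b / pm@frameInterval)
    all(s < 1 | (s >= 5 & s <= pm@frames - 5) | s >= pm@frames)
  }, logical(1))
  expect_identical(ds$label[edgeClear], ds$true_class[edgeClear])
  expect_gt(mean(ds$label == "1-step"), 0.9)

  ## overwhelming noise forces rejection
  set.seed(12)
  ph <- simParams(noiseSd = 2 * 50, copyNumberDist = c("2" = 1),
                  labelingProb = 1)
  dh <- makeLabeledDataset(ph, nTraces = 100L)
  expect_gt(mean(dh$label == "rejected"), 0.5)

  ## balanced mixture, no noise, full labeling: ~25% per class
  set.seed(13)
  pb <- simParams(copyNumberDist = c("0" = .25, "1" = .25, "2" = .25,
                                     "3" = .25),
                  labelingProb = 1, noiseSd = 0)
  db <- makeLabeledDataset(pb, nTraces = 2000L)
  props <- prop.table(table(factor(db$label, levels = channelClasses("farred"))))
  ## ~25% per class, allowing for the few percent of fluorophores whose
  ## bleach falls outside the 50 s visibility window (truth shifts one
  ## class down) on top of Monte-Carlo error
  expect_true(all(abs(props - 0.25) < 0.06))
  truthProps <- prop.table(table(factor(db$true_class,
                                        levels = channelClasses("farred"))))
  expect_true(all(abs(props - truthProps) < 0.02))

  ## z-scored traces satisfy the normalization invariant
  z <- traceMatrix(db, "zscore")
  live <- apply(z, 1L, sd) > 0
  expect_true(all(abs(rowMeans(z[live, ])) < 1e-9))
  expect_true(all(abs(sqrt(rowMeans(z[live, ]^2)) - 1) < 1e-9))
})

test_that("sim params round-trip through a JSON config file", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(frames = 200L, noiseSd = 4, labelingProb = 0.3,
                            copyNumberDist = list("1" = 0.5, "2" = 0.5),
                            nBio = 2L, nTech = 3L, spotsPerField = 10L),
                       f, auto_unbox = TRUE)
  p <- readSimParams(f)
  expect_s4_class(p, "SimParams")
  expect_identical(p@frames, 200L)
  expect_equal(p@labelingProb, 0.3)
  expect_equal(unname(p@copyNumberDist), c(0.5, 0.5))
  expect_equal(p@farredHalfTime, 200 * 0.05 / 5)   # default derived from frames
  unlink(f)
})

test_that("sim params validate their invariants", {
  expect_error(simParams(labelingProb = 1.2), "labelingProb")
  expect_error(simParams(copyNumberDist = c("1" = 0.5, "2" = 0.4)), "sum to 1")
  expect_error(simParams(frames = 1L), "frames")
  expect_error(simParams(farredHalfTime = -1), "half-times")
})
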