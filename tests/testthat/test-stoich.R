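mkPairs <- function(green, farred, bio = 1L, tech = 1L) {
  data.frame(spot_id = sprintf("s%03d", seq_along(green)),
             green_class = green, farred_class = farred,
             bio_rep = bio, tech_rep = tech, stringsAsFactors = FALSE)
}

test_that("pair filtering keeps monomeric-green, non-rejected far-red", {
  p <- mkPairs(green = c("1-step", "rejected", "1-step", "1-step",
                         "rejected", "1-step"),
               farred = c("2-step", "1-step", "rejected", "1-step",
                          "rejected", "3plus"))
  kept <- filterPairs(p)
  expect_identical(nrow(kept), 3L)
  expect_identical(kept$spot_id, c("s001", "s004", "s006"))
  ## idempotence and partition
  expect_identical(filterPairs(kept), kept)
  expect_identical(nrow(kept) + (nrow(p) - nrow(kept)), nrow(p))
  expect_error(filterPairs(mkPairs("2-step", "1-step")), "green class set")
})

test_that("class percentages are exact on constructed tables", {
  all1 <- mkPairs(rep("1-step", 10), rep("1-step", 10))
  s1 <- classPercentages(all1)
  expect_equal(c(s1$pct_1step, s1$pct_2step, s1$pct_3plus), c(100, 0, 0))

  mix <- mkPairs(rep("1-step", 10),
                 rep(c("1-step", "2-step", "3plus"), c(5, 3, 2)))
  sm <- classPercentages(mix)
  expect_equal(c(sm$pct_1step, sm$pct_2step, sm$pct_3plus), c(50, 30, 20))
  expect_identical(sm$n_analyzable, 10L)
})

test_that("percentages sum to 100 across random replicate tables", {
  set.seed(60)
  for (i in 1:200) {
    n <- sample(1:40, 1)
    p <- mkPairs(rep("1-step", n),
                 sample(c("1-step", "2-step", "3plus"), n, replace = TRUE),
                 bio = sample(1:3, n, replace = TRUE),
                 tech = sample(1:2, n, replace = TRUE))
    s <- classPercentages(p)
    full <- !s$empty
    expect_true(all(abs(s$pct_1step[full] + s$pct_2step[full] +
                          s$pct_3plus[full] - 100) < 1e-6))
  }
})

test_that("multimeric percentage rolls up technical then biological means", {
  allMono <- classPercentages(mkPairs(rep("1-step", 20), rep("1-step", 20),
                                      bio = rep(1:2, each = 10),
                                      tech = rep(1:2, 10)))
  r0 <- percentMultimeric(allMono)
  expect_equal(r0$grandMean, 0)

  allMulti <- classPercentages(mkPairs(rep("1-step", 20),
                                       rep(c("2-step", "3plus"), 10),
                                       bio = rep(1:2, each = 10),
                                       tech = rep(1:2, 10)))
  r100 <- percentMultimeric(allMulti)
  expect_equal(r100$grandMean, 100)
  expect_equal(r100$sem, 0)
  expect_identical(r100$nBio, 2L)
})

test_that("nested ANOVA matches the aov Error-stratum oracle on balanced data", {
  set.seed(61)
  d <- expand.grid(tech = 1:4, bio = 1:5, group = c("g1", "g2", "g3"))
  d$value <- rnorm(nrow(d)) +
    rep(rnorm(15, 0, 1.5), each = 4) +           # biological scatter
    ifelse(d$group == "g2", 2, 0)
  res <- nestedAnova(d$value, d$group, d$bio)
  fit <- summary(suppressWarnings(
    stats::aov(value ~ group + Error(factor(group):factor(bio)), data = d)))
  tab <- fit[["Error: factor(group):factor(bio)"]][[1]]
  expect_equal(res$F, tab["group", "F value"], tolerance = 1e-8)
  expect_equal(res$p, tab["group", "Pr(>F)"], tolerance = 1e-8)
  expect_equal(res$dfGroup, tab["group", "Df"])
  expect_equal(res$dfBio, tab["Residuals", "Df"])
  expect_identical(nrow(res$tukey), 3L)
  expect_true(all(res$tukey$p_adj >= 0 & res$tukey$p_adj <= 1))
})

test_that("nested ANOVA p-values are uniform under the null", {
  set.seed(62)
  ps <- replicate(500, {
    val <- rnorm(24) + rep(rnorm(8, 0, 1), each = 3)
    nestedAnova(val, rep(c("a", "b"), each = 12), rep(1:8, each = 3))$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("nested ANOVA detects a 10-biological-SD group separation", {
  set.seed(63)
  hits <- replicate(200, {
    bioEff <- rep(rnorm(8, 0, 1), each = 3)
    shift <- rep(c(0, 10), each = 12)            # 10 biological SDs apart
    val <- rnorm(24, 0, 0.5) + bioEff + shift
    nestedAnova(val, rep(c("a", "b"), each = 12), rep(1:8, each = 3))$p < 0.01
  })
  expect_gte(mean(hits), 0.95)
})

test_that("nested ANOVA validates its nesting structure", {
  expect_error(nestedAnova(rnorm(6), rep("a", 6), rep(1:3, 2)), "2 groups")
  expect_error(nestedAnova(rnorm(6), rep(c("a", "b"), each = 3),
                           rep(1, 6)), "degenerate")
})

test_that("labeling efficiency summarizes replicates and flags bad controls", {
  r <- labelingEfficiency(c(100, 100, 100), c(1, 2, 1))
  expect_equal(r$estimate, 100)
  expect_false(r$flag)
  expect_warning(bad <- labelingEfficiency(c(10, 12), c(30, 28)), "control")
  expect_true(bad$flag)
})

test_that("the thinning forward model has its closed forms", {
  d <- c("1" = 0.3, "2" = 0.5, "4" = 0.2)
  expect_equal(expectedObservedClasses(d, 1), c("0" = 0, "1" = 0.3,
                                                "2" = 0.5, "3" = 0,
                                                "4" = 0.2))
  obs <- expectedObservedClasses(c("2" = 1), 0.4)
  expect_equal(unname(obs), c(0.36, 0.48, 0.16), tolerance = 1e-12)
  expect_equal(sum(expectedObservedClasses(d, 0.37)), 1, tolerance = 1e-12)
  expect_error(expectedObservedClasses(c("1" = 0.4), 0.4), "sum to 1")
  expect_error(expectedObservedClasses(c("1" = 1), 1.4), "pLabel")
})

test_that("forward thinning agrees with Monte Carlo composition", {
  set.seed(64)
  n <- 1e5
  trueDist <- c("1" = 0.6, "3" = 0.4)
  copies <- sample(c(1L, 3L), n, replace = TRUE, prob = trueDist)
  labeled <- drawLabeledCopies(copies, 0.4)
  emp <- tabulate(labeled + 1L, nbins = 4L) / n
  theo <- expectedObservedClasses(trueDist, 0.4)
  expect_true(all(abs(emp - theo) < 4 * sqrt(theo * (1 - theo) / n) + 1e-4))
})

test_that("inverting the thinning model round-trips exact inputs", {
  trueDist <- c("0" = 0.1, "1" = 0.5, "3" = 0.15, "4" = 0.25)
  obs <- expectedObservedClasses(trueDist, 0.4)
  est <- invertTrueDistribution(obs, 0.4, maxCopies = 4L)
  full <- setNames(numeric(5), 0:4)
  full[names(trueDist)] <- trueDist
  expect_equal(est, full, tolerance = 1e-6)

  obs1 <- expectedObservedClasses(c("2" = 1), 1)
  expect_equal(invertTrueDistribution(obs1, 1, maxCopies = 2L),
               c("0" = 0, "1" = 0, "2" = 1), tolerance = 1e-9)

  expect_error(invertTrueDistribution(c("0" = 0.5, "3" = 0.5), 0.4,
                                      maxCopies = 2L), "infeasible")
  expect_error(invertTrueDistribution(obs, 0, maxCopies = 4L),
               "unidentifiable")
})
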