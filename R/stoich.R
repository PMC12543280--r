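#' Filter classified spot pairs down to the analyzable subset
#'
#' A colocalized pair enters the final stoichiometry analysis only when its
#' green trace shows exactly one photobleaching event (monomeric bait) and
#' its far-red trace was not rejected.
#'
#' @param pairs data.frame with columns `green_class` and `farred_class`
#'   (plus any provenance columns, which are preserved).
#' @return The analyzable subset of `pairs` (same columns).
#' @examples
#' filterPairs(data.frame(green_class = c("1-step", "rejected"),
#'                        farred_class = c("2-step", "1-step")))
#' @export
filterPairs <- function(pairs) {
  stopifnot(all(c("green_class", "farred_class") %in% colnames(pairs)))
  if (!all(pairs$green_class %in% GREEN_CLASSES))
    stop("green_class outside the green class set")
  if (!all(pairs$farred_class %in% FARRED_CLASSES))
    stop("farred_class outside the far-red class set")
  pairs[pairs$green_class == "1-step" & pairs$farred_class != "rejected", ,
        drop = FALSE]
}

#' Per-replicate far-red class percentages
#'
#' For each technical replicate, counts the analyzable far-red traces in
#' each class and converts them to percentages of the replicate's analyzable
#' total. Replicates with no analyzable traces are flagged and carry `NA`
#' percentages.
#'
#' @param pairs Analyzable pairs from [filterPairs()] with `bio_rep`,
#'   `tech_rep` and `farred_class` columns.
#' @return data.frame with one row per (bio_rep, tech_rep): `n_analyzable`,
#'   `n_1step`, `n_2step`, `n_3plus`, matching `pct_*` columns and `empty`.
#' @export
classPercentages <- function(pairs) {
  stopifnot(all(c("bio_rep", "tech_rep", "farred_class") %in%
                  colnames(pairs)))
  key <- interaction(pairs$bio_rep, pairs$tech_rep, drop = FALSE)
  lv <- c("1-step", "2-step", "3plus")
  tab <- table(key, factor(pairs$farred_class, levels = lv))
  ids <- do.call(rbind, strsplit(rownames(tab), ".", fixed = TRUE))
  out <- data.frame(bio_rep = type.convert(ids[, 1L], as.is = TRUE),
                    tech_rep = type.convert(ids[, 2L], as.is = TRUE),
                    n_analyzable = as.integer(rowSums(tab)),
                    n_1step = as.integer(tab[, "1-step"]),
                    n_2step = as.integer(tab[, "2-step"]),
                    n_3plus = as.integer(tab[, "3plus"]))
  denom <- ifelse(out$n_analyzable == 0L, NA_real_, out$n_analyzable)
  out$pct_1step <- 100 * out$n_1step / denom
  out$pct_2step <- 100 * out$n_2step / denom
  out$pct_3plus <- 100 * out$n_3plus / denom
  out$empty <- out$n_analyzable == 0L
  out[order(out$bio_rep, out$tech_rep), , drop = FALSE]
}

#' Multimeric complex percentage with replicate roll-up
#'
#' The multimeric percentage of a technical replicate is the share of
#' analyzable complexes whose far-red trace showed two or more
#' photobleaching steps (`2-step` + `3plus`). Each biological replicate is
#' the unweighted mean of its technical replicates, and the experiment-level
#' estimate is the mean with standard error over biological replicates ---
#' mirroring how replicate dot plots present large outlined (biological) and
#' small (technical) points.
#'
#' @param summaries Per-technical-replicate summaries from
#'   [classPercentages()] (empty replicates are dropped with a warning).
#' @return List with `perTech` (adds `pct_multimeric`), `perBio` (one row
#'   per biological replicate) and `grandMean`, `sem`, `nBio`.
#' @export
percentMultimeric <- function(summaries) {
  if (any(summaries$empty)) {
    warning("dropping ", sum(summaries$empty),
            " technical replicate(s) with no analyzable traces")
    summaries <- summaries[!summaries$empty, , drop = FALSE]
  }
  stopifnot(nrow(summaries) > 0L)
  summaries$pct_multimeric <- summaries$pct_2step + summaries$pct_3plus
  bioMeans <- tapply(summaries$pct_multimeric, summaries$bio_rep, mean)
  perBio <- data.frame(bio_rep = type.convert(names(bioMeans), as.is = TRUE),
                       pct_multimeric = as.numeric(bioMeans))
  sem <- if (nrow(perBio) > 1L)
    stats::sd(perBio$pct_multimeric) / sqrt(nrow(perBio)) else NA_real_
  list(perTech = summaries, perBio = perBio,
       grandMean = mean(perBio$pct_multimeric), sem = sem,
       nBio = nrow(perBio))
}

#' Nested one-way ANOVA with Tukey-adjusted pairwise comparisons
#'
#' Tests a group effect on technical-replicate measurements while
#' respecting the replicate hierarchy: the group mean square is compared
#' against the between-biological-replicate (within group) mean square, not
#' the technical-replicate error, so pseudoreplication does not inflate the
#' test. Pairwise group contrasts use the studentized range distribution on
#' the same biological-replicate stratum.
#'
#' @param values Numeric response, one entry per technical replicate.
#' @param group Group (condition) factor.
#' @param bio Biological-replicate identifier, nested within group (labels
#'   need not be globally unique; they are interpreted within group).
#' @return List with the ANOVA table pieces (`F`, `p`, `dfGroup`, `dfBio`,
#'   mean squares), `groupMeans` and `tukey` (data.frame of pairwise
#'   comparisons with adjusted p-values).
#' @export
nestedAnova <- function(values, group, bio) {
  group <- factor(group)
  cell <- interaction(group, bio, drop = TRUE)
  G <- nlevels(group)
  if (G < 2L) stop("need at least 2 groups")
  nBioPerGroup <- tapply(cell, group, function(z) length(unique(droplevels(z))))
  if (any(nBioPerGroup < 2L))
    stop("degenerate nesting: every group needs >= 2 biological replicates")

  grand <- mean(values)
  ng <- tapply(values, group, length)
  mg <- tapply(values, group, mean)
  ssGroup <- sum(ng * (mg - grand)^2)
  dfGroup <- G - 1L

  ncell <- tapply(values, cell, length)
  mcell <- tapply(values, cell, mean)
  cellGroup <- tapply(as.integer(group), cell, function(z) z[1L])
  ssBio <- sum(ncell * (mcell - mg[cellGroup])^2)
  dfBio <- sum(nBioPerGroup - 1L)

  msGroup <- ssGroup / dfGroup
  msBio <- ssBio / dfBio
  Fstat <- msGroup / msBio
  p <- stats::pf(Fstat, dfGroup, dfBio, lower.tail = FALSE)

  cmb <- utils::combn(levels(group), 2L)
  tukey <- data.frame(contrast = apply(cmb, 2L, paste, collapse = " - "))
  tukey$diff <- mg[cmb[1L, ]] - mg[cmb[2L, ]]
  se <- sqrt(msBio / 2 * (1 / ng[cmb[1L, ]] + 1 / ng[cmb[2L, ]]))
  tukey$q <- abs(tukey$diff) / se
  tukey$p_adj <- stats::ptukey(tukey$q, nmeans = G, df = dfBio,
                               lower.tail = FALSE)
  rownames(tukey) <- NULL

  list(F = Fstat, p = p, dfGroup = dfGroup, dfBio = dfBio,
       msGroup = msGroup, msBio = msBio,
       ssGroup = ssGroup, ssBio = ssBio,
       groupMeans = mg, tukey = tukey)
}

#' Labeling-efficiency estimate from colocalization fractions
#'
#' Summarizes per-replicate percentages of bait spots colocalized with dye
#' spots for stained samples, alongside the unstained-control rate. The
#' control is reported, not subtracted; a control exceeding the stained
#' estimate is flagged as implausible.
#'
#' @param stained Numeric vector of per-replicate colocalized percentages
#'   (0-100) from stained samples.
#' @param control Same for the unstained negative control.
#' @return List with `estimate`, `sem`, `controlRate`, `controlSem`, and
#'   `flag` (TRUE when control > estimate).
#' @export
labelingEfficiency <- function(stained, control = numeric(0)) {
  est <- mean(stained)
  sem <- if (length(stained) > 1L)
    stats::sd(stained) / sqrt(length(stained)) else NA_real_
  ctrl <- if (length(control)) mean(control) else NA_real_
  ctrlSem <- if (length(control) > 1L)
    stats::sd(control) / sqrt(length(control)) else NA_real_
  flag <- isTRUE(!is.na(ctrl) && ctrl > est)
  if (flag)
    warning("control colocalization exceeds the stained estimate")
  list(estimate = est, sem = sem, controlRate = ctrl, controlSem = ctrlSem,
       flag = flag)
}

## ---------------------------------------------------------------------------
## Binomial-thinning forward model and its inverse
## ---------------------------------------------------------------------------

checkDist <- function(d) {
  if (is.null(names(d)) || anyNA(suppressWarnings(as.integer(names(d)))))
    stop("distribution must be named by non-negative copy numbers")
  if (any(d < -1e-12) || abs(sum(d) - 1) > 1e-6)
    stop("distribution entries must be non-negative and sum to 1")
}

#' Expected observed step-count distribution under incomplete labeling
#'
#' Forward model of dye-labeling loss: a complex with `n` true copies shows
#' `k` labeled fluorophores with Binomial(n, p) probability, so the observed
#' step-count distribution is the binomial mixture of the true copy-number
#' distribution. This quantifies how a ~40% labeling efficiency makes the
#' measured stoichiometry an underestimate of the true one.
#'
#' @param trueDist Named probability vector over true copy numbers.
#' @param pLabel Labeling probability in \[0, 1\].
#' @return Named probability vector over observed labeled counts 0..max.
#' @examples
#' expectedObservedClasses(c("2" = 1), 0.4)
#' @export
expectedObservedClasses <- function(trueDist, pLabel) {
  checkDist(trueDist)
  if (pLabel < 0 || pLabel > 1) stop("pLabel must be in [0, 1]")
  ns <- as.integer(names(trueDist))
  K <- max(ns)
  obs <- numeric(K + 1L)
  for (i in seq_along(ns))
    obs[0:ns[i] + 1L] <- obs[0:ns[i] + 1L] +
      trueDist[i] * stats::dbinom(0:ns[i], ns[i], pLabel)
  names(obs) <- 0:K
  obs
}

#' Estimate the true copy-number distribution from observed step counts
#'
#' Inverts the binomial-thinning forward model by non-negative least
#' squares on the probability simplex: finds the true distribution over
#' copies 0..`maxCopies` whose forward image best matches the observed
#' step-count distribution, then renormalizes. With `pLabel > 0` the
#' forward operator is lower-triangular with positive diagonal, so exact
#' observed inputs are recovered exactly (up to solver tolerance).
#'
#' @param observed Named probability vector over observed labeled counts.
#' @param pLabel Labeling probability (> 0; at 0 the true distribution is
#'   unidentifiable).
#' @param maxCopies Largest true copy number allowed.
#' @return Named probability vector over true copies 0..`maxCopies`.
#' @examples
#' obs <- expectedObservedClasses(c("1" = 0.6, "3" = 0.4), 0.4)
#' invertTrueDistribution(obs, 0.4, maxCopies = 3)
#' @export
invertTrueDistribution <- function(observed, pLabel, maxCopies = 6L) {
  checkDist(observed)
  if (pLabel <= 0)
    stop("unidentifiable: pLabel must be > 0 to invert the thinning model")
  ks <- as.integer(names(observed))
  if (any(observed[ks > maxCopies] > 1e-12))
    stop("infeasible input: observed mass above maxCopies")
  kMax <- maxCopies
  b <- numeric(kMax + 1L)
  b[ks + 1L] <- observed
  M <- outer(0:kMax, 0:kMax, function(k, n) stats::dbinom(k, n, pLabel))
  fit <- pracma::lsqnonneg(M, b)
  est <- fit$x
  if (sum(est) <= 0) stop("inversion failed: all-zero solution")
  est <- est / sum(est)
  resid <- sqrt(sum((M %*% est - b)^2))
  if (resid > 1e-4)
    warning(sprintf("forward model reproduces observed only to %.2e", resid))
  names(est) <- 0:kMax
  est
}
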