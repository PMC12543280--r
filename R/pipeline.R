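#' Classify a two-channel trace set and build pair records
#'
#' Runs the per-channel analysis steps on colocalized trace pairs: Z-score
#' normalize each channel's raw traces, classify them with the trained green
#' and far-red networks, and join the class calls by spot so each complex
#' contributes one pair record. Zero-variance traces cannot be normalized
#' and are classed `rejected` without consulting the network. Spots lacking
#' a green trace (no green fluorophore detected) never form a pair and are
#' dropped.
#'
#' @param traces A [TraceSet] with an `intensity` assay containing both
#'   channels (as produced by [simulateExperiment()], or assembled from
#'   extraction).
#' @param greenModel,farredModel Trained [StepClassifier] objects.
#' @return data.frame of pair records: `spot_id`, `bio_rep`, `tech_rep`,
#'   `green_class`, `farred_class`.
#' @export
classifyPairs <- function(traces, greenModel, farredModel) {
  stopifnot(is(traces, "TraceSet"))
  one <- function(channel, model) {
    sel <- traces$channel == channel
    m <- traceMatrix(traces[, sel], "intensity")
    mu <- rowMeans(m)
    sdp <- sqrt(rowMeans((m - mu)^2))
    ok <- sdp > 0
    cls <- rep("rejected", nrow(m))
    if (any(ok)) {
      z <- (m[ok, , drop = FALSE] - mu[ok]) / sdp[ok]
      cls[ok] <- classifyTraces(model, z)$class
    }
    data.frame(spot_id = traces$spot_id[sel],
               bio_rep = traces$bio_rep[sel],
               tech_rep = traces$tech_rep[sel],
               class = cls, stringsAsFactors = FALSE)
  }
  g <- one("green", greenModel)
  f <- one("farred", farredModel)
  merged <- merge(f, g[, c("spot_id", "class")], by = "spot_id",
                  suffixes = c("_farred", "_green"))
  data.frame(spot_id = merged$spot_id, bio_rep = merged$bio_rep,
             tech_rep = merged$tech_rep,
             green_class = merged$class_green,
             farred_class = merged$class_farred,
             stringsAsFactors = FALSE)
}

#' Quantify multimeric complexes from classified pairs
#'
#' Applies the analyzable-pair filter, computes per-technical-replicate
#' class percentages and rolls them up to the biological-replicate
#' multimeric summary.
#'
#' @param pairs Pair records from [classifyPairs()] (or any data.frame with
#'   the same columns).
#' @return As [percentMultimeric()], with the replicate summary table under
#'   `$perTech`.
#' @export
quantifyPairs <- function(pairs) {
  percentMultimeric(classPercentages(filterPairs(pairs)))
}
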