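#' @include rca.R
NULL

#' Construct good/poor thresholds
#'
#' @param dscGoodMin DSC at or above which a segmentation is good
#'   (default 0.7; the interval \[0.7, 1.0\] is good).
#' @param msdGoodMax MSD in mm at or below which a segmentation is good
#'   (default 2.0; the interval \[0, 2.0\] mm is good).
#' @return A [QualityThresholds-class].
#' @export
qualityThresholds <- function(dscGoodMin = 0.7, msdGoodMax = 2.0)
  new("QualityThresholds", dscGoodMin = dscGoodMin, msdGoodMax = msdGoodMax)

#' Classify a metric value as good or poor
#'
#' DSC values at or above \code{dscGoodMin} are good; MSD values at or
#' below \code{msdGoodMax} mm are good; undefined (\code{NA}) values are
#' conservatively poor — an unassessable case is never passed.
#'
#' @param value Numeric vector of metric values (\code{NA} allowed).
#' @param metric \code{"dsc"} or \code{"msd"}.
#' @param thresholds A [QualityThresholds-class].
#' @return Character vector of \code{"good"} / \code{"poor"}.
#' @export
classifyValue <- function(value, metric = c("dsc", "msd"),
                          thresholds = qualityThresholds()) {
  metric <- match.arg(metric)
  good <- switch(metric,
                 dsc = value >= thresholds@dscGoodMin,
                 msd = value <= thresholds@msdGoodMax)
  out <- ifelse(is.na(good), "poor", ifelse(good, "good", "poor"))
  as.character(out)
}

#' Confusion statistics from paired good/poor labels
#'
#' Positive class = good segmentation: TP counts cases predicted good that
#' are really good, FP cases predicted good that are really poor.
#'
#' @param predicted,real Character vectors of \code{"good"}/\code{"poor"}
#'   of equal length (at least 1).
#' @return A [ConfusionStats-class].
#' @export
confusionFromLabels <- function(predicted, real) {
  if (length(predicted) != length(real))
    stop("predicted and real label vectors must have equal length")
  if (length(predicted) < 1L) stop("at least one pair is required")
  ok <- c("good", "poor")
  if (!all(predicted %in% ok) || !all(real %in% ok))
    stop("labels must be 'good' or 'poor'")
  new("ConfusionStats",
      tp = sum(predicted == "good" & real == "good"),
      fp = sum(predicted == "good" & real == "poor"),
      tn = sum(predicted == "poor" & real == "poor"),
      fn = sum(predicted == "poor" & real == "good"))
}

#' Construct ConfusionStats directly from counts
#' @param tp,fp,tn,fn Non-negative integer counts (positive = good).
#' @return A [ConfusionStats-class].
#' @export
confusionStats <- function(tp, fp, tn, fn)
  new("ConfusionStats", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn))

#' Percentage of correctly identified cases
#'
#' \code{100 * nCorrect / nTotal}, reported to one decimal place as in
#' standard benchmark reporting (e.g. 166 of 171 gives 97.1).
#'
#' @param nCorrect,nTotal Counts with \code{0 <= nCorrect <= nTotal},
#'   \code{nTotal >= 1}.
#' @return Numeric percentage rounded to one decimal.
#' @export
correctlyIdentifiedRate <- function(nCorrect, nTotal) {
  if (nTotal < 1L) stop("nTotal must be at least 1")
  if (nCorrect < 0L || nCorrect > nTotal)
    stop("nCorrect must lie in [0, nTotal]")
  round(100 * nCorrect / nTotal, 1L)
}

#' Mean absolute error between predicted and real metric values
#'
#' Pairs where either side is undefined are dropped; the number dropped is
#' attached as attribute \code{nDropped}.
#'
#' @param predicted,real Numeric vectors of equal length.
#' @return MAE in the units of the inputs.
#' @export
maePrediction <- function(predicted, real) {
  if (length(predicted) != length(real))
    stop("predicted and real must have equal length")
  ok <- !is.na(predicted) & !is.na(real)
  if (!any(ok)) stop("no pair with both values defined")
  structure(mean(abs(predicted[ok] - real[ok])),
            nDropped = sum(!ok))
}

#' Pearson correlation between predicted and real metric values
#'
#' @param predicted,real Numeric vectors; at least three defined pairs with
#'   non-zero variance on both sides.
#' @return List with \code{r} and two-sided \code{p}.
#' @export
pearsonR <- function(predicted, real) {
  ok <- !is.na(predicted) & !is.na(real)
  if (sum(ok) < 3L) stop("at least three defined pairs are required")
  x <- predicted[ok]; y <- real[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the inputs")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Spearman rank correlation (average ranks for ties)
#'
#' Used to compare continuous RCA predictions against ordinal manual QC
#' scores.
#'
#' @param predicted Numeric vector.
#' @param scores Numeric or integer vector (ordinal scores allowed).
#' @return Spearman's rho.
#' @export
spearmanRho <- function(predicted, scores) {
  ok <- !is.na(predicted) & !is.na(scores)
  if (sum(ok) < 3L) stop("at least three defined pairs are required")
  x <- predicted[ok]; y <- scores[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  unname(ct$estimate)
}

#' Prediction error profiled by real quality
#'
#' Bins the absolute prediction errors by the real metric value, exposing
#' how the error grows as the real quality worsens.
#'
#' @param predicted,real Numeric vectors of equal length.
#' @param breaks Bin edges passed to [cut()] (values outside are dropped).
#' @return Data frame with \code{bin}, \code{n}, \code{mae} (\code{NA} for
#'   empty bins).
#' @export
errorVsQualityProfile <- function(predicted, real,
                                  breaks = seq(0, 1, by = 0.2)) {
  if (length(predicted) != length(real))
    stop("predicted and real must have equal length")
  bin <- cut(real, breaks = breaks, include.lowest = TRUE)
  err <- abs(predicted - real)
  out <- data.frame(bin = levels(bin), n = 0L, mae = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    sel <- which(!is.na(bin) & bin == levels(bin)[i] & !is.na(err))
    out$n[i] <- length(sel)
    if (length(sel)) out$mae[i] <- mean(err[sel])
  }
  out
}

.predictedWH <- function(result, metric = "dsc") {
  p <- result@predicted
  p[[metric]][p$class == "WH"]
}

.realWHLabels <- function(tests, spec, thresholds, metric = "dsc") {
  vapply(tests, function(tc) {
    if (is.null(tc@gtLabels)) return(NA_character_)
    real <- evaluatePair(tc@predictedLabels, tc@gtLabels, spec)
    classifyValue(real[[metric]][real$class == "WH"], metric, thresholds)
  }, character(1))
}

#' Effect of reference-set size on RCA classification accuracy
#'
#' For every (size, run) pair a random subset of the reference set is drawn
#' without replacement with a run-specific derived seed, RCA predictions
#' are formed from that subset, each case is classified good/poor on the
#' predicted whole-heart DSC, and the accuracy against the ground-truth
#' classification is recorded. Because the RCA prediction is a pure
#' best-over-references aggregation, the per-(reference, case) metric table
#' is computed once for the full reference set and every subset prediction
#' is aggregated from those rows — identical, by construction, to
#' re-running RCA on the subset.
#'
#' @param references List of [Atlas-class] (the full reference set).
#' @param tests List of [RcaTestCase-class] with ground truth.
#' @param sizes Integer vector of subset sizes (each <= number of
#'   references).
#' @param runs Number of random repetitions per size.
#' @param seed Integer master seed; subset draws derive per-(size, run)
#'   seeds from it.
#' @param regConfig A [RegistrationConfig-class].
#' @param spec A [ClassSpec-class].
#' @param thresholds A [QualityThresholds-class].
#' @param nested When \code{TRUE}, within a run the subsets of increasing
#'   size are nested (a single seeded permutation per run, truncated), so
#'   per-case predicted DSC is non-decreasing in size by construction.
#' @param precomputed Optionally the output of [rcaBatch()] on the full
#'   reference set (reused instead of recomputing the registrations).
#' @return List with \code{table} (size, run, accuracy), \code{summary}
#'   (per-size mean/min/max accuracy) and \code{perCase} (size, run,
#'   case_id, predicted WH DSC).
#' @export
referenceSubsetExperiment <- function(references, tests, sizes, runs = 5L,
                                      seed = 1L,
                                      regConfig = registrationConfig(),
                                      spec = defaultClassSpec(),
                                      thresholds = qualityThresholds(),
                                      nested = FALSE, precomputed = NULL) {
  refIds <- vapply(references, function(a) a@id, character(1))
  if (any(sizes > length(references)))
    stop("subset size exceeds the number of references")
  if (runs < 1L) stop("runs must be at least 1")
  batch <- if (is.null(precomputed))
    rcaBatch(tests, references, regConfig, spec) else precomputed
  realLab <- .realWHLabels(tests, spec, thresholds)
  caseIds <- vapply(tests, function(tc) tc@id, character(1))
  if (anyNA(realLab)) stop("every test case needs ground-truth labels")

  tab <- data.frame()
  perCase <- data.frame()
  for (run in seq_len(runs)) {
    if (nested) {
      set.seed(seed + 7919L * run)
      perm <- sample(refIds)
    }
    for (is in seq_along(sizes)) {
      size <- sizes[is]
      if (nested) {
        subsetIds <- perm[seq_len(size)]
      } else {
        set.seed(seed + 7919L * run + 131L * is)
        subsetIds <- sample(refIds, size)
      }
      predDsc <- vapply(caseIds, function(cid) {
        rows <- batch$results[[cid]]@perReference
        rows <- rows[rows$reference_id %in% subsetIds, , drop = FALSE]
        bestAggregate(rows, spec)$predicted |> .subsetWH()
      }, numeric(1))
      predLab <- classifyValue(predDsc, "dsc", thresholds)
      acc <- accuracy(confusionFromLabels(predLab, realLab))
      tab <- rbind(tab, data.frame(size = size, run = run, accuracy = acc))
      perCase <- rbind(perCase,
                       data.frame(size = size, run = run, case_id = caseIds,
                                  predicted_wh_dsc = unname(predDsc),
                                  stringsAsFactors = FALSE))
    }
  }
  summary <- do.call(rbind, lapply(sort(unique(tab$size)), function(s) {
    a <- tab$accuracy[tab$size == s]
    data.frame(size = s, mean = mean(a), min = min(a), max = max(a))
  }))
  list(table = tab, summary = summary, perCase = perCase)
}

.subsetWH <- function(predicted) predicted$dsc[predicted$class == "WH"]

#' Per-class evaluation summary of a validation batch
#'
#' Condenses a ground-truthed batch into one row per (class, criterion):
#' good/poor classification accuracy, TPR and FPR using either the DSC or
#' the MSD criterion, plus the mean absolute prediction error for every
#' metric. Mirrors the canonical benchmark table layout with per-class,
#' class-average (AV) and whole-heart (WH) rows.
#'
#' @param batchSummary The \code{summary} data frame of [rcaBatch()] run on
#'   cases with ground truth (columns \code{predicted_*} and \code{real_*}).
#' @param thresholds A [QualityThresholds-class].
#' @return Data frame with columns \code{class}, \code{criterion},
#'   \code{accuracy}, \code{tpr}, \code{fpr}, \code{mae_dsc},
#'   \code{mae_msd}, \code{mae_rmsd}, \code{mae_hd}.
#' @export
evaluationSummary <- function(batchSummary,
                              thresholds = qualityThresholds()) {
  need <- c("class", "predicted_dsc", "real_dsc", "predicted_msd",
            "real_msd")
  if (!all(need %in% names(batchSummary)))
    stop("batch summary must contain predicted and real metric columns")
  out <- data.frame()
  for (cl in unique(batchSummary$class)) {
    sub <- batchSummary[batchSummary$class == cl, ]
    maes <- vapply(METRIC_NAMES, function(m) {
      p <- sub[[paste0("predicted_", m)]]
      r <- sub[[paste0("real_", m)]]
      if (all(is.na(p) | is.na(r))) NA_real_
      else as.numeric(maePrediction(p, r))
    }, numeric(1))
    for (crit in c("dsc", "msd")) {
      cs <- confusionFromLabels(
        classifyValue(sub[[paste0("predicted_", crit)]], crit, thresholds),
        classifyValue(sub[[paste0("real_", crit)]], crit, thresholds))
      out <- rbind(out, data.frame(
        class = cl, criterion = crit, accuracy = accuracy(cs),
        tpr = tpr(cs), fpr = fpr(cs),
        mae_dsc = maes[["dsc"]], mae_msd = maes[["msd"]],
        mae_rmsd = maes[["rmsd"]], mae_hd = maes[["hd"]],
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
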