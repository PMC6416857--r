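#' @include registration.R metrics.R
NULL

METRIC_NAMES <- c("dsc", "msd", "rmsd", "hd")

#' Score one reference atlas against a test case
#'
#' The single-reference RCA step, run in the reversed direction: the
#' reference image (moving) is registered to the test image (fixed) via
#' centre-of-mass alignment followed by the configured deformable backend,
#' the resulting transform warps the reference labels onto the test grid
#' (the test segmentation itself is never resampled), and the warped
#' reference labels are scored against the segmentation under test with
#' [evaluatePair()]. With the \code{"identity"} backend the registration is
#' skipped entirely (no CoM step either), which makes the RCA logic exactly
#' testable.
#'
#' @param test An [RcaTestCase-class].
#' @param reference An [Atlas-class].
#' @param regConfig A [RegistrationConfig-class].
#' @param spec A [ClassSpec-class].
#' @return List with \code{referenceId}, \code{metrics} (ClassMetrics data
#'   frame), \code{transform} and \code{regWarning}.
#' @export
rcaSingleReference <- function(test, reference,
                               regConfig = registrationConfig(),
                               spec = defaultClassSpec()) {
  init <- if (regConfig@backend == "identity") identityTransform()
          else comTranslation(test@image, reference@image)
  transform <- deformableRegister(test@image, reference@image, init,
                                  regConfig)
  warped <- warpLabels(reference@labels, transform, test@image)
  metrics <- evaluatePair(warped, test@predictedLabels, spec)
  list(referenceId = reference@id, metrics = metrics, transform = transform,
       regWarning = isTRUE(transform@warning))
}

#' Aggregate per-reference metrics into the RCA prediction
#'
#' Per (class, metric) slot, independently: the maximum over references for
#' DSC and the minimum for the distance metrics, ignoring undefined entries;
#' different references may win different slots. Ties are broken by the
#' lexicographically smallest reference id. The AV row is recomputed as the
#' unweighted mean of the defined predicted atomic-class values.
#'
#' @param rows Data frame with columns \code{reference_id}, \code{class},
#'   \code{dsc}, \code{msd}, \code{rmsd}, \code{hd} (one row per reference
#'   and class).
#' @param spec A [ClassSpec-class].
#' @return List with \code{predicted} (ClassMetrics data frame) and
#'   \code{bestReference} (data frame class/metric/reference_id).
#' @export
bestAggregate <- function(rows, spec = defaultClassSpec()) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop("per-reference table must contain at least one row")
  classes <- names(spec@atomicClasses)
  predicted <- .emptyClassMetrics(classes)
  best <- data.frame(class = character(), metric = character(),
                     reference_id = character(), stringsAsFactors = FALSE)
  rows <- rows[order(rows$reference_id), , drop = FALSE]
  for (cl in c(classes, "WH")) {
    sub <- rows[rows$class == cl, , drop = FALSE]
    i <- which(predicted$class == cl)
    for (m in METRIC_NAMES) {
      v <- sub[[m]]
      ok <- !is.na(v)
      if (!any(ok)) next
      j <- if (m == "dsc") which(ok)[which.max(v[ok])]
           else which(ok)[which.min(v[ok])]
      predicted[[m]][i] <- v[j]
      best <- rbind(best, data.frame(class = cl, metric = m,
                                     reference_id = sub$reference_id[j],
                                     stringsAsFactors = FALSE))
    }
  }
  ia <- which(predicted$class == "AV")
  per <- predicted[predicted$class %in% classes, ]
  for (m in METRIC_NAMES) {
    v <- per[[m]][!is.na(per[[m]])]
    predicted[[m]][ia] <- if (length(v)) mean(v) else NA_real_
  }
  list(predicted = predicted, bestReference = best)
}

#' Predict segmentation quality for one test case by RCA
#'
#' Registers every reference atlas to the test image, warps the reference
#' labels onto the test grid, scores each against the segmentation under
#' test, and aggregates the best value per (class, metric) as the quality
#' prediction. The result is independent of the order of the reference
#' list (ties resolved by reference id).
#'
#' @param test An [RcaTestCase-class].
#' @param references List of [Atlas-class] objects (at least one).
#' @param regConfig A [RegistrationConfig-class].
#' @param spec A [ClassSpec-class].
#' @return An [RcaResult-class].
#' @export
rcaPredict <- function(test, references, regConfig = registrationConfig(),
                       spec = defaultClassSpec()) {
  if (length(references) < 1L)
    stop("at least one reference atlas is required")
  if (!any(wholeHeartMask(test@predictedLabels, spec)))
    stop("test predicted segmentation is empty over the whole-heart mask")
  warnings <- character()
  rowsList <- vector("list", length(references))
  for (r in seq_along(references)) {
    res <- tryCatch(
      rcaSingleReference(test, references[[r]], regConfig, spec),
      error = function(e) e)
    if (inherits(res, "error")) {
      warnings <- c(warnings, sprintf("reference '%s' failed: %s",
                                      references[[r]]@id,
                                      conditionMessage(res)))
      next
    }
    tab <- res$metrics
    tab$reference_id <- res$referenceId
    tab$reg_warning <- res$regWarning
    if (res$regWarning)
      warnings <- c(warnings,
                    sprintf("reference '%s': registration did not improve similarity",
                            res$referenceId))
    rowsList[[r]] <- tab
  }
  rows <- do.call(rbind, rowsList[!vapply(rowsList, is.null, logical(1))])
  classes <- names(spec@atomicClasses)
  if (is.null(rows) || nrow(rows) == 0L) {
    warnings <- c(warnings, "fatal: all references failed registration")
    return(new("RcaResult", caseId = test@id,
               perReference = data.frame(),
               predicted = .emptyClassMetrics(classes),
               bestReference = data.frame(class = character(),
                                          metric = character(),
                                          reference_id = character()),
               nReferencesUsed = 0L, warnings = warnings))
  }
  rows <- rows[, c("reference_id", "class", METRIC_NAMES, "reg_warning")]
  agg <- bestAggregate(rows, spec)
  new("RcaResult", caseId = test@id, perReference = rows,
      predicted = agg$predicted, bestReference = agg$bestReference,
      nReferencesUsed = length(unique(rows$reference_id)),
      warnings = warnings)
}

#' Run RCA over a batch of test cases
#'
#' One [RcaResult-class] per case; when a case carries ground-truth labels
#' its real metrics are also computed with [evaluatePair()]. Failures are
#' isolated per case and reported in the \code{errors} element.
#'
#' @param tests List of [RcaTestCase-class] objects.
#' @param references List of [Atlas-class] objects.
#' @param regConfig A [RegistrationConfig-class].
#' @param spec A [ClassSpec-class].
#' @param verbose Print one progress line per case.
#' @return List with \code{results} (named list of [RcaResult-class]),
#'   \code{summary} (long data frame: case_id, class, predicted and real
#'   metric columns) and \code{errors} (data frame case_id/message).
#' @export
rcaBatch <- function(tests, references, regConfig = registrationConfig(),
                     spec = defaultClassSpec(), verbose = FALSE) {
  results <- list()
  errors <- data.frame(case_id = character(), message = character(),
                       stringsAsFactors = FALSE)
  summaries <- list()
  for (tc in tests) {
    res <- tryCatch(rcaPredict(tc, references, regConfig, spec),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors <- rbind(errors,
                      data.frame(case_id = tc@id,
                                 message = conditionMessage(res),
                                 stringsAsFactors = FALSE))
      if (verbose) message(sprintf("[rcaBatch] %s: ERROR %s", tc@id,
                                   conditionMessage(res)))
      next
    }
    results[[tc@id]] <- res
    pred <- res@predicted
    names(pred)[match(METRIC_NAMES, names(pred))] <-
      paste0("predicted_", METRIC_NAMES)
    pred <- cbind(case_id = tc@id, pred, stringsAsFactors = FALSE)
    if (!is.null(tc@gtLabels)) {
      real <- evaluatePair(tc@predictedLabels, tc@gtLabels, spec)
      names(real)[match(METRIC_NAMES, names(real))] <-
        paste0("real_", METRIC_NAMES)
      pred <- merge(pred, real, by = "class", sort = FALSE)
      pred <- pred[, c("case_id", "class",
                       paste0("predicted_", METRIC_NAMES),
                       paste0("real_", METRIC_NAMES))]
    }
    summaries[[tc@id]] <- pred
    if (verbose)
      message(sprintf("[rcaBatch] %s: predicted WH DSC %.3f", tc@id,
                      pred$predicted_dsc[pred$class == "WH"]))
  }
  summary <- if (length(summaries)) do.call(rbind, summaries)
             else data.frame()
  rownames(summary) <- NULL
  list(results = results, summary = summary, errors = errors)
}
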