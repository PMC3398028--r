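#' Cell keys for drug--ADE pairs
#'
#' @param x data.frame with \code{drug} and \code{ade} columns, or a
#'   character vector already in \code{"drug|ade"} form.
#' @return character vector of cell keys.
#' @export
cellKeys <- function(x) {
  if (is.character(x)) return(x)
  paste(x$drug, x$ade, sep = "|")
}

#' Evaluable cells and planted truth of a dataset
#'
#' The evaluation universe defaults to the cells that generated at least
#' one report in the dataset (a planted signal that produced no report
#' cannot be recovered by any report-based method and is excluded from the
#' truth set); \code{minReports = 0} evaluates over all grid cells
#' instead.
#'
#' @param x an [SrsExperiment].
#' @param minReports minimum cell count to enter the universe.
#' @return \code{evaluableCells}: keys of evaluable cells;
#'   \code{trueSignalCells}: keys of planted signals within the universe.
#' @export
evaluableCells <- function(x, minReports = 1L) {
  tr <- signalTruth(x)
  keep <- as.vector(counts(x)) >= minReports
  cellKeys(tr[keep, ])
}

#' @rdname evaluableCells
#' @export
trueSignalCells <- function(x, minReports = 1L) {
  tr <- signalTruth(x)
  keep <- tr$isSignal & as.vector(counts(x)) >= minReports
  cellKeys(tr[keep, ])
}

#' Confusion summary of detections against planted truth
#'
#' Counts true/false positives and negatives over the evaluable cell
#' universe and derives sensitivity \eqn{tp/(tp+fn)}, specificity
#' \eqn{tn/(tn+fp)} and Youden's index (sensitivity + specificity - 1).
#' Rates are proportions in [0, 1]; an empty truth set yields
#' \code{NA} sensitivity (undefined).
#'
#' @param detected detected cells (keys or drug/ade data.frame), a subset
#'   of \code{evaluable}.
#' @param truth planted true-signal cells; intersected with
#'   \code{evaluable}.
#' @param evaluable the cell universe.
#' @return one-row data.frame: \code{tp}, \code{fp}, \code{tn}, \code{fn},
#'   \code{sensitivity}, \code{specificity}, \code{youden}.
#' @examples
#' confusionSummary(c("D1|A1"), c("D1|A1", "D1|A2"),
#'                  c("D1|A1", "D1|A2", "D2|A1", "D2|A2"))
#' @export
confusionSummary <- function(detected, truth, evaluable) {
  det <- unique(cellKeys(detected))
  tru <- unique(cellKeys(truth))
  ev <- unique(cellKeys(evaluable))
  if (!all(det %in% ev))
    stop("detected cells must be a subset of the evaluable universe",
         call. = FALSE)
  tru <- intersect(tru, ev)
  tp <- length(intersect(det, tru))
  fp <- length(det) - tp
  fn <- length(tru) - tp
  tn <- length(ev) - tp - fp - fn
  sens <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  spec <- if (tn + fp == 0L) NA_real_ else tn / (tn + fp)
  data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
             sensitivity = sens, specificity = spec,
             youden = sens + spec - 1)
}

# one pass over a batch computing everything the evaluation tables need:
# mined rule lifts, per-method flag counts, truth bookkeeping, and pooled
# ROC scores for cells with a >= minCount
.batchEvaluation <- function(batch, liftGrid, params = miningParams(),
                             priors = bcpnnPriors(),
                             variant = "exact", minCount = 3L,
                             minReports = 1L,
                             methods = c("PRR", "ROR", "BCPNN", "MHRA"),
                             rocMethods = c("AR", "BCPNN", "MHRA")) {
  liftGrid <- sort(unique(liftGrid))
  mineParams <- miningParams(params@minSupportCount,
                             min(liftGrid, params@minLift),
                             params@minConfidence, params@maxRuleItems,
                             params@strict)
  cmp <- if (params@strict) `>` else `>=`
  nB <- length(batch)
  total <- numeric(nB)
  nTruth <- numeric(nB)
  sweepSens <- matrix(NA_real_, nB, length(liftGrid))
  sweepSpec <- matrix(NA_real_, nB, length(liftGrid))
  arDetected <- integer(nB)
  flags <- matrix(0L, nB, length(methods), dimnames = list(NULL, methods))
  rocScores <- setNames(vector("list", length(rocMethods)), rocMethods)
  rocLabels <- list()
  for (i in seq_len(nB)) {
    ds <- batch[[i]]
    total[i] <- totalReports(ds)
    ev <- evaluableCells(ds, minReports)
    tru <- trueSignalCells(ds, minReports)
    nTruth[i] <- length(tru)
    rules <- mineSignals(countsToReports(ds), mineParams)
    ruleCells <- cellKeys(rules)
    arDetected[i] <- sum(cmp(rules$lift, params@minLift))
    for (j in seq_along(liftGrid)) {
      det <- ruleCells[cmp(rules$lift, liftGrid[j])]
      cs <- confusionSummary(det, tru, ev)
      sweepSens[i, j] <- cs$sensitivity
      sweepSpec[i, j] <- cs$specificity
    }
    tab <- contingencyTables(ds)
    for (m in methods) {
      res <- switch(m, PRR = prr(tab), ROR = ror(tab),
                    BCPNN = bcpnnIc(tab, priors, variant),
                    MHRA = mhra(tab))
      flags[i, m] <- sum(res$isSignal)
    }
    keep <- tab$a >= minCount
    lab <- signalTruth(ds)$isSignal[keep]
    for (m in rocMethods)
      rocScores[[m]] <- c(rocScores[[m]],
                          rocScore(tab[keep, ], m, priors))
    rocLabels[[i]] <- lab
  }
  list(liftGrid = liftGrid, totalReports = total, nTruth = nTruth,
       sweepSens = sweepSens, sweepSpec = sweepSpec, flags = flags,
       arDetected = arDetected, rocScores = rocScores,
       rocLabels = unlist(rocLabels))
}

#' Sensitivity/specificity sweep over the minimum lift
#'
#' Mines every dataset once at the smallest lift in the grid, then
#' thresholds the mined rules at each grid value and averages the
#' per-dataset confusion rates. Sensitivity is non-increasing and
#' specificity non-decreasing in the lift threshold.
#'
#' @param batch list of [SrsExperiment] datasets (see
#'   [simulateSrsBatch()]).
#' @param liftGrid numeric vector of minimum-lift values.
#' @param params [MiningParams]; the support-count threshold and
#'   strictness apply at every grid point.
#' @param minReports evaluable-universe threshold, see [evaluableCells()].
#' @return data.frame with columns \code{minLift}, \code{sensitivity},
#'   \code{specificity}, \code{youden} (proportions averaged over
#'   datasets).
#' @examples
#' batch <- simulateSrsBatch(srsSimConfig(), 3, 7)
#' sweepMinLift(batch, c(1.0, 1.2, 1.4))
#' @export
sweepMinLift <- function(batch, liftGrid = seq(1.0, 1.6, by = 0.1),
                         params = miningParams(), minReports = 1L) {
  if (!length(liftGrid)) stop("liftGrid must be non-empty", call. = FALSE)
  be <- .batchEvaluation(batch, liftGrid, params, minReports = minReports,
                         methods = character(), rocMethods = character())
  sens <- colMeans(be$sweepSens)
  spec <- colMeans(be$sweepSpec)
  data.frame(minLift = be$liftGrid, sensitivity = sens, specificity = spec,
             youden = sens + spec - 1)
}

#' Average detection counts per method over a batch
#'
#' Applies each method's signal criterion to every dataset and reports the
#' mean and sample standard deviation (n - 1) of the number of flagged
#' drug--ADE combinations, next to the mean number of evaluable planted
#' signals.
#'
#' @inheritParams sweepMinLift
#' @param methods methods to run; \code{"AR"} uses the mining pipeline at
#'   \code{params}, the rest their standard criteria on the 2x2 tables.
#' @param priors,variant BCPNN settings, see [bcpnnIc()].
#' @return data.frame with columns \code{method}, \code{criterion},
#'   \code{meanDetected}, \code{sdDetected}, \code{meanTrueSignals},
#'   \code{sdTrueSignals}.
#' @export
meanDetections <- function(batch,
                           methods = c("AR", "PRR", "ROR", "BCPNN", "MHRA"),
                           params = miningParams(), priors = bcpnnPriors(),
                           variant = "exact", minReports = 1L) {
  disproM <- setdiff(methods, "AR")
  be <- .batchEvaluation(batch, liftGrid = params@minLift, params = params,
                         priors = priors, variant = variant,
                         minReports = minReports, methods = disproM,
                         rocMethods = character())
  nTrue <- be$nTruth
  crit <- c(
    AR = sprintf("support count >= %d and lift >= %g",
                 params@minSupportCount, params@minLift),
    PRR = "lower 95% limit of PRR > 1",
    ROR = "lower 95% limit of ROR > 1",
    BCPNN = "lower 95% limit of IC > 0",
    MHRA = "PRR >= 2 and chi2 >= 4 and a >= 3")
  rows <- lapply(methods, function(m) {
    detected <- if (m == "AR") be$arDetected else be$flags[, m]
    data.frame(method = m, criterion = unname(crit[m]),
               meanDetected = mean(detected), sdDetected = sd(detected),
               meanTrueSignals = mean(nTrue), sdTrueSignals = sd(nTrue),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Empirical ROC curve and Mann--Whitney AUC
#'
#' Ranks cells by score against binary labels. The AUC is the
#' Mann--Whitney statistic (ties counted 1/2), which equals the
#' trapezoidal area under the empirical ROC curve; the curve steps at
#' every distinct score value. Cells with \code{NA} scores are dropped
#' with a warning.
#'
#' @param scores numeric ranking scores (higher = more suspected).
#' @param labels logical (or 0/1) truth labels, same length.
#' @return A [RocCurve].
#' @examples
#' rocAuc(c(3, 2, 1), c(TRUE, TRUE, FALSE))
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  drop <- is.na(scores) | is.na(labels)
  if (any(drop)) {
    warning(sprintf("dropping %d cell(s) with undefined score or label",
                    sum(drop)))
    scores <- scores[!drop]
    labels <- labels[!drop]
  }
  nP <- as.numeric(sum(labels)) # avoid integer overflow in nP * nN
  nN <- as.numeric(sum(!labels))
  if (nP == 0 || nN == 0)
    stop("ROC needs at least one positive and one negative cell",
         call. = FALSE)
  r <- rank(scores, ties.method = "average")
  aucVal <- (sum(r[labels]) - nP * (nP + 1) / 2) / (nP * nN)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  thrEnd <- which(!duplicated(s, fromLast = TRUE)) # last index per score
  tpr <- c(0, cumsum(l)[thrEnd] / nP)
  fpr <- c(0, cumsum(!l)[thrEnd] / nN)
  new("RocCurve", fpr = fpr, tpr = tpr, auc = aucVal,
      nPos = as.integer(nP), nNeg = as.integer(nN))
}

#' @describeIn RocCurve-class the area under the curve.
#' @param x a \code{RocCurve}.
#' @export
#' @name auc
setMethod("auc", "RocCurve", function(x) x@auc)

#' ROC curve points
#'
#' @param x a [RocCurve].
#' @return data.frame with columns \code{fpr}, \code{tpr}.
#' @export
#' @name rocPoints
setMethod("rocPoints", "RocCurve", function(x) {
  data.frame(fpr = x@fpr, tpr = x@tpr)
})

#' @describeIn RocCurve-class display AUC and point count.
#' @param object a \code{RocCurve}.
#' @export
setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: AUC = %.3f (%d positives, %d negatives, %d points)\n",
              object@auc, object@nPos, object@nNeg, length(object@fpr)))
})

#' Pooled ROC curve of a method over a batch
#'
#' Pools, across all datasets, the drug--ADE cells with at least
#' \code{minCount} reports, scores each cell with the method's ranking
#' score (see [rocScore()]) and builds one empirical ROC curve against the
#' planted truth labels. Set \code{pool = FALSE} to instead average the
#' per-dataset AUCs (returned as a number).
#'
#' @inheritParams sweepMinLift
#' @param method one of \code{"AR"}, \code{"PRR"}, \code{"ROR"},
#'   \code{"BCPNN"}, \code{"MHRA"}.
#' @param minCount minimum reports \code{a} for a cell to enter the curve.
#' @param priors BCPNN priors.
#' @param pool pool cells across datasets (default) or average per-dataset
#'   AUCs.
#' @return A [RocCurve], or the mean AUC when \code{pool = FALSE}.
#' @export
pooledRoc <- function(batch, method = "AR", minCount = 3L,
                      priors = bcpnnPriors(), pool = TRUE) {
  per <- lapply(batch, function(ds) {
    tab <- contingencyTables(ds)
    keep <- tab$a >= minCount
    list(score = rocScore(tab[keep, ], method, priors),
         label = signalTruth(ds)$isSignal[keep])
  })
  if (pool) {
    rocAuc(unlist(lapply(per, `[[`, "score")),
           unlist(lapply(per, `[[`, "label")))
  } else {
    mean(vapply(per, function(p) auc(rocAuc(p$score, p$label)), numeric(1)))
  }
}
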