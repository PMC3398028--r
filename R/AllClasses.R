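#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats rpois setNames sd
#' @importFrom utils combn
NULL

#' Simulation configuration for a spontaneous reporting system grid
#'
#' An \code{SrsSimConfig} holds the full parameter grid of the Monte Carlo
#' report model: the drug/ADE grid dimensions, the stratum levels for drug
#' exposure, ADE background incidence, event severity and drug launch
#' duration, the reporting-probability table, and the planted-signal scheme
#' (fraction of cells that are true signals and their relative risks).
#'
#' Expected reports in a drug--ADE cell follow
#' \eqn{\lambda = e \times i \times RR \times pr}, where \eqn{e} is the
#' number of persons exposed to the drug, \eqn{i} the background incidence
#' of the event per exposed person, \eqn{RR} the relative risk planted in
#' the cell, and \eqn{pr} the probability that an occurring event is
#' actually reported (a function of launch duration and severity).
#'
#' @slot nDrugs,nAdes integer grid dimensions.
#' @slot exposureLevels numeric, persons exposed per drug stratum.
#' @slot incidenceLevels numeric, background incidence per ADE stratum.
#' @slot seriousFraction numeric in [0, 1], fraction of ADEs flagged serious.
#' @slot durationLevels numeric, drug launch durations in years.
#' @slot prTable data.frame with columns \code{duration}, \code{serious},
#'   \code{pr}: the reporting probability for each (duration, severity)
#'   stratum.
#' @slot signalFraction numeric in [0, 1), fraction of cells that are true
#'   signals.
#' @slot rrLevels numeric, relative risks assigned to true-signal cells.
#' @slot rrNull numeric, relative risk of non-signal cells (usually 1).
#' @slot seed integer default random seed.
#'
#' @seealso [srsSimConfig()] for the constructor with study defaults,
#'   [simulateSrs()] to draw a dataset.
#' @name SrsSimConfig-class
#' @aliases SrsSimConfig
#' @exportClass SrsSimConfig
setClass("SrsSimConfig",
  representation(
    nDrugs = "integer",
    nAdes = "integer",
    exposureLevels = "numeric",
    incidenceLevels = "numeric",
    seriousFraction = "numeric",
    durationLevels = "numeric",
    prTable = "data.frame",
    signalFraction = "numeric",
    rrLevels = "numeric",
    rrNull = "numeric",
    seed = "integer"
  )
)

setValidity("SrsSimConfig", function(object) {
  msg <- character()
  if (length(object@nDrugs) != 1L || is.na(object@nDrugs) || object@nDrugs < 1L)
    msg <- c(msg, "nDrugs must be a single positive integer")
  if (length(object@nAdes) != 1L || is.na(object@nAdes) || object@nAdes < 1L)
    msg <- c(msg, "nAdes must be a single positive integer")
  if (length(object@exposureLevels) < 1L || any(object@exposureLevels <= 0))
    msg <- c(msg, "every exposure level e must be > 0")
  if (length(object@incidenceLevels) < 1L ||
      any(object@incidenceLevels <= 0 | object@incidenceLevels >= 1))
    msg <- c(msg, "every incidence level i must lie in (0, 1)")
  if (object@seriousFraction < 0 || object@seriousFraction > 1)
    msg <- c(msg, "seriousFraction must lie in [0, 1]")
  pt <- object@prTable
  if (!all(c("duration", "serious", "pr") %in% names(pt))) {
    msg <- c(msg, "prTable needs columns duration, serious, pr")
  } else {
    if (any(pt$pr <= 0 | pt$pr > 1))
      msg <- c(msg, "every reporting probability pr must lie in (0, 1]")
    need <- expand.grid(duration = object@durationLevels,
                        serious = c(TRUE, FALSE))
    have <- paste(pt$duration, pt$serious)
    if (!all(paste(need$duration, need$serious) %in% have))
      msg <- c(msg, "prTable must cover every (duration, severity) stratum")
  }
  if (object@signalFraction < 0 || object@signalFraction >= 1)
    msg <- c(msg, "signalFraction must lie in [0, 1)")
  if (length(object@rrLevels) < 1L || any(object@rrLevels <= 0))
    msg <- c(msg, "rrLevels must be positive")
  if (length(object@rrNull) != 1L || object@rrNull <= 0)
    msg <- c(msg, "rrNull must be a single positive value")
  if (length(msg)) msg else TRUE
})

#' Collection of spontaneous reports as typed transactions
#'
#' A \code{ReportSet} stores spontaneous reports in long format: one row per
#' (report, item), where an item is either a drug or an ADE identified by a
#' code. A report is a transaction — a set of typed items with no
#' duplicates. Simulated reports carry exactly one drug and one ADE;
#' real-world reports may carry several of each.
#'
#' @slot items data.frame with columns \code{report} (integer or character
#'   id), \code{kind} (\code{"drug"} or \code{"ade"}) and \code{code}
#'   (non-empty item identifier).
#'
#' @seealso [countsToReports()], [readReports()], [contingencyTables()],
#'   [mineSignals()].
#' @name ReportSet-class
#' @aliases ReportSet
#' @exportClass ReportSet
setClass("ReportSet", representation(items = "data.frame"))

setValidity("ReportSet", function(object) {
  it <- object@items
  msg <- character()
  if (!all(c("report", "kind", "code") %in% names(it)))
    return("items needs columns report, kind, code")
  if (nrow(it) == 0L)
    msg <- c(msg, "a ReportSet must contain at least one report")
  bad <- setdiff(unique(it$kind), c("drug", "ade"))
  if (length(bad))
    msg <- c(msg, sprintf("unknown item kind(s): %s",
                          paste(bad, collapse = ", ")))
  if (any(!nzchar(as.character(it$code))))
    msg <- c(msg, "item codes must be non-empty")
  if (anyDuplicated(paste(it$report, it$kind, it$code)))
    msg <- c(msg, "duplicate items within a report are not allowed")
  if (length(msg)) msg else TRUE
})

#' Simulated spontaneous reporting system dataset
#'
#' \code{SrsExperiment} extends \linkS4class{SummarizedExperiment}: rows are
#' drugs, columns are ADEs, and three assays hold the drug--ADE grid:
#' \describe{
#'   \item{\code{counts}}{non-negative integer report counts per cell;}
#'   \item{\code{rr}}{the relative risk planted in each cell;}
#'   \item{\code{signal}}{logical, whether the cell is a planted true
#'     signal.}
#' }
#' \code{rowData} carries the drug profiles (exposure, launch duration),
#' \code{colData} the ADE profiles (incidence, severity), and
#' \code{metadata} the generating \linkS4class{SrsSimConfig} and the seed
#' used.
#'
#' @seealso [simulateSrs()], [counts()], [signalTruth()],
#'   [contingencyTables()].
#' @name SrsExperiment-class
#' @aliases SrsExperiment
#' @exportClass SrsExperiment
setClass("SrsExperiment", contains = "SummarizedExperiment")

setValidity("SrsExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("counts", "rr", "signal") %in% an))
    return("assays 'counts', 'rr' and 'signal' are required")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0) || any(cts != round(cts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (!is.logical(SummarizedExperiment::assay(object, "signal")))
    msg <- c(msg, "the signal assay must be logical")
  if (length(msg)) msg else TRUE
})

#' Empirical ROC curve with its area
#'
#' Ordered (false positive rate, true positive rate) points from (0, 0) to
#' (1, 1), together with the area under the curve. The AUC is computed as
#' the Mann--Whitney statistic (ties counted 1/2), which equals the
#' trapezoidal area under the empirical curve.
#'
#' @slot fpr,tpr numeric vectors of matching length, non-decreasing, from 0
#'   to 1.
#' @slot auc numeric in [0, 1].
#' @slot nPos,nNeg integer numbers of positive and negative cells scored.
#'
#' @seealso [rocAuc()], [pooledRoc()].
#' @name RocCurve-class
#' @aliases RocCurve
#' @exportClass RocCurve
setClass("RocCurve",
  representation(fpr = "numeric", tpr = "numeric", auc = "numeric",
                 nPos = "integer", nNeg = "integer")
)

setValidity("RocCurve", function(object) {
  msg <- character()
  if (length(object@fpr) != length(object@tpr))
    msg <- c(msg, "fpr and tpr must have equal length")
  if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
    msg <- c(msg, "ROC points must be monotone non-decreasing")
  eps <- 1e-12
  if (length(object@fpr) &&
      (abs(object@fpr[1L]) > eps || abs(object@tpr[1L]) > eps ||
       abs(object@fpr[length(object@fpr)] - 1) > eps ||
       abs(object@tpr[length(object@tpr)] - 1) > eps))
    msg <- c(msg, "ROC points must run from (0,0) to (1,1)")
  if (object@auc < -eps || object@auc > 1 + eps)
    msg <- c(msg, "auc must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Mining thresholds for association-rule signal detection
#'
#' Thresholds applied during rule generation: the minimum number of reports
#' supporting a rule (\code{minSupportCount}), the minimum lift and
#' confidence, and the maximum number of items in a retained rule. All
#' thresholds are inclusive (\eqn{\ge}) by default; \code{strict = TRUE}
#' switches the lift/confidence comparisons to strict inequality.
#'
#' @slot minSupportCount integer \eqn{\ge 1}.
#' @slot minLift numeric \eqn{\ge 0}.
#' @slot minConfidence numeric in [0, 1].
#' @slot maxRuleItems integer \eqn{\ge 2}.
#' @slot strict logical; use strict inequalities for lift/confidence.
#'
#' @seealso [miningParams()], [mineSignals()].
#' @name MiningParams-class
#' @aliases MiningParams
#' @exportClass MiningParams
setClass("MiningParams",
  representation(minSupportCount = "integer", minLift = "numeric",
                 minConfidence = "numeric", maxRuleItems = "integer",
                 strict = "logical")
)

setValidity("MiningParams", function(object) {
  msg <- character()
  if (object@minSupportCount < 1L)
    msg <- c(msg, "minSupportCount must be >= 1")
  if (object@minLift < 0) msg <- c(msg, "minLift must be >= 0")
  if (object@minConfidence < 0 || object@minConfidence > 1)
    msg <- c(msg, "minConfidence must lie in [0, 1]")
  if (object@maxRuleItems < 2L) msg <- c(msg, "maxRuleItems must be >= 2")
  if (length(msg)) msg else TRUE
})
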