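#' @importFrom BiocGenerics counts
NULL

#' Per-pair 2x2 contingency tables
#'
#' Build, for every drug--ADE pair, the classical pharmacovigilance 2x2
#' table over reports: \code{a} reports mentioning both the drug and the
#' ADE, \code{b} the drug with other ADEs, \code{c} other drugs with the
#' ADE, and \code{d} neither; \code{n = a + b + c + d} is the total number
#' of reports and is identical for every pair.
#'
#' @param x a drug-by-ADE count matrix, an [SrsExperiment], or a
#'   [ReportSet]. On a \code{ReportSet} with multi-item reports, a report
#'   containing the drug and at least one occurrence of the ADE counts once
#'   in \code{a} (report-level counting).
#' @return A data.frame with one row per drug--ADE pair and columns
#'   \code{drug}, \code{ade}, \code{a}, \code{b}, \code{c}, \code{d},
#'   \code{n}. If the input holds no reports at all the result carries the
#'   attribute \code{degenerate = TRUE}.
#' @examples
#' m <- matrix(c(10, 5, 5, 80), 2, 2, byrow = TRUE,
#'             dimnames = list(c("D1", "D2"), c("A1", "A2")))
#' contingencyTables(m)
#' @export
setGeneric("contingencyTables",
           function(x) standardGeneric("contingencyTables"))

#' @rdname signalTruth
#' @export
setGeneric("signalTruth", function(x) standardGeneric("signalTruth"))

#' @rdname drugProfiles
#' @export
setGeneric("drugProfiles", function(x) standardGeneric("drugProfiles"))

#' @rdname drugProfiles
#' @export
setGeneric("adeProfiles", function(x) standardGeneric("adeProfiles"))

#' @rdname totalReports
#' @export
setGeneric("totalReports", function(x) standardGeneric("totalReports"))

#' @rdname nReports
#' @export
setGeneric("nReports", function(x) standardGeneric("nReports"))

#' @rdname reportItems
#' @export
setGeneric("reportItems", function(x) standardGeneric("reportItems"))

#' @rdname auc
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname rocPoints
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))
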