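#' Construct a ReportSet from long-format items
#'
#' @param items data.frame with columns \code{report}, \code{kind}
#'   (\code{"drug"}/\code{"ade"}), \code{code}.
#' @param canonicalize sort items by (kind, code) within report and
#'   reports by id, so equal report collections compare identical.
#' @return A validated [ReportSet].
#' @export
reportSet <- function(items, canonicalize = TRUE) {
  items <- as.data.frame(items)[, c("report", "kind", "code")]
  items$kind <- as.character(items$kind)
  items$code <- as.character(items$code)
  if (canonicalize) {
    items <- items[order(items$report, items$kind, items$code), ]
    rownames(items) <- NULL
  }
  new("ReportSet", items = items)
}

#' Number of reports in a ReportSet
#'
#' @param x a [ReportSet].
#' @return integer count of distinct reports (transactions).
#' @export
#' @name nReports
setMethod("nReports", "ReportSet", function(x) {
  length(unique(x@items$report))
})

#' Long-format items of a ReportSet
#'
#' @param x a [ReportSet].
#' @return data.frame with columns \code{report}, \code{kind}, \code{code}.
#' @export
#' @name reportItems
setMethod("reportItems", "ReportSet", function(x) x@items)

#' @describeIn ReportSet-class number of transactions.
#' @param x a \code{ReportSet}.
#' @export
setMethod("length", "ReportSet", function(x) nReports(x))

#' @describeIn ReportSet-class display report and item counts.
#' @param object a \code{ReportSet}.
#' @export
setMethod("show", "ReportSet", function(object) {
  it <- object@items
  cat(sprintf("ReportSet: %d reports, %d items (%d drug codes, %d ADE codes)\n",
              nReports(object), nrow(it),
              length(unique(it$code[it$kind == "drug"])),
              length(unique(it$code[it$kind == "ade"]))))
})

#' Expand a count matrix into individual reports
#'
#' Each drug--ADE cell with count \eqn{k} is split into \eqn{k} reports,
#' each containing exactly one drug item and one ADE item, so the resulting
#' [ReportSet] has as many transactions as the dataset has reports.
#'
#' @param x an [SrsExperiment] or a drug-by-ADE count matrix with dimnames.
#' @return A [ReportSet]; report ids run from 1 in column-major cell order.
#' @examples
#' m <- matrix(c(3, 0, 0, 0), 2, 2,
#'             dimnames = list(c("D1", "D2"), c("A1", "A2")))
#' countsToReports(m)
#' @export
countsToReports <- function(x) {
  cts <- if (is(x, "SrsExperiment")) counts(x) else x
  if (is.null(dimnames(cts)))
    dimnames(cts) <- list(sprintf("D%02d", seq_len(nrow(cts))),
                          sprintf("A%02d", seq_len(ncol(cts))))
  k <- as.vector(cts)
  if (sum(k) == 0L)
    stop("cannot build reports from an all-zero count matrix", call. = FALSE)
  drug <- rep(rep(rownames(cts), ncol(cts)), k)
  ade <- rep(rep(colnames(cts), each = nrow(cts)), k)
  id <- seq_along(drug)
  items <- data.frame(
    report = rep(id, 2L),
    kind = rep(c("drug", "ade"), each = length(id)),
    code = c(drug, ade),
    stringsAsFactors = FALSE)
  reportSet(items)
}

#' Rebuild the count matrix from single-pair reports
#'
#' Inverse of [countsToReports()] for report sets in which every
#' transaction holds exactly one drug and one ADE.
#'
#' @param reports a [ReportSet] of single drug--ADE pair transactions.
#' @param drugs,ades optional code vectors fixing the matrix dimensions and
#'   order; defaults to the sorted codes observed.
#' @return integer drug-by-ADE count matrix.
#' @export
reportsToCounts <- function(reports, drugs = NULL, ades = NULL) {
  it <- reportItems(reports)
  wide <- .pairReports(it)
  if (is.null(wide))
    stop("reportsToCounts needs exactly one drug and one ADE per report",
         call. = FALSE)
  if (is.null(drugs)) drugs <- sort(unique(wide$drug))
  if (is.null(ades)) ades <- sort(unique(wide$ade))
  tab <- table(factor(wide$drug, levels = drugs),
               factor(wide$ade, levels = ades))
  matrix(as.integer(tab), nrow = length(drugs),
         dimnames = list(drugs, ades))
}

# reshape long items into one row per report (drug, ade); NULL when any
# report is not a single drug-ADE pair
.pairReports <- function(items) {
  dt <- data.table::as.data.table(items)
  kind <- code <- report <- NULL # appease R CMD check
  wide <- dt[, list(
    nd = sum(kind == "drug"), na = sum(kind == "ade"),
    drug = code[kind == "drug"][1L], ade = code[kind == "ade"][1L]),
    by = report]
  if (any(wide$nd != 1L) || any(wide$na != 1L)) return(NULL)
  as.data.frame(wide[, list(report, drug, ade)])
}

#' Read spontaneous reports from a delimited file
#'
#' Expects a delimited text file (gzip accepted) with a header and columns
#' \code{report_id}, \code{item_kind}, \code{item_code}; \code{item_kind}
#' must be \code{"drug"} or \code{"ade"}. Duplicate (report, item) rows are
#' collapsed with a warning; unknown kinds, empty codes or missing columns
#' raise parse errors naming the offending lines.
#'
#' @param path file path.
#' @param sep field delimiter; \code{"auto"} lets the reader detect it.
#' @return A canonicalized [ReportSet].
#' @seealso [writeReports()]
#' @export
readReports <- function(path, sep = "auto") {
  dt <- if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    data.table::fread(text = readLines(con), sep = sep, header = TRUE,
                      colClasses = "character")
  } else {
    data.table::fread(path, sep = sep, header = TRUE,
                      colClasses = "character")
  }
  need <- c("report_id", "item_kind", "item_code")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (nrow(dt) == 0L)
    stop(sprintf("%s: no report rows", path), call. = FALSE)
  badKind <- which(!dt$item_kind %in% c("drug", "ade"))
  if (length(badKind))
    stop(sprintf("%s: unknown item kind %s at data line(s) %s", path,
                 paste(sQuote(unique(dt$item_kind[badKind])), collapse = ", "),
                 paste(utils::head(badKind, 5L), collapse = ", ")),
         call. = FALSE)
  badCode <- which(!nzchar(dt$item_code))
  if (length(badCode))
    stop(sprintf("%s: empty item code at data line(s) %s", path,
                 paste(utils::head(badCode, 5L), collapse = ", ")),
         call. = FALSE)
  key <- paste(dt$report_id, dt$item_kind, dt$item_code)
  if (anyDuplicated(key)) {
    warning(sprintf("%s: %d duplicate (report, item) row(s) collapsed",
                    path, sum(duplicated(key))))
    dt <- dt[!duplicated(key), ]
  }
  id <- dt$report_id
  idInt <- suppressWarnings(as.integer(id))
  if (!anyNA(idInt) && all(idInt == as.numeric(id))) id <- idInt
  reportSet(data.frame(report = id, kind = dt$item_kind,
                       code = dt$item_code, stringsAsFactors = FALSE))
}

#' Write spontaneous reports to a delimited file
#'
#' Writes the canonical long format (\code{report_id}, \code{item_kind},
#' \code{item_code}) so that \code{readReports(writeReports(x))} returns a
#' ReportSet equal to the canonical form of \code{x}. A \code{.gz} suffix
#' compresses transparently.
#'
#' @param reports a [ReportSet].
#' @param path output file path.
#' @param sep field delimiter (default tab).
#' @return \code{path}, invisibly.
#' @export
writeReports <- function(reports, path, sep = "\t") {
  it <- reportItems(reports)
  out <- data.frame(report_id = it$report, item_kind = it$kind,
                    item_code = it$code, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = sep)
  invisible(path)
}
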