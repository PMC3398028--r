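.tablesFromMatrix <- function(cts) {
  if (any(cts < 0)) stop("negative counts are not allowed", call. = FALSE)
  if (is.null(dimnames(cts)))
    dimnames(cts) <- list(sprintf("D%02d", seq_len(nrow(cts))),
                          sprintf("A%02d", seq_len(ncol(cts))))
  rs <- rowSums(cts)
  csum <- colSums(cts)
  n <- sum(cts)
  a <- as.vector(cts)
  b <- rep(rs, ncol(cts)) - a
  cc <- rep(csum, each = nrow(cts)) - a
  d <- n - a - b - cc
  out <- data.frame(
    drug = rep(rownames(cts), ncol(cts)),
    ade = rep(colnames(cts), each = nrow(cts)),
    a = a, b = b, c = cc, d = d, n = n,
    stringsAsFactors = FALSE)
  if (n == 0) attr(out, "degenerate") <- TRUE
  out
}

#' @rdname contingencyTables
#' @export
setMethod("contingencyTables", "matrix", function(x) .tablesFromMatrix(x))

#' @rdname contingencyTables
#' @export
setMethod("contingencyTables", "SrsExperiment", function(x) {
  .tablesFromMatrix(counts(x))
})

#' @rdname contingencyTables
#' @export
setMethod("contingencyTables", "ReportSet", function(x) {
  it <- data.table::as.data.table(reportItems(x))
  n <- nReports(x)
  kind <- code <- report <- NULL # appease R CMD check
  drugIt <- unique(it[kind == "drug", list(report, drug = code)])
  adeIt <- unique(it[kind == "ade", list(report, ade = code)])
  drugs <- sort(unique(drugIt$drug))
  ades <- sort(unique(adeIt$ade))
  drug <- ade <- NULL
  co <- merge(drugIt, adeIt, by = "report", allow.cartesian = TRUE)[
    , list(a = .N), by = list(drug, ade)]
  nDrug <- drugIt[, list(nd = .N), by = drug]
  nAde <- adeIt[, list(na = .N), by = ade]
  grid <- data.table::CJ(drug = drugs, ade = ades)
  grid <- merge(grid, co, by = c("drug", "ade"), all.x = TRUE)
  grid <- merge(grid, nDrug, by = "drug", all.x = TRUE)
  grid <- merge(grid, nAde, by = "ade", all.x = TRUE)
  grid$a[is.na(grid$a)] <- 0L
  out <- data.frame(
    drug = grid$drug, ade = grid$ade, a = grid$a,
    b = grid$nd - grid$a, c = grid$na - grid$a,
    stringsAsFactors = FALSE)
  out$d <- n - out$a - out$b - out$c
  out$n <- n
  # column-major cell order (drugs fastest), matching the matrix method
  out <- out[order(match(out$ade, ades), match(out$drug, drugs)), ]
  rownames(out) <- NULL
  out
})

#' Write per-pair contingency tables to a TSV file
#'
#' @param tables data.frame from [contingencyTables()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeContingencyTables <- function(tables, path) {
  data.table::fwrite(tables[, c("drug", "ade", "a", "b", "c", "d")],
                     path, sep = "\t")
  invisible(path)
}
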