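#' Construct mining thresholds
#'
#' Defaults follow the study criteria for suspected drug--ADE rules:
#' support count \eqn{\ge} 3 and lift \eqn{\ge} 1.2, no confidence
#' threshold (confidence penalizes rare but strongly associated events),
#' and rules pruned to 2 items (one drug, one ADE).
#'
#' @param minSupportCount minimum number of reports supporting a rule.
#' @param minLift minimum lift.
#' @param minConfidence minimum confidence, in [0, 1].
#' @param maxRuleItems maximum total items in a retained rule.
#' @param strict use strict (>) instead of inclusive (>=) comparisons for
#'   lift and confidence.
#' @return A validated [MiningParams].
#' @export
miningParams <- function(minSupportCount = 3L, minLift = 1.2,
                         minConfidence = 0, maxRuleItems = 2L,
                         strict = FALSE) {
  new("MiningParams", minSupportCount = as.integer(minSupportCount),
      minLift = as.numeric(minLift), minConfidence = as.numeric(minConfidence),
      maxRuleItems = as.integer(maxRuleItems), strict = isTRUE(strict))
}

#' @describeIn MiningParams-class display thresholds.
#' @param object a \code{MiningParams}.
#' @export
setMethod("show", "MiningParams", function(object) {
  op <- if (object@strict) ">" else ">="
  cat(sprintf(
    "MiningParams: support count >= %d, lift %s %g, confidence %s %g, <= %d items\n",
    object@minSupportCount, op, object@minLift, op, object@minConfidence,
    object@maxRuleItems))
})

.itemLabel <- function(kind, code) paste(kind, code, sep = ":")
.itemKind <- function(label) sub(":.*$", "", label)
.itemCode <- function(label) sub("^[^:]*:", "", label)

#' Frequent itemsets of a report collection
#'
#' Enumerates every itemset (of any size \eqn{\ge} 1) contained in at least
#' \code{minSupportCount} reports, with its exact transaction count.
#' Counting is done over the observed transactions restricted to frequent
#' single items (an itemset containing an infrequent item cannot itself be
#' frequent), so the result satisfies downward closure: every subset of a
#' returned itemset is returned.
#'
#' @param reports a [ReportSet].
#' @param minSupportCount minimum transaction count, \eqn{\ge} 1.
#' @return data.frame with columns \code{items} (comma-joined sorted item
#'   labels \code{kind:code}), \code{size}, \code{count} and \code{support}
#'   (= count / number of reports).
#' @examples
#' rs <- reportSet(data.frame(
#'   report = c(1, 1, 2, 2, 3, 3, 4, 4),
#'   kind = rep(c("drug", "ade"), 4),
#'   code = c("D1", "A1", "D1", "A1", "D1", "A2", "D2", "A1")))
#' frequentItemsets(rs, 2)
#' @export
frequentItemsets <- function(reports, minSupportCount = 3L) {
  stopifnot(is(reports, "ReportSet"))
  if (minSupportCount < 1L)
    stop("minSupportCount must be >= 1", call. = FALSE)
  it <- data.table::as.data.table(reportItems(reports))
  n <- nReports(reports)
  item <- report <- N <- item.x <- item.y <- NULL # appease R CMD check
  it[, item := .itemLabel(kind, code)]
  c1 <- it[, list(count = .N), by = item]
  L1 <- c1[c1$count >= minSupportCount]
  levels <- list(data.table::data.table(
    items = L1$item, size = 1L, count = L1$count))
  if (nrow(L1)) {
    cur <- it[item %in% L1$item, list(report, item)]
    # size 2 via a report-wise self join
    pr <- merge(cur, cur, by = "report", allow.cartesian = TRUE)
    pr <- pr[pr$item.x < pr$item.y][
      , list(count = .N), by = list(item.x, item.y)]
    L2 <- pr[pr$count >= minSupportCount]
    if (nrow(L2)) {
      levels <- c(levels, list(data.table::data.table(
        items = paste(L2$item.x, L2$item.y, sep = ","),
        size = 2L, count = L2$count)))
      # sizes >= 3: combinations within reports that still have >= k
      # frequent items; monotonicity stops the loop
      k <- 3L
      sizes <- cur[, list(m = .N), by = report]
      repeat {
        keep <- sizes$report[sizes$m >= k]
        if (!length(keep)) break
        sub <- cur[report %in% keep]
        lst <- split(sub$item, sub$report)
        keys <- unlist(lapply(lst, function(v)
          combn(sort(v), k, paste, collapse = ",")), use.names = FALSE)
        tab <- table(keys)
        tab <- tab[tab >= minSupportCount]
        if (!length(tab)) break
        levels <- c(levels, list(data.table::data.table(
          items = names(tab), size = k, count = as.integer(tab))))
        k <- k + 1L
      }
    }
  }
  out <- as.data.frame(data.table::rbindlist(levels))
  out$support <- out$count / n
  out[order(out$size, -out$count, out$items), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

# non-empty proper subsets of indices 1..s, as a list of index vectors
.properSubsets <- function(s) {
  unlist(lapply(seq_len(s - 1L), function(k)
    combn(s, k, simplify = FALSE)), recursive = FALSE)
}

#' Generate association rules from frequent itemsets
#'
#' Splits every frequent itemset of size \eqn{\ge} 2 into all
#' antecedent/consequent partitions A -> B and keeps the rules whose
#' support count, confidence and lift meet the thresholds, with
#' \eqn{support = P(A \cup B)}, \eqn{confidence = P(A \cup B) / P(A)} and
#' \eqn{lift = P(A \cup B) / (P(A) P(B))} computed exactly from the
#' transaction counts.
#'
#' @param itemsets data.frame from [frequentItemsets()] on the same
#'   reports.
#' @param reports the [ReportSet] the itemsets were mined from.
#' @param params a [MiningParams].
#' @return data.frame with columns \code{antecedent}, \code{consequent}
#'   (comma-joined item labels), \code{nItems}, \code{supportCount},
#'   \code{support}, \code{confidence}, \code{lift}.
#' @export
generateRules <- function(itemsets, reports, params = miningParams()) {
  n <- nReports(reports)
  cnt <- setNames(itemsets$count, itemsets$items)
  cmp <- if (params@strict) `>` else `>=`
  big <- itemsets[itemsets$size >= 2L &
                    itemsets$count >= params@minSupportCount, , drop = FALSE]
  # 2-item sets dominate; both their rules are formed vectorized
  two <- big[big$size == 2L, , drop = FALSE]
  rows <- list()
  if (nrow(two)) {
    sp <- strsplit(two$items, ",", fixed = TRUE)
    x <- vapply(sp, `[`, "", 1L)
    y <- vapply(sp, `[`, "", 2L)
    ant <- c(x, y)
    con <- c(y, x)
    cntS <- rep(two$count, 2L)
    cA <- unname(cnt[ant])
    cB <- unname(cnt[con])
    rows <- list(data.frame(
      antecedent = ant, consequent = con, nItems = 2L,
      supportCount = cntS, support = cntS / n,
      confidence = cntS / cA, lift = cntS * n / (cA * cB),
      stringsAsFactors = FALSE))
  }
  multi <- big[big$size > 2L, , drop = FALSE]
  for (i in seq_len(nrow(multi))) {
    v <- strsplit(multi$items[i], ",", fixed = TRUE)[[1L]]
    s <- length(v)
    splits <- .properSubsets(s)
    ant <- vapply(splits, function(ix) paste(v[ix], collapse = ","), "")
    con <- vapply(splits, function(ix) paste(v[-ix], collapse = ","), "")
    cA <- cnt[ant]
    cB <- cnt[con]
    rows <- c(rows, list(data.frame(
      antecedent = ant, consequent = con, nItems = s,
      supportCount = multi$count[i], support = multi$count[i] / n,
      confidence = unname(multi$count[i] / cA),
      lift = unname(multi$count[i] * n / (cA * cB)),
      stringsAsFactors = FALSE)))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(antecedent = character(), consequent = character(),
               nItems = integer(), supportCount = integer(),
               support = numeric(), confidence = numeric(),
               lift = numeric(), stringsAsFactors = FALSE)
  keep <- cmp(out$confidence, params@minConfidence) &
    cmp(out$lift, params@minLift)
  out <- out[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Template-match rules to the drug-to-ADE direction
#'
#' Keeps only rules whose antecedent items are all drugs, whose consequent
#' items are all ADEs, and whose total item count does not exceed
#' \code{maxRuleItems} (default 2: exactly one drug implying one ADE).
#'
#' @param rules data.frame from [generateRules()].
#' @param maxRuleItems maximum total items in a rule.
#' @return the conforming subset of \code{rules}.
#' @export
templateMatch <- function(rules, maxRuleItems = 2L) {
  allOfKind <- function(side, kind) {
    vapply(strsplit(side, ",", fixed = TRUE),
           function(v) all(.itemKind(v) == kind), logical(1L))
  }
  ok <- allOfKind(rules$antecedent, "drug") &
    allOfKind(rules$consequent, "ade")
  out <- rules[ok & rules$nItems <= maxRuleItems, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mine suspected drug-to-ADE association rules
#'
#' The full pipeline: frequent itemsets at the support-count threshold,
#' rule generation under the confidence and lift thresholds, then template
#' matching to drug-antecedent/ADE-consequent rules pruned to
#' \code{maxRuleItems} items. Deterministic given the reports.
#'
#' @param reports a [ReportSet].
#' @param params a [MiningParams].
#' @return data.frame of surviving rules, ordered by decreasing lift, with
#'   the columns of [generateRules()] plus \code{drug} and \code{ade}
#'   (item codes; NA for rules with more than one item on a side).
#' @examples
#' ds <- simulateSrs(srsSimConfig(nDrugs = 10, nAdes = 8), seed = 1)
#' rules <- mineSignals(countsToReports(ds))
#' head(rules)
#' @export
mineSignals <- function(reports, params = miningParams()) {
  fi <- frequentItemsets(reports, params@minSupportCount)
  rules <- generateRules(fi, reports, params)
  rules <- templateMatch(rules, params@maxRuleItems)
  singleA <- !grepl(",", rules$antecedent, fixed = TRUE)
  singleB <- !grepl(",", rules$consequent, fixed = TRUE)
  rules$drug <- ifelse(singleA, .itemCode(rules$antecedent), NA_character_)
  rules$ade <- ifelse(singleB, .itemCode(rules$consequent), NA_character_)
  rules <- rules[order(-rules$lift, rules$antecedent, rules$consequent), ,
                 drop = FALSE]
  rownames(rules) <- NULL
  rules
}

#' Write mined rules to a TSV file
#'
#' @param rules data.frame from [mineSignals()] or [generateRules()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRules <- function(rules, path) {
  cols <- intersect(c("antecedent", "consequent", "supportCount", "support",
                      "confidence", "lift"), names(rules))
  data.table::fwrite(rules[, cols], path, sep = "\t")
  invisible(path)
}
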