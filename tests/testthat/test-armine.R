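pairReports <- function(...) {
  pairs <- list(...)
  rows <- lapply(seq_along(pairs), function(i) {
    data.frame(report = i, kind = c("drug", "ade"),
               code = pairs[[i]], stringsAsFactors = FALSE)
  })
  reportSet(do.call(rbind, rows))
}

test_that("frequent itemsets carry exact counts at the threshold", {
  rs <- pairReports(c("D1", "A1"), c("D1", "A1"), c("D1", "A2"),
                    c("D2", "A1"))
  fi <- frequentItemsets(rs, 2)
  got <- setNames(fi$count, fi$items)
  expect_equal(got[["drug:D1"]], 3)
  expect_equal(got[["ade:A1"]], 3)
  expect_equal(got[["ade:A1,drug:D1"]], 2)
  expect_equal(nrow(fi), 3)
  # threshold above n: nothing is frequent
  expect_equal(nrow(frequentItemsets(rs, 5)), 0)
  # threshold 1: every observed itemset
  fi1 <- frequentItemsets(rs, 1)
  expect_true(all(c("drug:D2", "ade:A2,drug:D1") %in% fi1$items))
})

test_that("itemset mining agrees with brute-force enumeration and is closed downward", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    rs <- randomReportSet(25, nDrugs = 3, nAdes = 3, maxPerKind = 3)
    for (thr in c(1, 2, 4)) {
      fi <- frequentItemsets(rs, thr)
      bf <- bruteForceItemsets(reportItems(rs), thr)
      fiS <- fi[order(fi$items), c("items", "size", "count")]
      bfS <- bf[order(bf$items), ]
      rownames(fiS) <- rownames(bfS) <- NULL
      expect_equal(fiS, bfS)
      # downward closure: all subsets of every frequent set are frequent
      for (s in strsplit(fi$items, ",")) {
        if (length(s) > 1)
          for (drop in seq_along(s))
            expect_true(paste(s[-drop], collapse = ",") %in% fi$items)
      }
    }
  }
})

test_that("rule statistics match the 2x2 arithmetic on a hand example", {
  # a=10, b=5, c=5, d=80 spelled out as 100 single-pair reports
  rs <- do.call(pairReports, c(
    replicate(10, c("D1", "A1"), simplify = FALSE),
    replicate(5, c("D1", "A2"), simplify = FALSE),
    replicate(5, c("D2", "A1"), simplify = FALSE),
    replicate(80, c("D2", "A2"), simplify = FALSE)))
  rules <- mineSignals(rs, miningParams(minSupportCount = 3, minLift = 1.2))
  r <- rules[rules$drug == "D1" & rules$ade == "A1", ]
  expect_equal(r$support, 0.10, tolerance = 1e-12)
  expect_equal(r$confidence, 10 / 15, tolerance = 1e-12)
  expect_equal(r$lift, 10 * 100 / (15 * 15), tolerance = 1e-12)
  expect_equal(r$supportCount, 10)
})

test_that("independent items have lift exactly 1 and sit on the threshold boundary", {
  # 2x2 with a/n = (a+b)/n * (a+c)/n: a=4, b=4, c=4, d=4 -> lift 1
  rs <- do.call(pairReports, c(
    replicate(4, c("D1", "A1"), simplify = FALSE),
    replicate(4, c("D1", "A2"), simplify = FALSE),
    replicate(4, c("D2", "A1"), simplify = FALSE),
    replicate(4, c("D2", "A2"), simplify = FALSE)))
  fi <- frequentItemsets(rs, 3)
  all1 <- generateRules(fi, rs, miningParams(minSupportCount = 3,
                                             minLift = 0))
  expect_true(all(abs(all1$lift - 1) < 1e-12))
  # min lift 1.2 excludes lift-1 rules; inclusive threshold keeps equality
  expect_equal(nrow(generateRules(fi, rs, miningParams(3, minLift = 1.2))), 0)
  expect_gt(nrow(generateRules(fi, rs, miningParams(3, minLift = 1))), 0)
  expect_equal(nrow(generateRules(fi, rs, miningParams(3, minLift = 1,
                                                       strict = TRUE))), 0)
})

test_that("template matching keeps only drug -> ADE rules within the size cap", {
  rules <- data.frame(
    antecedent = c("drug:D1", "ade:A1", "drug:D1,drug:D2", "drug:D2",
                   "drug:D1", "ade:A2", "drug:D3", "drug:D1,ade:A1",
                   "drug:D2", "ade:A1,drug:D1"),
    consequent = c("ade:A1", "drug:D1", "ade:A1", "ade:A2",
                   "drug:D2", "ade:A1", "ade:A3", "ade:A2",
                   "ade:A1", "ade:A2"),
    nItems = c(2, 2, 3, 2, 2, 2, 2, 3, 2, 3),
    supportCount = 5, support = 0.1, confidence = 0.5, lift = 2,
    stringsAsFactors = FALSE)
  kept <- templateMatch(rules, 2)
  expect_equal(nrow(kept), 4)
  expect_true(all(grepl("^drug:", kept$antecedent)))
  expect_true(all(grepl("^ade:", kept$consequent)))
  # the 3-item drug,drug -> ade rule returns once the cap is lifted
  expect_equal(nrow(templateMatch(rules, 3)), 5)
})

test_that("mined rule metrics equal the contingency closed forms on simulated data", {
  ds <- simulateSrs(tinyConfig(), seed = 17)
  rs <- countsToReports(ds)
  rules <- mineSignals(rs, miningParams(minSupportCount = 3, minLift = 0))
  tab <- contingencyTables(ds)
  key <- paste(tab$drug, tab$ade)
  idx <- match(paste(rules$drug, rules$ade), key)
  a <- tab$a[idx]; b <- tab$b[idx]; cc <- tab$c[idx]
  n <- tab$n[idx]
  expect_equal(rules$support, a / n, tolerance = 1e-12)
  expect_equal(rules$confidence, a / (a + b), tolerance = 1e-12)
  expect_equal(rules$lift, a * n / ((a + b) * (a + cc)), tolerance = 1e-12)
})

test_that("raising the minimum lift never enlarges the rule set", {
  ds <- simulateSrs(tinyConfig(), seed = 19)
  rs <- countsToReports(ds)
  prev <- NULL
  for (ml in c(1.0, 1.2, 1.4, 1.6)) {
    cur <- mineSignals(rs, miningParams(minSupportCount = 3, minLift = ml))
    cur <- paste(cur$antecedent, cur$consequent)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("mining an empty report collection is an error", {
  expect_error(reportSet(data.frame(report = integer(), kind = character(),
                                    code = character())))
})
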