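# Independent oracles and small fixtures shared across the test files.

# a 2x2 table used throughout the hand-computed examples
handTable <- function() data.frame(a = 10, b = 5, c = 5, d = 80)

# tiny grid that still exercises every stratum
tinyConfig <- function(...) {
  srsSimConfig(nDrugs = 12, nAdes = 8, seed = 5, ...)
}

# brute-force frequent-itemset oracle: enumerate every subset of the
# observed item universe and count containing transactions by membership
bruteForceItemsets <- function(items, minCount) {
  split_ <- split(paste(items$kind, items$code, sep = ":"), items$report)
  universe <- sort(unique(unlist(split_)))
  stopifnot(length(universe) <= 14) # keep enumeration tractable
  out <- list()
  for (k in seq_along(universe)) {
    sets <- combn(universe, k, simplify = FALSE)
    for (s in sets) {
      cnt <- sum(vapply(split_, function(tr) all(s %in% tr), logical(1)))
      if (cnt >= minCount)
        out[[length(out) + 1L]] <- data.frame(
          items = paste(s, collapse = ","), size = k, count = cnt,
          stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# random multi-item report set over a small universe
randomReportSet <- function(nReports = 30, nDrugs = 4, nAdes = 4,
                            maxPerKind = 2) {
  rows <- lapply(seq_len(nReports), function(r) {
    nd <- sample(maxPerKind, 1)
    na <- sample(maxPerKind, 1)
    data.frame(
      report = r,
      kind = rep(c("drug", "ade"), c(nd, na)),
      code = c(sample(sprintf("D%d", seq_len(nDrugs)), nd),
               sample(sprintf("A%d", seq_len(nAdes)), na)),
      stringsAsFactors = FALSE)
  })
  reportSet(do.call(rbind, rows))
}

# Monte Carlo oracle for the BCPNN posterior moments: sample the three
# independent Beta posteriors and take moments of log2(p11/(p1 p2))
bcpnnMcOracle <- function(a, b, c, d, nSamp = 4e5,
                          priors = bcpnnPriors()) {
  n <- a + b + c + d
  c1 <- a + b
  c2 <- a + c
  gamma <- priors$gamma11 * (n + priors$alpha) * (n + priors$beta) /
    ((c1 + priors$alpha1) * (c2 + priors$beta1))
  p11 <- rbeta(nSamp, priors$gamma11 + a, gamma - priors$gamma11 + n - a)
  p1 <- rbeta(nSamp, priors$alpha1 + c1, priors$alpha - priors$alpha1 + n - c1)
  p2 <- rbeta(nSamp, priors$beta1 + c2, priors$beta - priors$beta1 + n - c2)
  ic <- log2(p11 / (p1 * p2))
  list(e = mean(ic), v = var(ic))
}

# trapezoidal area under an ROC curve's points
trapezoidArea <- function(curve) {
  p <- rocPoints(curve)
  sum(diff(p$fpr) * (head(p$tpr, -1) + tail(p$tpr, -1)) / 2)
}
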