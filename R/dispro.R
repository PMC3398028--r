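Z95 <- 1.96 # conventional two-sided 95% multiplier

.asTables <- function(tab) {
  if (is.matrix(tab)) tab <- contingencyTables(tab)
  stopifnot(all(c("a", "b", "c", "d") %in% names(tab)))
  # double precision: products of margins overflow integer range
  for (col in c("a", "b", "c", "d")) tab[[col]] <- as.numeric(tab[[col]])
  tab$n <- tab$a + tab$b + tab$c + tab$d
  tab
}

.resultFrame <- function(tab, method, estimate, lower95, isSignal, defined,
                         chi2 = NA_real_) {
  out <- data.frame(method = method, estimate = estimate, lower95 = lower95,
                    chi2 = chi2, isSignal = isSignal & defined,
                    defined = defined, stringsAsFactors = FALSE)
  idc <- intersect(c("drug", "ade", "a", "b", "c", "d", "n"), names(tab))
  cbind(tab[idc], out)
}

#' Proportional reporting ratio
#'
#' \eqn{PRR = [a/(a+b)] / [c/(c+d)]} with a log-scale Wald 95\% interval,
#' \eqn{LI_{95} = \exp(\ln PRR - 1.96 \sqrt{1/a - 1/(a+b) + 1/c -
#' 1/(c+d)})}. A pair is flagged when the lower limit exceeds 1. The
#' statistic is undefined (\code{defined = FALSE}, never a signal) when
#' \code{a = 0}, \code{c = 0} or a margin vanishes; no continuity
#' correction is applied.
#'
#' @param tab data.frame of contingency tables (columns \code{a},
#'   \code{b}, \code{c}, \code{d}; see [contingencyTables()]) or a count
#'   matrix.
#' @return data.frame with one row per pair: the id/count columns of
#'   \code{tab} plus \code{method}, \code{estimate}, \code{lower95},
#'   \code{chi2} (NA here), \code{isSignal}, \code{defined}.
#' @examples
#' prr(data.frame(a = 10, b = 5, c = 5, d = 80))
#' @export
prr <- function(tab) {
  tab <- .asTables(tab)
  a <- tab$a; b <- tab$b; cc <- tab$c; d <- tab$d
  defined <- a > 0 & cc > 0 & (a + b) > 0 & (cc + d) > 0
  est <- ifelse(defined, (a / (a + b)) / (cc / (cc + d)), NA_real_)
  se <- ifelse(defined,
               sqrt(1 / a - 1 / (a + b) + 1 / cc - 1 / (cc + d)), NA_real_)
  lo <- exp(log(est) - Z95 * se)
  .resultFrame(tab, "PRR", est, lo, lo > 1, defined)
}

#' Reporting odds ratio
#'
#' \eqn{ROR = ad / bc} with log-scale Wald 95\% interval
#' \eqn{\exp(\ln ROR - 1.96\sqrt{1/a + 1/b + 1/c + 1/d})}; flagged when the
#' lower limit exceeds 1; undefined when any cell is zero.
#'
#' @inheritParams prr
#' @inherit prr return
#' @examples
#' ror(data.frame(a = 10, b = 5, c = 5, d = 80))
#' @export
ror <- function(tab) {
  tab <- .asTables(tab)
  a <- tab$a; b <- tab$b; cc <- tab$c; d <- tab$d
  defined <- a > 0 & b > 0 & cc > 0 & d > 0
  est <- ifelse(defined, (a * d) / (b * cc), NA_real_)
  se <- ifelse(defined, sqrt(1 / a + 1 / b + 1 / cc + 1 / d), NA_real_)
  lo <- exp(log(est) - Z95 * se)
  .resultFrame(tab, "ROR", est, lo, lo > 1, defined)
}

#' BCPNN prior hyperparameters
#'
#' The Beta pseudo-counts of the Bayesian information-component model: the
#' two marginal proportions have priors Beta(\code{alpha1}, \code{alpha} -
#' \code{alpha1}) and Beta(\code{beta1}, \code{beta} - \code{beta1}); the
#' joint proportion has prior Beta(\code{gamma11}, \code{gamma} -
#' \code{gamma11}) with \code{gamma} calibrated to the data so that an
#' exactly independent table has IC = 0:
#' \eqn{\gamma = \gamma_{11} (n+\alpha)(n+\beta) /
#' ((a+b+\alpha_1)(a+c+\beta_1))}. Defaults are the standard uninformative
#' choice \eqn{\alpha_1 = \beta_1 = \gamma_{11} = 1},
#' \eqn{\alpha = \beta = 2}.
#'
#' @param alpha1,alpha,beta1,beta,gamma11 positive pseudo-counts.
#' @return named list of hyperparameters.
#' @export
bcpnnPriors <- function(alpha1 = 1, alpha = 2, beta1 = 1, beta = 2,
                        gamma11 = 1) {
  p <- list(alpha1 = alpha1, alpha = alpha, beta1 = beta1, beta = beta,
            gamma11 = gamma11)
  if (any(unlist(p) <= 0)) stop("all priors must be positive", call. = FALSE)
  p
}

#' Bayesian information component (BCPNN)
#'
#' The information component \eqn{IC = \log_2 [P(xy) / (P(x) P(y))]} under
#' independent Beta posteriors for the joint and the two marginal reporting
#' proportions (priors from [bcpnnPriors()]). The default
#' \code{variant = "exact"} uses the exact closed-form posterior moments,
#' \deqn{E(IC) = [\psi(\gamma_{11}+a) - \psi(\gamma+n) - \psi(\alpha_1+a+b)
#'  + \psi(\alpha+n) - \psi(\beta_1+a+c) + \psi(\beta+n)] / \ln 2,}
#' with the variance given by the matching trigamma expression;
#' \code{variant = "approx"} uses the classical log-of-expectation
#' approximation of the early BCPNN literature. A pair is flagged when
#' \eqn{E(IC) - 1.96 \sqrt{V(IC)} > 0}.
#'
#' @inheritParams prr
#' @param priors hyperparameters from [bcpnnPriors()].
#' @param variant \code{"exact"} (digamma/trigamma posterior moments) or
#'   \code{"approx"} (classical closed-form approximation).
#' @inherit prr return
#' @examples
#' bcpnnIc(data.frame(a = 10, b = 5, c = 5, d = 80))
#' @export
bcpnnIc <- function(tab, priors = bcpnnPriors(),
                    variant = c("exact", "approx")) {
  variant <- match.arg(variant)
  tab <- .asTables(tab)
  a <- tab$a; n <- tab$n
  c1 <- tab$a + tab$b # drug margin
  c2 <- tab$a + tab$c # ADE margin
  defined <- n > 0
  gamma <- priors$gamma11 * (n + priors$alpha) * (n + priors$beta) /
    ((c1 + priors$alpha1) * (c2 + priors$beta1))
  if (variant == "exact") {
    eic <- (digamma(priors$gamma11 + a) - digamma(gamma + n) -
              digamma(priors$alpha1 + c1) + digamma(priors$alpha + n) -
              digamma(priors$beta1 + c2) + digamma(priors$beta + n)) / log(2)
    vic <- (trigamma(priors$gamma11 + a) - trigamma(gamma + n) +
              trigamma(priors$alpha1 + c1) - trigamma(priors$alpha + n) +
              trigamma(priors$beta1 + c2) - trigamma(priors$beta + n)) /
      log(2)^2
  } else {
    eic <- log2((a + priors$gamma11) * (n + priors$alpha) *
                  (n + priors$beta) /
                  ((n + gamma) * (c1 + priors$alpha1) * (c2 + priors$beta1)))
    vic <- ((n - a + gamma - priors$gamma11) /
              ((a + priors$gamma11) * (1 + n + gamma)) +
              (n - c1 + priors$alpha - priors$alpha1) /
              ((c1 + priors$alpha1) * (1 + n + priors$alpha)) +
              (n - c2 + priors$beta - priors$beta1) /
              ((c2 + priors$beta1) * (1 + n + priors$beta))) / log(2)^2
  }
  eic[!defined] <- NA_real_
  vic[!defined] <- NA_real_
  lo <- eic - Z95 * sqrt(vic)
  .resultFrame(tab, "BCPNN", eic, lo, lo > 0, defined)
}

#' Yates-corrected Pearson chi-square of a 2x2 table
#'
#' \eqn{\chi^2 = n (|ad - bc| - n/2)^2 / [(a+b)(c+d)(a+c)(b+d)]}, with the
#' continuity term floored at zero; \code{yates = FALSE} drops the
#' correction.
#'
#' @inheritParams prr
#' @param yates apply the continuity correction.
#' @return numeric vector of chi-square values (NA where a margin is
#'   zero).
#' @export
yatesChisq <- function(tab, yates = TRUE) {
  tab <- .asTables(tab)
  a <- tab$a; b <- tab$b; cc <- tab$c; d <- tab$d; n <- tab$n
  den <- (a + b) * (cc + d) * (a + cc) * (b + d)
  num <- abs(a * d - b * cc)
  if (yates) num <- pmax(0, num - n / 2)
  ifelse(den > 0, n * num^2 / den, NA_real_)
}

#' MHRA composite signal criterion
#'
#' Flags a pair when \eqn{PRR \ge 2}, Yates-corrected \eqn{\chi^2 \ge 4}
#' and \eqn{a \ge 3} simultaneously. The reported estimate is the PRR
#' point value; \code{chi2} carries the chi-square.
#'
#' @inheritParams prr
#' @param yates apply the Yates continuity correction to the chi-square.
#' @inherit prr return
#' @examples
#' mhra(data.frame(a = 10, b = 5, c = 5, d = 80))
#' @export
mhra <- function(tab, yates = TRUE) {
  tab <- .asTables(tab)
  p <- prr(tab)
  chi2 <- yatesChisq(tab, yates = yates)
  defined <- p$defined & !is.na(chi2)
  sig <- defined & p$estimate >= 2 & chi2 >= 4 & tab$a >= 3
  .resultFrame(tab, "MHRA", p$estimate, NA_real_, sig, defined, chi2 = chi2)
}

#' Run several disproportionality methods at once
#'
#' @inheritParams prr
#' @param methods subset of \code{c("PRR", "ROR", "BCPNN", "MHRA")}.
#' @param priors BCPNN priors, see [bcpnnPriors()].
#' @param variant BCPNN variant, see [bcpnnIc()].
#' @return row-bound data.frame of the per-method results.
#' @export
disproAnalysis <- function(tab, methods = c("PRR", "ROR", "BCPNN", "MHRA"),
                           priors = bcpnnPriors(),
                           variant = c("exact", "approx")) {
  methods <- match.arg(methods, several.ok = TRUE)
  tab <- .asTables(tab)
  res <- lapply(methods, function(m) {
    switch(m,
           PRR = prr(tab),
           ROR = ror(tab),
           BCPNN = bcpnnIc(tab, priors, variant),
           MHRA = mhra(tab))
  })
  do.call(rbind, res)
}

#' Ranking score of a method for ROC analysis
#'
#' The per-cell score each algorithm ranks candidate pairs by: the rule
#' lift \eqn{a n / ((a+b)(a+c))} for AR, the posterior expected information
#' component for BCPNN, and the PRR point estimate for MHRA (and for PRR;
#' ROR scores by the odds ratio). The \eqn{a \ge 3} report filter used for
#' ROC construction is applied by the caller (see [pooledRoc()]).
#'
#' @inheritParams prr
#' @param method one of \code{"AR"}, \code{"PRR"}, \code{"ROR"},
#'   \code{"BCPNN"}, \code{"MHRA"}.
#' @param priors BCPNN priors.
#' @return numeric score vector, NA where the method is undefined.
#' @examples
#' rocScore(data.frame(a = 10, b = 5, c = 5, d = 80), "AR")
#' @export
rocScore <- function(tab, method = c("AR", "PRR", "ROR", "BCPNN", "MHRA"),
                     priors = bcpnnPriors()) {
  method <- match.arg(method)
  tab <- .asTables(tab)
  switch(method,
         AR = ifelse((tab$a + tab$b) > 0 & (tab$a + tab$c) > 0,
                     tab$a * tab$n / ((tab$a + tab$b) * (tab$a + tab$c)),
                     NA_real_),
         PRR = prr(tab)$estimate,
         ROR = ror(tab)$estimate,
         BCPNN = bcpnnIc(tab, priors)$estimate,
         MHRA = prr(tab)$estimate)
}
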