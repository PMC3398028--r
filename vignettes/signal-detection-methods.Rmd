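---
title: "Simulating spontaneous reporting systems and benchmarking signal-detection methods"
author: "pvmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating spontaneous reporting systems and benchmarking signal-detection methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvmine)
```

## Background

Spontaneous reporting systems (SRS) collect voluntary reports of suspected
adverse drug events (ADEs). Signal detection asks which drug–ADE pairs are
reported disproportionately often, flagging them for expert review. The
classical tools are disproportionality statistics on the per-pair 2×2
table — the proportional reporting ratio (PRR), the reporting odds ratio
(ROR), the Bayesian information component of the BCPNN, and the MHRA
composite criterion. Association-rule (AR) mining offers an alternative:
treat each report as a transaction of typed items (drugs, ADEs), mine
frequent itemsets, and keep drug→ADE rules whose support and lift clear
thresholds.

Because no real SRS comes with ground truth, methods are compared on
simulated systems with planted signals. `pvmine` implements the full
chain: a Monte Carlo SRS simulator, the AR miner, the four
disproportionality comparators, and an evaluation harness
(sensitivity/specificity sweeps, ROC/AUC against the planted truth).

## The report model

The number of reports in a drug–ADE cell is an independent Poisson draw
with mean

$$\lambda = e \cdot i \cdot RR \cdot pr,$$

where

* $e$ — drug exposure frequency (persons exposed),
* $i$ — background incidence of the event per exposed person,
* $RR$ — the relative risk planted in the cell (1 for non-signals),
* $pr$ — the probability that an occurring event is actually reported.

The default grid (`srsSimConfig()`) emulates a mid-size national SRS over
one reporting period: 60 drugs × 40 ADEs (2,400 cells); exposure
$e \in \{300{,}000,\, 30{,}000\}$, each on half the drugs; incidence
$i \in \{1/200,\, 1/500\}$, each on half the ADEs; half the ADEs serious;
drug launch durations of 1, 5 and 10 years in equal thirds within each
exposure stratum. Reporting probabilities decline with time on the market
and are higher for serious events:

| duration | serious | mild  |
|---------:|--------:|------:|
| 1 year   | 0.095   | 0.080 |
| 5 years  | 0.080   | 0.055 |
| 10 years | 0.030   | 0.010 |

The ladder spans 0.095 down to 0.010, with 0.080 serving both the
(1 year, mild) and (5 year, serious) strata; the stratum-average reporting
probability is then $0.35/6 \approx 5.8\%$, which at the default grid
yields about 108,000 reports per simulated period — the scale the design
is calibrated to. Strata are assigned deterministically in index order, so
every configuration has exactly balanced strata and the expected total is
an exact closed form (the test suite checks the simulated mean against
it).

Of the 2,400 cells, 10% are planted as true signals, placed uniformly at
random, with relative risks $\{10, 4.9, 1.5, 1.2\}$ in equal shares (60
cells each at the defaults); the remainder are coincidental with
$RR = 1$. The equal split is the minimal assumption given a set of levels
and no stated allocation. All randomness is governed by one seed per
dataset; `simulateSrsBatch()` derives per-dataset sub-seeds from a master
seed (a fixed-seed draw of distinct 31-bit integers), so batches are
reproducible and any single dataset can be regenerated independently.

### What counts as a recoverable signal

A planted signal whose cell produced zero reports cannot be recovered by
any report-based method. The evaluation therefore defaults to the
*evaluable* universe — cells with at least one report — and to the
evaluable truth set (planted signals with ≥1 report; about 236–237 of the
240 planted cells at the defaults, the deficit coming from the low-λ
strata). `evaluableCells(x, minReports = 0)` switches to the full grid
when the stricter definition is wanted.

## Association-rule mining

With $n$ reports, an itemset's *support* is the fraction of reports
containing it; a rule $A \rightarrow B$ has

$$\mathrm{support} = P(A \cup B), \qquad
  \mathrm{confidence} = \frac{P(A \cup B)}{P(A)}, \qquad
  \mathrm{lift} = \frac{P(A \cup B)}{P(A)\,P(B)}.$$

`frequentItemsets()` counts every itemset occurring in at least
`minSupportCount` reports by enumerating the observed transactions
(restricted to frequent single items), so downward closure holds by
construction and the counts are exact — no approximation is involved. On
the universes this package targets (a few thousand item codes, small
transactions) this brute-force counting is faster and simpler than
tree-based alternatives. `generateRules()` forms every
antecedent/consequent split of each frequent itemset and applies the
confidence and lift thresholds; `templateMatch()` keeps rules whose
antecedent items are all drugs and consequent items all ADEs, pruned to
`maxRuleItems` (default 2: one drug implying one ADE). `mineSignals()`
chains the three.

Default thresholds are a support count of 3 (the conventional minimum
number of reports for a credible combination), lift 1.2, and **no**
confidence threshold: a rare but strongly drug-associated event can have
low confidence, so confidence is a poor screen for signals. All
thresholds are inclusive (≥), matching the criterion "support ≥ 3 and
lift ≥ 1.2"; `miningParams(strict = TRUE)` switches lift/confidence to
strict inequalities for sensitivity analyses.

On single-pair transactions the rule statistics reduce exactly to 2×2
arithmetic — support $a/n$, confidence $a/(a+b)$, lift
$an/((a+b)(a+c))$ — and the test suite verifies this equivalence against
the contingency module on simulated data.

## Disproportionality statistics

For a pair with table $(a, b, c, d)$ and $n = a+b+c+d$:

* **PRR** $= \dfrac{a/(a+b)}{c/(c+d)}$ with the log-scale Wald interval
  $\exp\!\big(\ln PRR \pm 1.96\sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}\big)$;
  signal when the lower limit exceeds 1.
* **ROR** $= \dfrac{ad}{bc}$ with
  $\exp\!\big(\ln ROR \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d}\big)$; signal
  when the lower limit exceeds 1.
* **MHRA**: signal when $PRR \ge 2$, Yates-corrected $\chi^2 \ge 4$, and
  $a \ge 3$ simultaneously.
* **BCPNN**: the information component
  $IC = \log_2 \dfrac{P(xy)}{P(x)P(y)}$ under independent Beta posteriors
  for the joint and marginal reporting proportions; signal when the 95%
  lower limit $E(IC) - 1.96\sqrt{V(IC)}$ exceeds 0.

Zero denominators are a real phenomenon in sparse SRS data. No continuity
or Haldane correction is applied: where a statistic is not computable the
result carries `defined = FALSE` and is never a signal. The Yates
correction (floored at zero) is the default for the MHRA chi-square;
`yates = FALSE` disables it. The interval multiplier is fixed at the
conventional 1.96.

### BCPNN details

The priors (`bcpnnPriors()`) are the standard uninformative pseudo-counts
$\alpha_1 = \beta_1 = \gamma_{11} = 1$, $\alpha = \beta = 2$, with the
joint prior total $\gamma$ calibrated to the data so that an exactly
independent table gives $IC = 0$. Two moment computations are offered:

* `variant = "exact"` (default): the exact posterior moments via digamma
  and trigamma functions — for $p \sim \mathrm{Beta}(u, v)$,
  $E(\ln p) = \psi(u) - \psi(u+v)$ and
  $\mathrm{Var}(\ln p) = \psi_1(u) - \psi_1(u+v)$, summed over the three
  independent posteriors.
* `variant = "approx"`: the classical closed-form approximation
  (log of posterior expectations with a delta-method variance), kept for
  comparability with the early BCPNN literature.

The exact moments were chosen as the default because they agree with a
numeric (Monte Carlo) evaluation of the posterior to well under 0.01 bits
even at single-digit counts, where the classical approximation deviates
by several hundredths of a bit.

## Evaluation

`confusionSummary()` counts TP/FP/TN/FN over the evaluable universe;
Youden's index is *defined* as sensitivity + specificity − 1 and is always
derived from the computed rates, never reported independently of them.
`sweepMinLift()` mines each dataset once at the smallest lift in the grid
and thresholds the mined rules per grid point, so sensitivity is
non-increasing and specificity non-decreasing in the threshold by
construction. `meanDetections()` reports each method's mean flagged-cell
count with the sample (n−1) standard deviation.

ROC analysis (`rocAuc()`, `pooledRoc()`) ranks cells with at least
`minCount = 3` reports by the method's natural score — lift for AR, the
posterior expected IC for BCPNN, the PRR point estimate for MHRA (a
configuration-visible choice; any monotone transform of a score leaves
the AUC unchanged). The AUC is the Mann–Whitney statistic with ties
counted ½, which equals the trapezoidal area under the empirical curve;
the suite checks this identity and cross-checks the AUC against an
independent ROC implementation. The default pools the filtered cells of
all datasets into one curve; `pool = FALSE` averages per-dataset AUCs
instead.

## Numerical and design notes

* **Determinism.** Identical (configuration, seed) pairs give
  bit-identical datasets; all simulation entry points restore the
  caller's RNG state. `reproduceStudy()` writes a manifest (seeds,
  configuration, thresholds) sufficient to re-run any stage exactly.
* **Problem sizes.** The test suite runs the full grid at 2–40 datasets
  per check and the parameter-recovery properties at 100 replicates; the
  acceptance script uses 200 datasets. These sizes put the standard error
  of every reported mean well under the tolerances being checked while
  keeping a complete run in the minutes range on one core.
* **Ties and boundaries.** Mining thresholds are inclusive; equality at
  `minLift` keeps a rule. ROC ties are handled by the ½ convention, and
  tied score blocks appear as single diagonal segments of the curve.
* **Degenerate inputs.** All-zero count matrices yield tables flagged
  `degenerate`; empty report collections, unknown item kinds, and missing
  columns in report files raise errors naming the offending lines.

## Known limitations

* **Structural dependence among null cells.** The reporting probability
  varies jointly with drug age and event severity and is not a product of
  a drug factor and an ADE factor. Margins therefore do not factorize
  exactly even for non-signal cells: some strata (old drugs × serious
  events under the default ladder) carry structural lift above 1, and
  with large counts these cells are flagged by lift- and
  disproportionality-based criteria alike. This is a property of the
  data-generating design, not an implementation artifact; it inflates
  false-positive counts relative to an idealized fully independent null
  and should be kept in mind when quoting specificity.
* **What the simulator does not model.** One drug and one ADE per report
  (real reports carry several of each — the data structures support this,
  the generator does not produce it); no duplicated or near-duplicate
  reports; no coding or vocabulary noise; a fixed reporting probability
  per stratum (no time dynamics, no media effects); no confounding by
  age, sex, or co-medication. Passing the planted-truth benchmarks
  therefore demonstrates correct arithmetic and sensible relative
  behaviour of the methods, not field performance on a real SRS.
* **Scope.** Multi-item rule *analysis* (one drug → several ADEs, drug
  interactions) is supported by the miner but not evaluated; stratified
  disproportionality and shrinkage methods beyond the BCPNN are out of
  scope.

## Session info

```{r}
sessionInfo()
```
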