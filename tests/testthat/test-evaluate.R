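test_that("confusion rates follow their definitions on exact cases", {
  ev <- sprintf("C%02d", 1:10)
  tru <- ev[1:4]
  perfect <- confusionSummary(tru, tru, ev)
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "youden")]),
               c(sensitivity = 1, specificity = 1, youden = 1))
  none <- confusionSummary(character(), tru, ev)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  mixed <- confusionSummary(c(ev[1], ev[5]), tru, ev)
  expect_equal(unlist(mixed[c("tp", "fp", "tn", "fn")]),
               c(tp = 1, fp = 1, tn = 5, fn = 3))
  expect_equal(mixed$sensitivity, 0.25)
  expect_equal(mixed$specificity, 5 / 6)
  # detections outside the universe are a caller error
  expect_error(confusionSummary("X99", tru, ev), "subset")
  # empty truth: sensitivity undefined, flagged as NA
  expect_true(is.na(confusionSummary(character(), character(), ev)$sensitivity))
})

test_that("Youden's index equals sensitivity + specificity - 1 on computed outputs", {
  set.seed(31)
  ev <- sprintf("C%03d", 1:200)
  for (rep in 1:20) {
    tru <- sample(ev, 40)
    det <- sample(ev, sample(0:80, 1))
    cs <- confusionSummary(det, tru, ev)
    expect_identical(cs$youden, cs$sensitivity + cs$specificity - 1)
  }
})

test_that("AUC handles perfect ranking, ties, and mixed orders", {
  expect_equal(auc(rocAuc(c(3, 2, 1), c(1, 1, 0))), 1)
  expect_equal(auc(rocAuc(c(1, 1, 1, 1), c(1, 0, 1, 0))), 0.5)
  expect_equal(auc(rocAuc(c(1, 2, 3, 4), c(0, 1, 0, 1))), 0.75)
  expect_error(rocAuc(1:3, c(1, 1, 1)), "positive and one negative")
  expect_warning(r <- rocAuc(c(1, 2, NA), c(0, 1, 1)), "undefined")
  expect_equal(auc(r), 1)
})

test_that("Mann-Whitney AUC equals the trapezoidal area for tied and untied scores", {
  set.seed(91)
  for (rep in 1:20) {
    n <- 60
    scores <- sample(seq(0, 2, by = 0.25), n, replace = TRUE) # heavy ties
    labels <- runif(n) < 0.3
    if (!any(labels) || all(labels)) next
    curve <- rocAuc(scores, labels)
    expect_equal(auc(curve), trapezoidArea(curve), tolerance = 1e-12)
    # curve shape invariants
    expect_true(!is.unsorted(rocPoints(curve)$fpr))
    expect_true(!is.unsorted(rocPoints(curve)$tpr))
    expect_equal(head(unlist(rocPoints(curve)[1, ]), 2),
                 c(fpr = 0, tpr = 0))
    expect_equal(unlist(rocPoints(curve)[nrow(rocPoints(curve)), ]),
                 c(fpr = 1, tpr = 1))
    # invariant under strictly monotone score transformations
    expect_equal(auc(rocAuc(exp(scores), labels)), auc(curve))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  scores <- rnorm(300)
  labels <- runif(300) < plogis(scores)
  if (!any(labels) || all(labels)) skip("degenerate draw")
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc(rocAuc(scores, labels)), ref, tolerance = 1e-9)
})

test_that("the lift sweep is monotone: sensitivity down, specificity up", {
  batch <- simulateSrsBatch(srsSimConfig(), 3, masterSeed = 71)
  sw <- sweepMinLift(batch, seq(1.0, 1.6, by = 0.2))
  expect_true(all(diff(sw$sensitivity) <= 1e-12))
  expect_true(all(diff(sw$specificity) >= -1e-12))
  expect_equal(sw$youden, sw$sensitivity + sw$specificity - 1)
  # a single dataset with a one-point grid is just that dataset's confusion
  one <- sweepMinLift(batch[1], 1.2)
  rules <- mineSignals(countsToReports(batch[[1]]))
  cs <- confusionSummary(cellKeys(rules), trueSignalCells(batch[[1]]),
                         evaluableCells(batch[[1]]))
  expect_equal(one$sensitivity, cs$sensitivity)
  expect_equal(one$specificity, cs$specificity)
})

test_that("detection summaries average per-dataset flag counts", {
  ds <- simulateSrs(srsSimConfig(), seed = 81)
  batch <- list(ds, ds, ds) # identical datasets: SD must vanish
  det <- meanDetections(batch, c("AR", "PRR", "MHRA"))
  expect_equal(det$sdDetected, rep(0, 3))
  expect_equal(det$sdTrueSignals, rep(0, 3))
  tab <- contingencyTables(ds)
  expect_equal(det$meanDetected[det$method == "PRR"], sum(prr(tab)$isSignal))
  expect_equal(det$meanDetected[det$method == "MHRA"], sum(mhra(tab)$isSignal))
  # an unattainable lift threshold detects nothing
  none <- meanDetections(batch[1], "AR", miningParams(minLift = Inf))
  expect_equal(none$meanDetected, 0)
})

test_that("pooled ROC filters on the report count and beats chance on planted signals", {
  batch <- simulateSrsBatch(srsSimConfig(), 2, masterSeed = 61)
  curve <- pooledRoc(batch, "AR", minCount = 3)
  tabs <- lapply(batch, contingencyTables)
  nKept <- sum(vapply(tabs, function(t) sum(t$a >= 3), numeric(1)))
  expect_equal(curve@nPos + curve@nNeg, nKept)
  expect_gt(auc(curve), 0.7)
  byDataset <- pooledRoc(batch, "AR", minCount = 3, pool = FALSE)
  expect_true(is.numeric(byDataset) && byDataset > 0.5 && byDataset <= 1)
})
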