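#' End-to-end simulation study driver
#'
#' Simulates a batch of spontaneous-reporting datasets, runs the
#' association-rule miner and the four disproportionality comparators on
#' every dataset, and assembles the three study summary tables: the
#' minimum-lift sensitivity/specificity sweep, the average detection
#' counts per method, and the pooled ROC AUCs (AR, BCPNN, MHRA over cells
#' with at least \code{minCount} reports). When \code{outDir} is given the
#' tables are written as TSV together with a JSON run manifest sufficient
#' to re-run the study bit-identically.
#'
#' @param nDatasets number of simulated datasets.
#' @param seed master seed for the batch.
#' @param outDir optional output directory (created if missing).
#' @param config an [SrsSimConfig].
#' @param liftGrid minimum-lift values for the sweep.
#' @param params [MiningParams] used for the detection-count table.
#' @param priors,variant BCPNN settings.
#' @param minCount report filter for the ROC curves.
#' @return list with elements \code{meanTotalReports},
#'   \code{sdTotalReports}, \code{sweep}, \code{detections}, \code{aucs}
#'   (named numeric), \code{rocCurves} (named list of [RocCurve]) and
#'   \code{manifest}.
#' @examples
#' res <- reproduceStudy(nDatasets = 2, seed = 11)
#' res$detections
#' @export
reproduceStudy <- function(nDatasets = 1000L, seed = 1L, outDir = NULL,
                           config = srsSimConfig(),
                           liftGrid = seq(1.0, 1.6, by = 0.1),
                           params = miningParams(),
                           priors = bcpnnPriors(), variant = "exact",
                           minCount = 3L) {
  if (nDatasets < 1L) stop("nDatasets must be >= 1", call. = FALSE)
  batch <- simulateSrsBatch(config, nDatasets, seed)
  be <- .batchEvaluation(batch, liftGrid, params, priors, variant, minCount)
  sens <- colMeans(be$sweepSens)
  spec <- colMeans(be$sweepSpec)
  sweep <- data.frame(minLift = be$liftGrid, sensitivity = sens,
                      specificity = spec, youden = sens + spec - 1)
  crit <- c(
    AR = sprintf("support count >= %d and lift >= %g",
                 params@minSupportCount, params@minLift),
    PRR = "lower 95% limit of PRR > 1",
    ROR = "lower 95% limit of ROR > 1",
    BCPNN = "lower 95% limit of IC > 0",
    MHRA = "PRR >= 2 and chi2 >= 4 and a >= 3")
  det <- cbind(be$arDetected, be$flags)
  colnames(det)[1L] <- "AR"
  detections <- data.frame(
    method = colnames(det), criterion = unname(crit[colnames(det)]),
    meanDetected = colMeans(det), sdDetected = apply(det, 2L, sd),
    meanTrueSignals = mean(be$nTruth), sdTrueSignals = sd(be$nTruth),
    row.names = NULL, stringsAsFactors = FALSE)
  rocCurves <- lapply(be$rocScores, function(s) rocAuc(s, be$rocLabels))
  aucs <- vapply(rocCurves, auc, numeric(1))
  manifest <- list(
    tool = "pvmine", version = as.character(utils::packageVersion("pvmine")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    nDatasets = nDatasets, masterSeed = as.integer(seed),
    datasetSeeds = datasetSeeds(seed, nDatasets),
    config = .configAsList(config),
    params = list(minSupportCount = params@minSupportCount,
                  minLift = params@minLift,
                  minConfidence = params@minConfidence,
                  maxRuleItems = params@maxRuleItems,
                  strict = params@strict),
    priors = priors, bcpnnVariant = variant, rocMinCount = minCount,
    liftGrid = liftGrid)
  out <- list(meanTotalReports = mean(be$totalReports),
              sdTotalReports = sd(be$totalReports),
              sweep = sweep, detections = detections, aucs = aucs,
              rocCurves = rocCurves, manifest = manifest)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(sweep, file.path(outDir, "lift_sweep.tsv"),
                       sep = "\t")
    data.table::fwrite(detections, file.path(outDir, "detections.tsv"),
                       sep = "\t")
    data.table::fwrite(
      data.frame(method = names(aucs), auc = unname(aucs)),
      file.path(outDir, "auc.tsv"), sep = "\t")
    for (m in names(rocCurves))
      data.table::fwrite(rocPoints(rocCurves[[m]]),
                         file.path(outDir, sprintf("roc_%s.tsv", m)),
                         sep = "\t")
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    manifestPaths <- file.path(outDir, c("lift_sweep.tsv", "detections.tsv",
                                         "auc.tsv", "manifest.json"))
    out$paths <- manifestPaths
  }
  out
}

.configAsList <- function(config) {
  list(nDrugs = config@nDrugs, nAdes = config@nAdes,
       exposureLevels = config@exposureLevels,
       incidenceLevels = config@incidenceLevels,
       seriousFraction = config@seriousFraction,
       durationLevels = config@durationLevels,
       prTable = config@prTable,
       signalFraction = config@signalFraction,
       rrLevels = config@rrLevels, rrNull = config@rrNull,
       seed = config@seed)
}

#' Build an SrsSimConfig from a YAML or JSON file
#'
#' Reads a configuration file whose top-level fields mirror the arguments
#' of [srsSimConfig()]; missing fields keep their defaults. The
#' \code{prTable} field, if present, must be a table with columns
#' \code{duration}, \code{serious}, \code{pr}.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A validated [SrsSimConfig].
#' @export
readSimConfig <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON configs requires the jsonlite package",
           call. = FALSE)
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(lst$prTable)) lst$prTable <- as.data.frame(lst$prTable)
  do.call(srsSimConfig, lst)
}
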