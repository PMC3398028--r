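#' Default reporting-probability table
#'
#' Reporting probabilities by drug launch duration (years) and event
#' severity. Reporting is assumed more complete for recently launched drugs
#' and for serious events, so \code{pr} decreases with duration and, within
#' a duration, is at least as high for serious events: 0.095 down to 0.010
#' across the six strata, with 0.080 serving both (1 yr, mild) and
#' (5 yr, serious).
#'
#' @return data.frame with columns \code{duration}, \code{serious},
#'   \code{pr}.
#' @export
defaultPrTable <- function() {
  data.frame(
    duration = c(1, 1, 5, 5, 10, 10),
    serious = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    pr = c(0.095, 0.080, 0.080, 0.055, 0.030, 0.010)
  )
}

#' Construct a simulation configuration
#'
#' Returns an [SrsSimConfig] describing the Monte Carlo report model. The
#' defaults reproduce the reference study grid: 60 drugs x 40 ADEs (2,400
#' cells), drug exposure \eqn{e \in \{300000, 30000\}} each on half the
#' drugs, ADE background incidence \eqn{i \in \{1/200, 1/500\}} each on half
#' the ADEs, half the ADEs serious, launch durations \{1, 5, 10\} years in
#' equal thirds, the reporting probabilities of [defaultPrTable()], and 10\%
#' of cells planted as true signals with relative risks
#' \{10, 4.9, 1.5, 1.2\} in equal shares (the rest have RR 1).
#'
#' @param nDrugs,nAdes grid dimensions.
#' @param exposureLevels persons exposed, one stratum per level, equal
#'   shares of the drugs.
#' @param incidenceLevels background incidences, equal shares of the ADEs.
#' @param seriousFraction fraction of ADEs flagged serious (within each
#'   incidence stratum).
#' @param durationLevels launch durations in years, split over the drugs as
#'   evenly as possible within each exposure stratum.
#' @param prTable reporting probability per (duration, severity) stratum.
#' @param signalFraction fraction of cells planted as true signals.
#' @param rrLevels relative risks for true signals, allocated in equal
#'   shares (remainder cells take levels in listed order).
#' @param rrNull relative risk of non-signal cells.
#' @param seed default seed used by [simulateSrs()] when none is given.
#' @return A validated [SrsSimConfig].
#' @examples
#' cfg <- srsSimConfig()
#' cfg
#' @export
srsSimConfig <- function(nDrugs = 60L, nAdes = 40L,
                         exposureLevels = c(300000, 30000),
                         incidenceLevels = c(1 / 200, 1 / 500),
                         seriousFraction = 0.5,
                         durationLevels = c(1, 5, 10),
                         prTable = defaultPrTable(),
                         signalFraction = 0.10,
                         rrLevels = c(10, 4.9, 1.5, 1.2),
                         rrNull = 1,
                         seed = 1L) {
  new("SrsSimConfig",
      nDrugs = as.integer(nDrugs), nAdes = as.integer(nAdes),
      exposureLevels = as.numeric(exposureLevels),
      incidenceLevels = as.numeric(incidenceLevels),
      seriousFraction = as.numeric(seriousFraction),
      durationLevels = as.numeric(durationLevels),
      prTable = prTable,
      signalFraction = as.numeric(signalFraction),
      rrLevels = as.numeric(rrLevels), rrNull = as.numeric(rrNull),
      seed = as.integer(seed))
}

#' @describeIn SrsSimConfig-class compact display of the parameter grid.
#' @param object an \code{SrsSimConfig}.
#' @export
setMethod("show", "SrsSimConfig", function(object) {
  cat(sprintf("SrsSimConfig: %d drugs x %d ADEs (%d cells)\n",
              object@nDrugs, object@nAdes, object@nDrugs * object@nAdes))
  cat("  exposure e:", paste(format(object@exposureLevels, big.mark = ","),
                             collapse = ", "), "\n")
  cat("  incidence i:", paste(signif(object@incidenceLevels, 3),
                              collapse = ", "), "\n")
  cat("  durations (yr):", paste(object@durationLevels, collapse = ", "),
      " pr:", paste(object@prTable$pr, collapse = ", "), "\n")
  cat(sprintf("  signals: %.0f%% of cells, RR in {%s} (null RR %g)\n",
              100 * object@signalFraction,
              paste(object@rrLevels, collapse = ", "), object@rrNull))
})

# near-even integer split of n over k groups; remainder goes to the
# earliest groups
.evenSplit <- function(n, k) {
  base <- n %/% k
  base + as.integer(seq_len(k) <= n %% k)
}

.strictSplit <- function(n, k, what) {
  if (n %% k != 0L)
    stop(sprintf("%d %s cannot be divided into %d equal strata", n, what, k),
         call. = FALSE)
  rep(n %/% k, k)
}

#' Build drug and ADE profiles from a configuration
#'
#' Assigns every drug an exposure stratum and a launch duration, and every
#' ADE an incidence stratum and a severity flag. Exposure, incidence and
#' severity strata must divide the grid exactly (an error is raised
#' otherwise, e.g. 41 drugs over two half-strata); durations are split as
#' evenly as possible within each exposure stratum, remainder to the
#' earliest listed duration. The assignment is deterministic in index
#' order, so the strata are exactly balanced and reproducible.
#'
#' @param config an [SrsSimConfig].
#' @return list with elements \code{drugs} (data.frame \code{drug},
#'   \code{exposure}, \code{duration}) and \code{ades} (data.frame
#'   \code{ade}, \code{incidence}, \code{serious}).
#' @examples
#' p <- buildProfiles(srsSimConfig())
#' table(p$drugs$exposure, p$drugs$duration)
#' @export
buildProfiles <- function(config) {
  stopifnot(is(config, "SrsSimConfig"))
  validObject(config)
  nd <- config@nDrugs
  na <- config@nAdes
  eSizes <- .strictSplit(nd, length(config@exposureLevels), "drugs")
  exposure <- rep(config@exposureLevels, eSizes)
  duration <- unlist(lapply(eSizes, function(m) {
    rep(config@durationLevels, .evenSplit(m, length(config@durationLevels)))
  }), use.names = FALSE)
  drugs <- data.frame(
    drug = sprintf("D%02d", seq_len(nd)),
    exposure = exposure, duration = duration,
    stringsAsFactors = FALSE)

  iSizes <- .strictSplit(na, length(config@incidenceLevels), "ADEs")
  incidence <- rep(config@incidenceLevels, iSizes)
  serious <- unlist(lapply(iSizes, function(m) {
    nSer <- round(config@seriousFraction * m)
    if (abs(nSer - config@seriousFraction * m) > 1e-9)
      stop("seriousFraction does not divide the incidence strata evenly",
           call. = FALSE)
    rep(c(TRUE, FALSE), c(nSer, m - nSer))
  }), use.names = FALSE)
  ades <- data.frame(
    ade = sprintf("A%02d", seq_len(na)),
    incidence = incidence, serious = serious,
    stringsAsFactors = FALSE)
  list(drugs = drugs, ades = ades)
}

#' Plant true signals on the drug--ADE grid
#'
#' Flags \code{round(signalFraction * nDrugs * nAdes)} cells, chosen
#' uniformly at random, as true signals and allocates the configured RR
#' levels to them in equal shares (remainder cells take levels in listed
#' order). All other cells receive \code{rrNull}. Uses the current RNG
#' state; seed management is done by the caller (see [simulateSrs()]).
#'
#' @param config an [SrsSimConfig].
#' @param drugs,ades profile data.frames from [buildProfiles()].
#' @return list with \code{rr} (numeric nDrugs x nAdes matrix) and
#'   \code{signal} (logical matrix), with drug/ADE dimnames.
#' @export
assignSignals <- function(config, drugs, ades) {
  nd <- nrow(drugs)
  na <- nrow(ades)
  nCells <- nd * na
  nSig <- round(config@signalFraction * nCells)
  rr <- matrix(config@rrNull, nd, na,
               dimnames = list(drugs$drug, ades$ade))
  sig <- matrix(FALSE, nd, na, dimnames = dimnames(rr))
  if (nSig > 0L) {
    cells <- sample.int(nCells, nSig)
    k <- length(config@rrLevels)
    rrs <- rep(config@rrLevels, .evenSplit(nSig, k))
    rr[cells] <- rrs
    sig[cells] <- TRUE
  }
  list(rr = rr, signal = sig)
}

#' Expected number of reports in a cell
#'
#' The Poisson mean of the report count for one drug--ADE cell:
#' \eqn{\lambda = e \cdot i \cdot RR \cdot pr}.
#'
#' @param e drug exposure frequency (persons exposed), positive.
#' @param i ADE background incidence per exposed person, positive.
#' @param rr relative risk of the cell, positive.
#' @param pr reporting probability, positive.
#' @return numeric Poisson mean(s); arguments recycle.
#' @examples
#' expectedReportRate(300000, 1 / 200, 10, 0.095)  # 1425
#' @export
expectedReportRate <- function(e, i, rr, pr) {
  if (any(e <= 0) || any(i <= 0) || any(rr <= 0) || any(pr <= 0))
    stop("all of e, i, rr, pr must be positive", call. = FALSE)
  e * i * rr * pr
}

# run code with a private RNG stream; the caller's RNG state is untouched
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate one spontaneous reporting dataset
#'
#' Draws every cell count independently from a Poisson distribution with
#' mean \code{expectedReportRate(e, i, rr, pr)}, where \code{e} and the
#' launch duration come from the drug profile, \code{i} and the severity
#' from the ADE profile, \code{rr} from the planted signal table, and
#' \code{pr} from the (duration, severity) reporting table. The same
#' (config, seed) pair always yields an identical dataset; the caller's RNG
#' state is left untouched.
#'
#' @param config an [SrsSimConfig].
#' @param seed integer seed; defaults to the seed stored in \code{config}.
#' @return An [SrsExperiment] with assays \code{counts}, \code{rr},
#'   \code{signal}.
#' @examples
#' ds <- simulateSrs(srsSimConfig(), seed = 7)
#' ds
#' totalReports(ds)
#' @export
simulateSrs <- function(config, seed = config@seed) {
  stopifnot(is(config, "SrsSimConfig"))
  validObject(config)
  prof <- buildProfiles(config)
  .withSeed(seed, {
    truth <- assignSignals(config, prof$drugs, prof$ades)
    prKey <- paste(config@prTable$duration, config@prTable$serious)
    prLookup <- setNames(config@prTable$pr, prKey)
    prMat <- outer(prof$drugs$duration, prof$ades$serious,
                   function(d, s) prLookup[paste(d, s)])
    lambda <- outer(prof$drugs$exposure, prof$ades$incidence) *
      truth$rr * prMat
    cts <- matrix(rpois(length(lambda), lambda),
                  nrow = config@nDrugs, dimnames = dimnames(truth$rr))
    rd <- S4Vectors::DataFrame(prof$drugs, row.names = prof$drugs$drug)
    cd <- S4Vectors::DataFrame(prof$ades, row.names = prof$ades$ade)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = cts, rr = truth$rr, signal = truth$signal),
      rowData = rd, colData = cd,
      metadata = list(config = config, seed = as.integer(seed)))
    new("SrsExperiment", se)
  })
}

#' Simulate a batch of datasets
#'
#' Derives one sub-seed per dataset from \code{masterSeed} (a fixed-seed
#' draw of distinct 31-bit integers, so batches are reproducible and
#' individual datasets can be regenerated independently) and calls
#' [simulateSrs()] for each.
#'
#' @param config an [SrsSimConfig].
#' @param nDatasets number of datasets, \eqn{\ge 1}.
#' @param masterSeed integer master seed.
#' @return list of [SrsExperiment] objects.
#' @examples
#' batch <- simulateSrsBatch(srsSimConfig(nDrugs = 6, nAdes = 4), 3, 42)
#' vapply(batch, totalReports, numeric(1))
#' @export
simulateSrsBatch <- function(config, nDatasets, masterSeed = config@seed) {
  if (nDatasets < 1L) stop("nDatasets must be >= 1", call. = FALSE)
  seeds <- datasetSeeds(masterSeed, nDatasets)
  lapply(seeds, function(s) simulateSrs(config, seed = s))
}

#' Per-dataset sub-seeds of a batch
#'
#' The documented substream scheme of [simulateSrsBatch()]: seeding the RNG
#' with \code{masterSeed} and drawing \code{n} distinct integers below
#' 2^31.
#'
#' @param masterSeed integer master seed.
#' @param n number of sub-seeds.
#' @return integer vector of length \code{n}.
#' @export
datasetSeeds <- function(masterSeed, n) {
  .withSeed(masterSeed, sample.int(2147483646L, n))
}

#' @describeIn SrsExperiment-class report counts matrix (drugs x ADEs).
#' @param object an \code{SrsExperiment}.
#' @export
setMethod("counts", "SrsExperiment", function(object) {
  SummarizedExperiment::assay(object, "counts")
})

#' Planted truth of a simulated dataset
#'
#' @param x an [SrsExperiment].
#' @return data.frame with one row per cell: \code{drug}, \code{ade},
#'   \code{rr}, \code{isSignal} (column-major cell order, drugs fastest).
#' @export
#' @name signalTruth
setMethod("signalTruth", "SrsExperiment", function(x) {
  rr <- SummarizedExperiment::assay(x, "rr")
  sig <- SummarizedExperiment::assay(x, "signal")
  data.frame(
    drug = rep(rownames(x), ncol(x)),
    ade = rep(colnames(x), each = nrow(x)),
    rr = as.vector(rr), isSignal = as.vector(sig),
    stringsAsFactors = FALSE)
})

#' Drug and ADE profiles of a simulated dataset
#'
#' @param x an [SrsExperiment].
#' @return data.frame of per-drug (exposure, duration) or per-ADE
#'   (incidence, serious) profiles.
#' @export
#' @name drugProfiles
setMethod("drugProfiles", "SrsExperiment", function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
})

#' @rdname drugProfiles
#' @export
setMethod("adeProfiles", "SrsExperiment", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' Total number of reports in a dataset
#'
#' @param x an [SrsExperiment].
#' @return integer, the sum of the count matrix.
#' @export
#' @name totalReports
setMethod("totalReports", "SrsExperiment", function(x) {
  sum(counts(x))
})

#' @describeIn SrsExperiment-class display grid size, totals and planted
#'   signal count.
#' @export
setMethod("show", "SrsExperiment", function(object) {
  callNextMethod()
  cat(sprintf("total reports: %d; planted signals: %d of %d cells\n",
              totalReports(object),
              sum(SummarizedExperiment::assay(object, "signal")),
              nrow(object) * ncol(object)))
})
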