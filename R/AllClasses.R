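#' @include AllGenerics.R
NULL

#' CurlSession: one subject-arm concentration-curl recording
#'
#' Container for a single recording session: a 50 Hz (by default) time series
#' of nine IMU channels (3-axis accelerometer in m/s^2, gyroscope in deg/s,
#' magnetometer in uT) plus a heart-rate track in bpm, the per-set sample
#' boundaries (warm-up set first), the Borg RPE reported after each set, and
#' the dumbbell mass lifted.
#'
#' Sample intervals are 0-based half-open `[start, end)` index pairs
#' throughout the package; row `i` of `sensorData(x)` is sample index `i - 1`.
#'
#' @slot subjectId character scalar.
#' @slot arm `"left"` or `"right"`.
#' @slot samplingRate sampling frequency in Hz.
#' @slot samples data.frame with columns `t`, the nine IMU channels,
#'   `heart_rate`, and optionally the derived signals appended by
#'   [addDerivedSignals()].
#' @slot setBoundaries integer matrix, one row per set (warm-up included),
#'   columns `start`, `end`: 0-based half-open sample-index intervals.
#' @slot reportedRPE integer vector of Borg ratings (6-20), one per set.
#' @slot dumbbellMass mass in kg.
#'
#' @export
setClass("CurlSession",
  slots = c(subjectId = "character",
            arm = "character",
            samplingRate = "numeric",
            samples = "data.frame",
            setBoundaries = "matrix",
            reportedRPE = "integer",
            dumbbellMass = "numeric"))

setValidity("CurlSession", function(object) {
  msg <- character()
  s <- object@samples
  needed <- c("t", IMU_CHANNELS, "heart_rate")
  if (!all(needed %in% names(s)))
    msg <- c(msg, paste("samples must contain columns:",
                        paste(setdiff(needed, names(s)), collapse = ", ")))
  if (!(length(object@arm) == 1L && object@arm %in% c("left", "right")))
    msg <- c(msg, "arm must be 'left' or 'right'")
  if (!(length(object@samplingRate) == 1L && object@samplingRate > 0))
    msg <- c(msg, "samplingRate must be a positive scalar")
  if (nrow(s) > 1L && "t" %in% names(s)) {
    dt <- diff(s$t)
    if (any(dt <= 0) ||
        max(abs(dt - 1 / object@samplingRate)) > 1e-6 / object@samplingRate)
      msg <- c(msg, "timestamps must strictly increase with spacing 1/samplingRate")
  }
  b <- object@setBoundaries
  if (ncol(b) != 2L) {
    msg <- c(msg, "setBoundaries must have two columns (start, end)")
  } else if (nrow(b) > 0L) {
    if (any(b[, 1L] >= b[, 2L]) || any(b < 0L) || any(b[, 2L] > nrow(s)))
      msg <- c(msg, "setBoundaries must be non-empty intervals within the sample range")
    if (nrow(b) > 1L && any(b[-1L, 1L] < b[-nrow(b), 2L]))
      msg <- c(msg, "setBoundaries must be ordered and non-overlapping")
  }
  if (length(object@reportedRPE) != nrow(b))
    msg <- c(msg, "need one reported RPE per set (warm-up included)")
  if (length(object@reportedRPE) &&
      (any(object@reportedRPE < 6L) || any(object@reportedRPE > 20L)))
    msg <- c(msg, "reported RPE must lie on the Borg scale [6, 20]")
  if ("heart_rate" %in% names(s) && nrow(s) &&
      (any(s$heart_rate < 30) || any(s$heart_rate > 210)))
    msg <- c(msg, "heart_rate must lie within [30, 210] bpm")
  if (length(msg)) msg else TRUE
})

#' @describeIn CurlSession constructor.
#' @param subjectId,arm,samplingRate,samples,setBoundaries,reportedRPE,dumbbellMass
#'   see the corresponding slots.
#' @export
CurlSession <- function(subjectId, arm, samplingRate, samples, setBoundaries,
                        reportedRPE, dumbbellMass) {
  storage.mode(setBoundaries) <- "integer"
  colnames(setBoundaries) <- c("start", "end")
  new("CurlSession", subjectId = as.character(subjectId), arm = arm,
      samplingRate = samplingRate, samples = samples,
      setBoundaries = setBoundaries, reportedRPE = as.integer(reportedRPE),
      dumbbellMass = dumbbellMass)
}

#' @describeIn CurlSession subject identifier.
#' @param x a `CurlSession`.
#' @export
setMethod("subjectId", "CurlSession", function(x) x@subjectId)

#' @describeIn CurlSession which arm was recorded.
#' @export
setMethod("arm", "CurlSession", function(x) x@arm)

#' @describeIn CurlSession sampling frequency in Hz.
#' @export
setMethod("samplingRate", "CurlSession", function(x) x@samplingRate)

#' @describeIn CurlSession the sample table.
#' @export
setMethod("sensorData", "CurlSession", function(x) x@samples)

#' @describeIn CurlSession 0-based half-open per-set sample intervals.
#' @export
setMethod("setBoundaries", "CurlSession", function(x) x@setBoundaries)

#' @describeIn CurlSession Borg RPE reported after each set.
#' @export
setMethod("reportedRPE", "CurlSession", function(x) x@reportedRPE)

#' @describeIn CurlSession dumbbell mass in kg.
#' @export
setMethod("dumbbellMass", "CurlSession", function(x) x@dumbbellMass)

#' @describeIn CurlSession number of sets (warm-up included).
#' @export
setMethod("nSets", "CurlSession", function(x) nrow(x@setBoundaries))

setMethod("show", "CurlSession", function(object) {
  cat("CurlSession:", object@subjectId, sprintf("(%s arm)", object@arm), "\n")
  cat("  ", nrow(object@samples), " samples at ", object@samplingRate,
      " Hz; ", nrow(object@setBoundaries), " sets (warm-up first)\n", sep = "")
  cat("  reported RPE:", paste(object@reportedRPE, collapse = ", "),
      "| dumbbell:", object@dumbbellMass, "kg\n")
})

#' RepFeatureExperiment: per-repetition feature matrix
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' 33 windowed statistical features (rows) for every labelled repetition
#' (columns). `rowData` carries the source signal and statistic of each
#' feature; `colData` carries repetition identifiers (subject, arm, set, rep)
#' and labels (reported/fused/normalized RPE, fatigue status).
#'
#' @export
setClass("RepFeatureExperiment", contains = "SummarizedExperiment")

setValidity("RepFeatureExperiment", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  if (nrow(object) != 33L)
    msg <- c(msg, "expected exactly 33 feature rows")
  if (!identical(rownames(object), featureGrid()))
    msg <- c(msg, "feature rows must match featureGrid() in order")
  needed <- c("subject_id", "arm", "set_index", "rep_index",
              "fused_rpe", "is_fatigued")
  miss <- setdiff(needed, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste("colData must contain:", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' SelectionResult: dual Spearman screening outcome
#'
#' Per-feature Spearman rank correlation against the fused Borg RPE in the
#' fatigue-only subset and in the complete dataset, the two significance
#' flags at the configured allowance, and the overlap (`selected`) set.
#'
#' @slot table data.frame with one row per feature: `feature`, `signal`,
#'   `statistic`, `rho_fatigue`, `p_fatigue`, `sig_fatigue`, `rho_complete`,
#'   `p_complete`, `sig_complete`, `selected`.
#' @slot alpha the significance allowance (two-sided p-value threshold).
#' @export
setClass("SelectionResult",
  slots = c(table = "data.frame", alpha = "numeric"))

setValidity("SelectionResult", function(object) {
  msg <- character()
  tb <- object@table
  needed <- c("feature", "sig_fatigue", "sig_complete", "selected")
  if (!all(needed %in% names(tb)))
    msg <- c(msg, "selection table is missing required columns")
  else if (!identical(tb$selected, tb$sig_fatigue & tb$sig_complete))
    msg <- c(msg, "selected must equal sig_fatigue AND sig_complete")
  if (!(length(object@alpha) == 1L && object@alpha > 0 && object@alpha < 1))
    msg <- c(msg, "alpha must be a scalar in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @describeIn SelectionResult the selected (overlap) feature names, in
#'   stable feature order.
#' @param x a `SelectionResult`.
#' @export
setMethod("selectedFeatures", "SelectionResult",
          function(x) x@table$feature[x@table$selected])

#' @describeIn SelectionResult the full per-feature table.
#' @export
setMethod("selectionTable", "SelectionResult", function(x) x@table)

#' @describeIn SelectionResult the significance allowance used.
#' @export
setMethod("significanceAllowance", "SelectionResult", function(x) x@alpha)

setMethod("show", "SelectionResult", function(object) {
  tb <- object@table
  cat("SelectionResult:", sum(tb$selected), "of", nrow(tb),
      "features selected (alpha =", object@alpha, ")\n")
  byStat <- table(sub("^.*_(mean|sd|aad)$", "\\1", tb$feature[tb$selected]))
  for (s in FEATURE_STATS)
    cat(" ", s, ":", if (s %in% names(byStat)) byStat[[s]] else 0L, "\n")
})

#' EvalReport: classifier evaluation under one protocol
#'
#' @slot protocol `"subject_specific"` or `"cross_subject"`.
#' @slot metrics data.frame, one row per model: `model`, `precision`,
#'   `recall`, `accuracy`, `f1` as fractions in `[0, 1]` (unweighted means
#'   over folds, then over subjects where applicable).
#' @slot folds data.frame with the per-fold breakdown (confusion counts and
#'   metrics per model and fold/subject).
#' @slot config list snapshot of the evaluation configuration.
#' @export
setClass("EvalReport",
  slots = c(protocol = "character", metrics = "data.frame",
            folds = "data.frame", config = "list"))

setValidity("EvalReport", function(object) {
  msg <- character()
  if (!(length(object@protocol) == 1L &&
        object@protocol %in% c("subject_specific", "cross_subject")))
    msg <- c(msg, "protocol must be 'subject_specific' or 'cross_subject'")
  m <- object@metrics
  num <- unlist(m[setdiff(names(m), "model")])
  if (length(num) && any(!is.na(num) & (num < 0 | num > 1)))
    msg <- c(msg, "metrics must be fractions in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn EvalReport which validation protocol produced the report.
#' @param x an `EvalReport`.
#' @export
setMethod("protocol", "EvalReport", function(x) x@protocol)

#' @describeIn EvalReport per-model aggregate metrics (fractions).
#' @export
setMethod("evalMetrics", "EvalReport", function(x) x@metrics)

#' @describeIn EvalReport per-fold metric breakdown.
#' @export
setMethod("foldMetrics", "EvalReport", function(x) x@folds)

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport [", object@protocol, "]\n", sep = "")
  m <- object@metrics
  for (col in c("precision", "recall", "accuracy", "f1"))
    m[[col]] <- sprintf("%.1f%%", 100 * m[[col]])
  print(m, row.names = FALSE)
})
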