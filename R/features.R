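#' @include AllClasses.R
NULL

#' Average absolute deviation about the mean
#'
#' `mean(|x - mean(x)|)`. Together with the mean and the population standard
#' deviation this forms the per-window statistic triple computed for every
#' signal; it never exceeds the standard deviation (Jensen's inequality).
#'
#' @param x numeric vector (non-empty).
#' @return non-negative scalar.
#' @examples
#' aad(c(1, 2, 3)) # 2/3
#' @export
aad <- function(x) {
  if (!length(x)) stop("input error: empty input", call. = FALSE)
  mean(abs(x - mean(x)))
}

#' Population standard deviation
#'
#' Standard deviation with divisor `N` (not `N - 1`): the windows are treated
#' as complete signals, not samples from a larger population.
#'
#' @param x numeric vector of length >= 2.
#' @return non-negative scalar.
#' @examples
#' sdPop(c(-1, 1)) # 1
#' @export
sdPop <- function(x) {
  if (length(x) < 2L) stop("input error: need at least 2 samples", call. = FALSE)
  sqrt(mean((x - mean(x))^2))
}

#' Extract the 33 features of one repetition
#'
#' Mean, population standard deviation and average absolute deviation of each
#' of the 11 signals (9 IMU channels, total acceleration, exerted force) over
#' the repetition's half-open sample slice. Derived signals are appended to
#' the session first if absent.
#'
#' @param session a [CurlSession].
#' @param rep one-row slice of a repetition table (needs `start`, `end`).
#' @return named numeric vector of length 33, ordered as [featureGrid()].
#' @export
extractFeatures <- function(session, rep) {
  stopifnot(is(session, "CurlSession"))
  s <- sensorData(session)
  if (!all(DERIVED_SIGNALS %in% names(s))) {
    session <- addDerivedSignals(session)
    s <- sensorData(session)
  }
  start <- rep$start[1L]; end <- rep$end[1L]
  if (end - start < 2L)
    stop("input error: repetition shorter than 2 samples", call. = FALSE)
  idx <- (start + 1L):end
  vals <- vapply(FEATURE_SIGNALS, function(sig) {
    x <- s[[sig]][idx]
    c(mean(x), sdPop(x), aad(x))
  }, numeric(3L))
  out <- as.vector(vals)
  names(out) <- featureGrid()
  out
}

#' Build the cohort feature matrix
#'
#' One column per labelled repetition, 33 feature rows, packaged as a
#' [RepFeatureExperiment]. Repetitions shorter than 2 samples are skipped
#' with a warning; duplicate (subject, arm, set, rep) keys are an error.
#'
#' @param sessions list of [CurlSession] objects (or a single session).
#' @param labeledReps list of labelled repetition tables from
#'   [labelRepetitions()], parallel to `sessions` (or a single table).
#' @return a [RepFeatureExperiment].
#' @export
buildFeatureMatrix <- function(sessions, labeledReps) {
  if (is(sessions, "CurlSession")) sessions <- list(sessions)
  if (is.data.frame(labeledReps)) labeledReps <- list(labeledReps)
  stopifnot(length(sessions) == length(labeledReps))
  featList <- list(); metaList <- list()
  for (i in seq_along(sessions)) {
    sess <- addDerivedSignals(sessions[[i]])
    reps <- labeledReps[[i]]
    keep <- (reps$end - reps$start) >= 2L
    if (any(!keep))
      warning(sum(!keep), " repetition(s) shorter than 2 samples skipped",
              call. = FALSE)
    reps <- reps[keep, , drop = FALSE]
    if (!nrow(reps)) next
    featList[[length(featList) + 1L]] <-
      vapply(seq_len(nrow(reps)), function(j)
        extractFeatures(sess, reps[j, ]), numeric(33L))
    metaList[[length(metaList) + 1L]] <- reps
  }
  if (!length(featList)) stop("input error: no usable repetitions", call. = FALSE)
  mat <- do.call(cbind, featList)
  meta <- do.call(rbind, c(metaList, list(make.row.names = FALSE)))
  key <- paste(meta$subject_id, meta$arm, meta$set_index, meta$rep_index,
               sep = "_")
  if (anyDuplicated(key))
    stop("integrity error: duplicate (subject, arm, set, rep) keys",
         call. = FALSE)
  colnames(mat) <- key
  rownames(mat) <- featureGrid()
  cd <- S4Vectors::DataFrame(meta, row.names = key)
  rd <- S4Vectors::DataFrame(
    signal = rep(FEATURE_SIGNALS, each = 3L),
    statistic = rep(FEATURE_STATS, times = length(FEATURE_SIGNALS)),
    row.names = featureGrid())
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat), rowData = rd, colData = cd)
  new("RepFeatureExperiment", se)
}

#' Write / read a feature matrix as CSV
#'
#' Rows are repetitions: the identifier and label columns first, then the 33
#' feature columns. Numeric values survive a round trip to at least 12
#' significant digits.
#'
#' @param fm a [RepFeatureExperiment].
#' @param path CSV path.
#' @return `readFeatureMatrix` returns a [RepFeatureExperiment].
#' @export
writeFeatureMatrix <- function(fm, path) {
  stopifnot(is(fm, "RepFeatureExperiment"))
  df <- cbind(as.data.frame(SummarizedExperiment::colData(fm)),
              t(SummarizedExperiment::assay(fm, "features")))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  featCols <- featureGrid()
  metaCols <- setdiff(names(df), featCols)
  mat <- t(as.matrix(df[featCols]))
  key <- paste(df$subject_id, df$arm, df$set_index, df$rep_index, sep = "_")
  colnames(mat) <- key
  cd <- S4Vectors::DataFrame(df[metaCols], row.names = key)
  rd <- S4Vectors::DataFrame(
    signal = rep(FEATURE_SIGNALS, each = 3L),
    statistic = rep(FEATURE_STATS, times = length(FEATURE_SIGNALS)),
    row.names = featureGrid())
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat), rowData = rd, colData = cd)
  new("RepFeatureExperiment", se)
}
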