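#' @include AllClasses.R
NULL

#' Write and read sessions as CSV plus a JSON sidecar
#'
#' The on-disk schema is one CSV per session with columns `t`, the nine IMU
#' channels, `heart_rate` (and any derived signal columns present), plus a
#' JSON sidecar holding `subject_id`, `arm`, `sampling_rate`,
#' `set_boundaries` (0-based half-open index pairs), `reported_rpe` and
#' `dumbbell_mass`. Externally supplied recordings converted to this schema
#' (e.g. real IMU exports) are read the same way.
#'
#' @param session a [CurlSession].
#' @param csvPath path of the sample CSV.
#' @param jsonPath path of the metadata sidecar; defaults to `csvPath` with a
#'   `.json` extension.
#' @return `writeSession` returns the two paths invisibly; `readSession`
#'   returns a [CurlSession].
#' @export
writeSession <- function(session, csvPath,
                         jsonPath = sub("\\.csv$", ".json", csvPath)) {
  stopifnot(is(session, "CurlSession"))
  utils::write.csv(sensorData(session), csvPath, row.names = FALSE)
  meta <- list(subject_id = subjectId(session), arm = arm(session),
               sampling_rate = samplingRate(session),
               set_boundaries = unname(apply(setBoundaries(session), 1L,
                                             function(r) as.integer(r),
                                             simplify = FALSE)),
               reported_rpe = reportedRPE(session),
               dumbbell_mass = dumbbellMass(session))
  jsonlite::write_json(meta, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csvPath, json = jsonPath))
}

#' @rdname writeSession
#' @export
readSession <- function(csvPath,
                        jsonPath = sub("\\.csv$", ".json", csvPath)) {
  samples <- utils::read.csv(csvPath)
  meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  b <- meta$set_boundaries
  if (is.list(b)) b <- do.call(rbind, b)
  b <- matrix(as.integer(b), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  CurlSession(subjectId = meta$subject_id, arm = meta$arm,
              samplingRate = meta$sampling_rate, samples = samples,
              setBoundaries = b, reportedRPE = meta$reported_rpe,
              dumbbellMass = meta$dumbbell_mass)
}

#' Write and read per-repetition ground truth as CSV
#'
#' @param groundTruth data.frame as returned by [generateSession()] or
#'   [groundTruthTable()].
#' @param path CSV path.
#' @return `readGroundTruth` returns the data.frame.
#' @export
writeGroundTruth <- function(groundTruth, path) {
  utils::write.csv(groundTruth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) utils::read.csv(path)

#' Write a whole cohort to a directory
#'
#' One `<subject>_<arm>.csv` / `.json` pair per session plus a pooled
#' `ground_truth.csv`.
#'
#' @param cohort result of [generateCohort()].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(cohort))
    writeSession(cohort[[nm]]$session, file.path(dir, paste0(nm, ".csv")))
  writeGroundTruth(groundTruthTable(cohort),
                   file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory containing `<subject>_<arm>.csv`/`.json` pairs.
#' @return named list of [CurlSession] objects.
#' @export
readCohortSessions <- function(dir) {
  if (!dir.exists(dir))
    stop("input error: session directory '", dir, "' does not exist",
         call. = FALSE)
  csvs <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(csvs))
    stop("input error: no session files in '", dir, "'", call. = FALSE)
  csvs <- csvs[basename(csvs) != "ground_truth.csv"]
  out <- lapply(csvs, readSession)
  names(out) <- sub("\\.csv$", "", basename(csvs))
  out
}
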