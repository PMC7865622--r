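#' @include AllClasses.R
NULL

#' Convert heart rate to the Borg RPE scale
#'
#' The Borg 6-20 scale is anchored so that ten times the rating approximates
#' heart rate in bpm; the inverse mapping `hr / 10` turns a measured heart
#' rate into a Borg-equivalent exertion value (unrounded).
#'
#' @param hr heart rate in bpm (positive).
#' @return Borg-equivalent value, `hr / 10`.
#' @examples
#' hrToRPE(145) # 14.5
#' @export
hrToRPE <- function(hr) {
  if (any(!is.finite(hr)) || any(hr <= 0))
    stop("input error: heart rate must be positive", call. = FALSE)
  hr / 10
}

#' Does the reported RPE diverge from the measured heart rate?
#'
#' A reported Borg rating and a measured heart rate are considered divergent
#' when they disagree by more than the tolerance after putting both on the
#' bpm scale: `|reported * 10 - hr| > tolerance`. Agreement exactly at the
#' tolerance still counts as convergent.
#'
#' @param reportedRPE Borg rating (6-20).
#' @param meanHR mean heart rate over the repetition, bpm.
#' @param tolerance allowed disagreement in bpm (default 10).
#' @return logical.
#' @examples
#' isDivergent(17, 145) # TRUE:  |170 - 145| = 25 > 10
#' isDivergent(15, 160) # FALSE: exactly at the tolerance
#' @export
isDivergent <- function(reportedRPE, meanHR, tolerance = 10) {
  abs(reportedRPE * 10 - meanHR) > tolerance
}

#' Fuse reported RPE with measured heart rate
#'
#' Convergent repetitions keep the reported Borg rating unchanged. Divergent
#' ones (see [isDivergent()]) are relabelled with the average of the
#' reported rating and the heart-rate-derived rating, rounded half-up and
#' clamped to the Borg scale: `round((reported + hr/10) / 2)`.
#'
#' @inheritParams isDivergent
#' @param rounded if `FALSE`, return the pre-rounding fused value (the raw
#'   average for divergent repetitions, the reported rating otherwise).
#' @return integer Borg rating in 6-20 (numeric when `rounded = FALSE`).
#' @examples
#' fuseRPE(17, 145)                  # 16  ((17 + 14.5)/2 = 15.75 -> 16)
#' fuseRPE(17, 145, rounded = FALSE) # 15.75
#' fuseRPE(15, 150)                  # 15  (convergent, unchanged)
#' @export
fuseRPE <- function(reportedRPE, meanHR, tolerance = 10, rounded = TRUE) {
  div <- isDivergent(reportedRPE, meanHR, tolerance)
  fused <- ifelse(div, (reportedRPE + hrToRPE(meanHR)) / 2, reportedRPE)
  if (!rounded) return(fused)
  as.integer(clamp(roundHalfUp(fused), 6, 20))
}

#' Min-max normalize a fused RPE
#'
#' Linear rescaling of the Borg rating onto `[0, 1]` with the maximum fixed
#' at 20 (the top of the scale) and the minimum set per session from the RPE
#' reported after the warm-up, to absorb between-subject differences in how
#' the scale is used: `(rpe - setMin) / (20 - setMin)`, clipped to `[0, 1]`.
#'
#' @param fusedRPE Borg rating(s).
#' @param setMin session minimum (warm-up reported RPE), `6 <= setMin < 20`.
#' @return values in `[0, 1]`.
#' @export
normalizeRPE <- function(fusedRPE, setMin) {
  if (any(setMin >= 20) || any(setMin < 6))
    stop("input error: setMin must satisfy 6 <= setMin < 20", call. = FALSE)
  clamp((fusedRPE - setMin) / (20 - setMin), 0, 1)
}

#' Binarize a Borg rating into fatigue / non-fatigue
#'
#' Ratings 17-20 are fatigue, 6-16 non-fatigue.
#'
#' @param fusedRPE Borg rating(s) in 6-20.
#' @return character vector, `"fatigue"` or `"non_fatigue"`.
#' @examples
#' binarizeRPE(17) # "fatigue"
#' binarizeRPE(16) # "non_fatigue"
#' @export
binarizeRPE <- function(fusedRPE) {
  if (any(fusedRPE < 6) || any(fusedRPE > 20))
    stop("input error: Borg rating out of range [6, 20]", call. = FALSE)
  ifelse(fusedRPE >= 17, "fatigue", "non_fatigue")
}

#' Label segmented repetitions
#'
#' Assigns every repetition its set's reported Borg RPE, fuses that rating
#' with the mean heart rate over the repetition window, normalizes the fused
#' rating against the warm-up minimum, and binarizes into fatigue /
#' non-fatigue.
#'
#' @param session a [CurlSession].
#' @param reps repetition table from [detectRepetitions()].
#' @param tolerance divergence tolerance in bpm (default 10).
#' @return the repetition table with columns `reported_rpe`, `mean_hr`,
#'   `fused_rpe`, `normalized_rpe`, `is_fatigued` appended.
#' @export
labelRepetitions <- function(session, reps, tolerance = 10) {
  stopifnot(is(session, "CurlSession"))
  if (!nrow(reps)) stop("input error: no repetitions to label", call. = FALSE)
  hr <- sensorData(session)$heart_rate
  rpt <- reportedRPE(session)
  reps$reported_rpe <- rpt[reps$set_index + 1L]
  reps$mean_hr <- vapply(seq_len(nrow(reps)), function(i)
    mean(hr[(reps$start[i] + 1L):reps$end[i]]), numeric(1L))
  reps$fused_rpe <- fuseRPE(reps$reported_rpe, reps$mean_hr, tolerance)
  reps$normalized_rpe <- normalizeRPE(reps$fused_rpe, setMin = rpt[1L])
  reps$is_fatigued <- binarizeRPE(reps$fused_rpe) == "fatigue"
  reps
}
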