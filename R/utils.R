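#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going up (15.5 -> 16, 16.5 -> 17),
#' unlike [base::round()] which rounds half to even. Fused Borg labels use
#' this rule so that a mid-point average always lands on the higher rating.
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @examples
#' roundHalfUp(15.75) # 16
#' roundHalfUp(16.5)  # 17
#' @export
roundHalfUp <- function(x) {
  stopifnot(is.numeric(x))
  sign(x) * floor(abs(x) + 0.5)
}

#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Centred moving average with truncated edge windows
#'
#' @param x numeric vector.
#' @param width window width in samples (coerced to an odd integer >= 1).
#' @return smoothed vector, same length as `x`.
#' @keywords internal
movingAverage <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L || length(x) < 2L) return(x)
  half <- (width - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' @keywords internal
isCount <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

#' @keywords internal
stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Channel and feature vocabulary shared across modules. Order is the stable
# column/row order used everywhere (feature matrices, selection tables).
IMU_CHANNELS <- c("acc_x", "acc_y", "acc_z",
                  "gyr_x", "gyr_y", "gyr_z",
                  "mag_x", "mag_y", "mag_z")
DERIVED_SIGNALS <- c("total_acceleration", "exerted_force")
FEATURE_SIGNALS <- c(IMU_CHANNELS, DERIVED_SIGNALS)
FEATURE_STATS <- c("mean", "sd", "aad")

#' Canonical feature names
#'
#' The 33 per-repetition features: mean, standard deviation and average
#' absolute deviation of each of the 11 signals (9 IMU channels plus total
#' acceleration and exerted force), in stable order.
#'
#' @return character vector of length 33, e.g. `"acc_y_mean"`.
#' @export
featureGrid <- function() {
  as.vector(t(outer(FEATURE_SIGNALS, FEATURE_STATS, paste, sep = "_")))
}
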