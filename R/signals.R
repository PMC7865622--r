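#' @include AllClasses.R
NULL

#' Total acceleration magnitude
#'
#' Elementwise Euclidean norm of the three accelerometer axes,
#' `sqrt(ax^2 + ay^2 + az^2)`. Being a vector magnitude it is independent of
#' sensor placement: any rotation or axis permutation of the accelerometer
#' frame leaves it unchanged.
#'
#' @param ax,ay,az equal-length accelerometer channels, m/s^2.
#' @return per-sample magnitude, m/s^2 (non-negative).
#' @examples
#' totalAcceleration(3, 4, 0) # 5
#' @export
totalAcceleration <- function(ax, ay, az) {
  if (length(ax) != length(ay) || length(ay) != length(az))
    stop("input error: accelerometer channels must have equal length",
         call. = FALSE)
  sqrt(ax^2 + ay^2 + az^2)
}

#' Exerted force
#'
#' Newton's second law applied per sample: the force exerted to move the
#' dumbbell is its mass times the acceleration magnitude, `F = m * a`.
#'
#' @param mass dumbbell mass in kg (positive).
#' @param accel per-sample acceleration, m/s^2 (typically
#'   [totalAcceleration()]).
#' @return per-sample force, N.
#' @examples
#' exertedForce(4.5, 2) # 9
#' @export
exertedForce <- function(mass, accel) {
  if (!is.numeric(mass) || length(mass) != 1L || is.na(mass) || mass <= 0)
    stop("input error: mass must be a positive scalar", call. = FALSE)
  mass * accel
}

#' Append the derived signals to a session
#'
#' Adds `total_acceleration` and `exerted_force` columns to the session's
#' sample table (using the session's dumbbell mass), leaving everything else
#' untouched. Idempotent.
#'
#' @param session a [CurlSession].
#' @return the session with both derived columns present.
#' @export
addDerivedSignals <- function(session) {
  stopifnot(is(session, "CurlSession"))
  s <- session@samples
  s$total_acceleration <- totalAcceleration(s$acc_x, s$acc_y, s$acc_z)
  s$exerted_force <- exertedForce(dumbbellMass(session), s$total_acceleration)
  session@samples <- s
  session
}
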