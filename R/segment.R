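#' @include AllClasses.R
NULL

#' Segment a session into individual repetitions
#'
#' Within each set boundary independently, the chosen channel is smoothed
#' with a centred moving average and its peaks (contraction positions) are
#' located; the troughs between consecutive peaks (release positions) define
#' the repetition boundaries, so each repetition is a trough-to-trough slice
#' containing exactly one peak. The first and last repetitions of a set are
#' closed by the set boundary itself.
#'
#' @param session a [CurlSession].
#' @param channel channel to segment on; `"acc_y"` (sideways hand vibration)
#'   by default.
#' @param smoothingWindow moving-average width, seconds.
#' @param minSeparation minimum peak-to-peak separation, seconds.
#' @param prominenceFraction a peak must rise above the set minimum by at
#'   least this fraction of the set's signal range.
#' @return data.frame with one row per repetition: `subject_id`, `arm`,
#'   `set_index` (0 = warm-up), `rep_index`, `start`, `end` (0-based
#'   half-open sample indices), `duration` (seconds), in temporal order.
#'   A flat or degenerate set contributes zero repetitions and a warning.
#' @export
detectRepetitions <- function(session, channel = "acc_y",
                              smoothingWindow = 0.3, minSeparation = 1.0,
                              prominenceFraction = 0.2) {
  stopifnot(is(session, "CurlSession"))
  s <- sensorData(session)
  if (!channel %in% names(s))
    stop("input error: channel '", channel, "' not present", call. = FALSE)
  if (nrow(s) == 0L) stop("input error: empty session", call. = FALSE)
  fs <- samplingRate(session)
  bnds <- setBoundaries(session)
  out <- list()
  for (k in seq_len(nrow(bnds))) {
    s0 <- bnds[k, 1L]; e0 <- bnds[k, 2L]
    x <- s[[channel]][(s0 + 1L):e0]
    sm <- movingAverage(x, round(smoothingWindow * fs))
    rng <- diff(range(sm))
    if (!is.finite(rng) || rng <= .Machine$double.eps^0.5) {
      warning("set ", k - 1L, ": flat '", channel,
              "' signal, no repetitions detected", call. = FALSE)
      next
    }
    pk <- pracma::findpeaks(sm,
                            minpeakdistance = max(1L, round(minSeparation * fs)),
                            minpeakheight = min(sm) + prominenceFraction * rng)
    if (is.null(pk)) {
      warning("set ", k - 1L, ": no prominent peaks on '", channel,
              "', no repetitions detected", call. = FALSE)
      next
    }
    peaks <- sort(pk[, 2L])
    cuts <- integer(0)
    if (length(peaks) > 1L)
      cuts <- vapply(seq_len(length(peaks) - 1L), function(i) {
        span <- peaks[i]:peaks[i + 1L]
        span[which.min(sm[span])]
      }, integer(1L))
    rel <- c(1L, cuts, length(x) + 1L)          # 1-based slice boundaries
    starts <- s0 + rel[-length(rel)] - 1L       # back to 0-based absolute
    ends <- s0 + rel[-1L] - 1L
    out[[length(out) + 1L]] <- data.frame(
      subject_id = subjectId(session), arm = arm(session),
      set_index = k - 1L, rep_index = seq_along(starts) - 1L,
      start = starts, end = ends, duration = (ends - starts) / fs,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(subject_id = character(), arm = character(),
                      set_index = integer(), rep_index = integer(),
                      start = integer(), end = integer(),
                      duration = numeric()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-set completion time relative to the first main set
#'
#' Mean repetition duration per main set and its percentage increase over
#' the first main set, `100 * (mean_k - mean_1) / mean_1`, plus the average
#' increase across sets 2..n. Longer completion times in later sets are the
#' kinematic signature of accumulating fatigue.
#'
#' @param reps repetition table from [detectRepetitions()] (or ground truth
#'   with `duration` added). Warm-up (set 0) is ignored.
#' @return list with `perSet` (data.frame: `set_index`, `n_reps`,
#'   `mean_duration`, `pct_increase`; `NA` entries flag empty sets) and
#'   `average` (mean increase over sets 2..n).
#' @export
completionTimeTable <- function(reps) {
  main <- reps[reps$set_index >= 1L, , drop = FALSE]
  if (!"duration" %in% names(main))
    stop("input error: reps need a 'duration' column", call. = FALSE)
  if (!any(main$set_index == 1L))
    stop("input error: no repetitions in the first main set", call. = FALSE)
  sets <- seq_len(max(main$set_index))
  perSet <- data.frame(
    set_index = sets,
    n_reps = vapply(sets, function(k) sum(main$set_index == k), integer(1L)),
    mean_duration = vapply(sets, function(k) {
      d <- main$duration[main$set_index == k]
      if (length(d)) mean(d) else NA_real_
    }, numeric(1L)))
  ref <- perSet$mean_duration[perSet$set_index == 1L]
  perSet$pct_increase <- ifelse(perSet$set_index == 1L, NA_real_,
                                100 * (perSet$mean_duration - ref) / ref)
  list(perSet = perSet,
       average = averageSetChange(perSet$pct_increase[perSet$set_index > 1L]))
}

#' Per-set endurance change relative to the first main set
#'
#' Muscular endurance is tracked as the mean peak-to-trough amplitude of a
#' gyroscope channel per repetition (angular-velocity swing); its percentage
#' change versus the first main set shrinks as fatigue sets in.
#'
#' @param session the [CurlSession] the repetitions came from.
#' @param reps repetition table from [detectRepetitions()].
#' @param channel channel whose amplitude is tracked (default `"gyr_z"`).
#' @param smoothingWindow moving-average width in seconds applied before
#'   measuring the amplitude, to keep sensor noise out of the extrema.
#' @return list with `perSet` (data.frame: `set_index`, `n_reps`,
#'   `mean_amplitude`, `pct_change`) and `average` over sets 2..n.
#' @export
enduranceChangeTable <- function(session, reps, channel = "gyr_z",
                                 smoothingWindow = 0.3) {
  stopifnot(is(session, "CurlSession"))
  s <- sensorData(session)
  if (!channel %in% names(s))
    stop("input error: channel '", channel, "' not present", call. = FALSE)
  sm <- movingAverage(s[[channel]], round(smoothingWindow * samplingRate(session)))
  main <- reps[reps$set_index >= 1L, , drop = FALSE]
  if (!any(main$set_index == 1L))
    stop("input error: no repetitions in the first main set", call. = FALSE)
  amp <- vapply(seq_len(nrow(main)), function(i) {
    seg <- sm[(main$start[i] + 1L):main$end[i]]
    diff(range(seg))
  }, numeric(1L))
  sets <- seq_len(max(main$set_index))
  perSet <- data.frame(
    set_index = sets,
    n_reps = vapply(sets, function(k) sum(main$set_index == k), integer(1L)),
    mean_amplitude = vapply(sets, function(k) {
      a <- amp[main$set_index == k]
      if (length(a)) mean(a) else NA_real_
    }, numeric(1L)))
  ref <- perSet$mean_amplitude[perSet$set_index == 1L]
  perSet$pct_change <- ifelse(perSet$set_index == 1L, NA_real_,
                              100 * (perSet$mean_amplitude - ref) / ref)
  list(perSet = perSet,
       average = averageSetChange(perSet$pct_change[perSet$set_index > 1L]))
}

#' Average a row of per-set percentage changes
#'
#' The across-set summary used by the completion-time and endurance tables:
#' the arithmetic mean of the per-set percentage cells, ignoring missing
#' sets.
#'
#' @param changes numeric vector of per-set percentage changes.
#' @return the mean change (percent).
#' @export
averageSetChange <- function(changes) {
  if (all(is.na(changes))) return(NA_real_)
  mean(changes, na.rm = TRUE)
}
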