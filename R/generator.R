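#' @include AllClasses.R
NULL

# Fixed pulse amplitudes of the synthetic curl waveform, per channel.
# Gyroscope in deg/s, accelerometer in m/s^2 (gravity-removed by
# construction), magnetometer coupling in uT on top of a static baseline.
.CHANNEL_AMP <- c(acc_x = 0.8, acc_y = 3.0, acc_z = 1.2,
                  gyr_x = 120, gyr_y = 25, gyr_z = 80)
.MAG_BASE <- c(mag_x = 21, mag_y = -12, mag_z = 40)
.MAG_COUPLING <- c(mag_x = 0.5, mag_y = 1.0, mag_z = 2.0)
.VALLEY_DEPTH <- 0.05   # inter-rep valley depth, fraction of pulse amplitude

#' Synthetic-cohort generator configuration
#'
#' Defines the study conditions emulated by the generator: 20 subjects, two
#' arms each, a 5-rep warm-up set plus five 15-rep main sets at 50 Hz, with
#' per-set completion-time inflation and gyroscope-amplitude (muscular
#' endurance) change relative to the first main set, a Borg-RPE trajectory
#' rising from the warm-up range to the final range, and a heart-rate track
#' that follows ten times the instantaneous RPE.
#'
#' @param nSubjects,armsPerSubject,warmupReps,nSets,repsPerSet protocol
#'   counts (defaults 20, 2, 5, 5, 15).
#' @param samplingRate IMU sampling frequency in Hz (default 50).
#' @param baseRepDuration full trough-to-trough duration of a first-set
#'   repetition in seconds (default 2.0, i.e. ~100 samples at 50 Hz). The
#'   inter-rep valley is part of this span.
#' @param dumbbellMass mass lifted, kg (default 4.5).
#' @param setTimeInflation fractional completion-time increase of main sets
#'   2..nSets relative to set 1 (length `nSets - 1`).
#' @param enduranceChange fractional gyroscope-amplitude change of main sets
#'   2..nSets relative to set 1 (length `nSets - 1`).
#' @param fatigueSkew waveform asymmetry/peakedness parameter (> 0 gives
#'   fatigued repetitions a positively skewed sample distribution).
#' @param warmupRPERange,finalRPERange integer Borg ranges for the RPE
#'   reported after the warm-up and after the final set.
#' @param withinSetRise Borg units by which true RPE rises within one set
#'   (capped so the trajectory never decreases between sets).
#' @param hrNoiseSD per-sample heart-rate noise, bpm.
#' @param hrCap heart-rate monitor ceiling, bpm (at most 210).
#' @param interRepGap duration of the inter-rep valley, seconds.
#' @param channelNoiseSD additive noise scale per sensor group, named
#'   `c(acc=, gyr=, mag=)` in channel units.
#' @param interSetRest rest between sets, seconds.
#' @param durationJitterSD,amplitudeJitterSD lognormal per-rep jitter scales.
#' @param subjectAmplitudeSD,subjectDurationSD lognormal between-subject
#'   strength and tempo variation.
#' @param seed integer cohort seed; per-session seeds are derived from it.
#' @return a validated list of class `"GeneratorConfig"`.
#' @export
generatorConfig <- function(nSubjects = 20L, armsPerSubject = 2L,
                            warmupReps = 5L, nSets = 5L, repsPerSet = 15L,
                            samplingRate = 50, baseRepDuration = 2.0,
                            dumbbellMass = 4.5,
                            setTimeInflation = c(0.017, 0.081, 0.143, 0.310),
                            enduranceChange = c(0.006, 0.011, -0.055, -0.041),
                            fatigueSkew = 0.8,
                            warmupRPERange = c(10L, 12L),
                            finalRPERange = c(17L, 20L),
                            withinSetRise = 0.9,
                            hrNoiseSD = 3, hrCap = 210,
                            interRepGap = 0.5,
                            channelNoiseSD = c(acc = 0.1, gyr = 3, mag = 0.4),
                            interSetRest = 3.0,
                            durationJitterSD = 0.02, amplitudeJitterSD = 0.02,
                            subjectAmplitudeSD = 0.10, subjectDurationSD = 0.05,
                            seed = 101L) {
  cfg <- list(nSubjects = as.integer(nSubjects),
              armsPerSubject = as.integer(armsPerSubject),
              warmupReps = as.integer(warmupReps), nSets = as.integer(nSets),
              repsPerSet = as.integer(repsPerSet),
              samplingRate = samplingRate,
              baseRepDuration = baseRepDuration, dumbbellMass = dumbbellMass,
              setTimeInflation = setTimeInflation,
              enduranceChange = enduranceChange, fatigueSkew = fatigueSkew,
              warmupRPERange = as.integer(warmupRPERange),
              finalRPERange = as.integer(finalRPERange),
              withinSetRise = withinSetRise,
              hrNoiseSD = hrNoiseSD, hrCap = hrCap,
              interRepGap = interRepGap, channelNoiseSD = channelNoiseSD,
              interSetRest = interSetRest,
              durationJitterSD = durationJitterSD,
              amplitudeJitterSD = amplitudeJitterSD,
              subjectAmplitudeSD = subjectAmplitudeSD,
              subjectDurationSD = subjectDurationSD,
              seed = as.integer(seed))
  class(cfg) <- "GeneratorConfig"
  validateGeneratorConfig(cfg)
  cfg
}

#' @keywords internal
validateGeneratorConfig <- function(cfg) {
  stopIfNot(inherits(cfg, "GeneratorConfig"), "not a GeneratorConfig")
  for (fld in c("nSubjects", "armsPerSubject", "warmupReps", "nSets",
                "repsPerSet"))
    stopIfNot(isCount(cfg[[fld]]),
              paste0("configuration error: ", fld, " must be a count >= 1"))
  stopIfNot(cfg$samplingRate > 0,
            "configuration error: samplingRate must be positive")
  stopIfNot(length(cfg$setTimeInflation) == cfg$nSets - 1L,
            "configuration error: setTimeInflation must have length nSets - 1")
  stopIfNot(length(cfg$enduranceChange) == cfg$nSets - 1L,
            "configuration error: enduranceChange must have length nSets - 1")
  for (fld in c("warmupRPERange", "finalRPERange")) {
    r <- cfg[[fld]]
    stopIfNot(length(r) == 2L && r[1L] <= r[2L] && r[1L] >= 6L && r[2L] <= 20L,
              paste0("configuration error: ", fld,
                     " must lie within the Borg scale [6, 20]"))
  }
  stopIfNot(cfg$hrCap <= 210,
            "configuration error: hrCap exceeds the 210 bpm monitor limit")
  stopIfNot(cfg$interRepGap >= 0 &&
              cfg$interRepGap < cfg$baseRepDuration,
            "configuration error: interRepGap must be shorter than a rep")
  stopIfNot(all(c("acc", "gyr", "mag") %in% names(cfg$channelNoiseSD)),
            "configuration error: channelNoiseSD needs acc/gyr/mag entries")
  invisible(TRUE)
}

# Per-set true-RPE endpoints for one subject: set ends are the integer Borg
# values the subject reports (linear warm-up -> final, rounded), and each
# set starts `withinSetRise` below its end, never below the previous end.
#' @keywords internal
rpeSetEndpoints <- function(cfg, warmupRPE, finalRPE) {
  n <- cfg$nSets
  ends <- round(warmupRPE + (finalRPE - warmupRPE) * (0:n) / n)
  starts <- numeric(n + 1L)
  starts[1L] <- max(ends[1L] - cfg$withinSetRise, cfg$warmupRPERange[1L])
  for (k in seq_len(n))
    starts[k + 1L] <- max(ends[k + 1L] - cfg$withinSetRise, ends[k])
  data.frame(set_index = 0:n, start = starts, end = as.numeric(ends))
}

#' True per-repetition RPE trajectory for one set
#'
#' Returns the ground-truth Borg RPE assigned to each repetition of the given
#' set: linear within the set from the set-start value to the integer set-end
#' value the subject reports, monotone non-decreasing across the session.
#'
#' @param config a [generatorConfig()].
#' @param setIndex 0-based set index (0 = warm-up).
#' @param subjectOffset number in `[0, 1]` placing the subject within the
#'   warm-up and final RPE ranges (0 = lower bound of both).
#' @return numeric vector, one Borg value per repetition of that set.
#' @export
rpeTrajectory <- function(config, setIndex, subjectOffset = 0.5) {
  validateGeneratorConfig(config)
  stopIfNot(setIndex >= 0 && setIndex <= config$nSets,
            "setIndex out of range")
  stopIfNot(subjectOffset >= 0 && subjectOffset <= 1,
            "subjectOffset must be in [0, 1]")
  w <- config$warmupRPERange[1L] +
    round(subjectOffset * diff(config$warmupRPERange))
  f <- config$finalRPERange[1L] +
    round(subjectOffset * diff(config$finalRPERange))
  ep <- rpeSetEndpoints(config, w, f)
  m <- if (setIndex == 0L) config$warmupReps else config$repsPerSet
  row <- ep[ep$set_index == setIndex, ]
  if (m == 1L) return(row$end)
  row$start + (row$end - row$start) * (seq_len(m) - 1L) / (m - 1L)
}

# Unit repetition waveform: half-valley, raised-cosine pulse (rise fraction
# `rise`, sharpened by `power`), half-valley. Peak value 1, valley -depth.
#' @keywords internal
repShape <- function(nSamples, gapSamples, rise = 0.5, power = 1,
                     depth = .VALLEY_DEPTH) {
  h <- max(1L, round(gapSamples / 2))
  nPulse <- nSamples - 2L * h
  if (nPulse < 4L) return(rep(0, nSamples))
  u <- (seq_len(h) - 1L) / h
  valleyIn <- -depth * 0.5 * (1 + cos(pi * u))
  tau <- (seq_len(nPulse) - 0.5) / nPulse
  base <- ifelse(tau < rise,
                 0.5 * (1 - cos(pi * tau / rise)),
                 0.5 * (1 + cos(pi * (tau - rise) / (1 - rise))))
  pulse <- base^power
  c(valleyIn, pulse, rev(valleyIn))
}

# Map true RPE to a fatigue intensity in [0, 1] driving waveform asymmetry.
#' @keywords internal
fatigueIntensity <- function(trueRPE) clamp((trueRPE - 14) / 6, 0, 1)

#' Generate one synthetic concentration-curl session
#'
#' Produces a [CurlSession] with smooth per-repetition pulse waveforms on the
#' motion channels, per-set completion-time inflation and gyroscope-amplitude
#' change as configured, positively skewed pulses for fatigued repetitions, a
#' heart-rate track following ten times the instantaneous true RPE, and the
#' per-set reported Borg RPE; plus the per-repetition ground truth.
#'
#' @param config a [generatorConfig()].
#' @param subjectId,arm identifiers for the session.
#' @param seed integer seed for this session (`NULL` = use the current RNG
#'   state).
#' @return list with elements `session` ([CurlSession]) and `groundTruth`
#'   (data.frame: `subject_id`, `arm`, `set_index`, `rep_index`,
#'   `start_sample`, `end_sample`, `true_rpe`, `is_fatigued`; sample indices
#'   0-based half-open).
#' @export
generateSession <- function(config, subjectId = "S01", arm = "right",
                            seed = NULL) {
  validateGeneratorConfig(config)
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  fs <- config$samplingRate
  nSets <- config$nSets

  subjAmp <- exp(stats::rnorm(1, 0, config$subjectAmplitudeSD))
  subjDur <- exp(stats::rnorm(1, 0, config$subjectDurationSD))
  offset <- stats::runif(1)
  w <- config$warmupRPERange[1L] + round(offset * diff(config$warmupRPERange))
  f <- config$finalRPERange[1L] + round(offset * diff(config$finalRPERange))
  ep <- rpeSetEndpoints(config, w, f)

  leadN <- round(1.0 * fs)
  restN <- round(config$interSetRest * fs)
  gapN <- round(config$interRepGap * fs)

  timeFactor <- c(1, 1, 1 + config$setTimeInflation)      # sets 0..nSets
  gyroFactor <- c(1, 1, 1 + config$enduranceChange)

  boundaries <- matrix(integer(0), ncol = 2L)
  gt <- list()
  rpeNodes <- data.frame(idx = 0, rpe = ep$start[1L])   # sample index, value
  cursor <- leadN

  # unit waveform segments; channel amplitudes are applied afterwards
  segments <- list(rep(0, leadN))
  segGyro <- list(rep(1, leadN))
  segJit <- list(rep(1, leadN))

  for (k in 0:nSets) {
    m <- if (k == 0L) config$warmupReps else config$repsPerSet
    traj <- {
      row <- ep[ep$set_index == k, ]
      if (m == 1L) row$end
      else row$start + (row$end - row$start) * (seq_len(m) - 1L) / (m - 1L)
    }
    setStart <- cursor
    rpeNodes <- rbind(rpeNodes, data.frame(idx = setStart, rpe = ep$start[k + 1L]))
    for (j in seq_len(m)) {
      d <- config$baseRepDuration * timeFactor[k + 1L] * subjDur *
        exp(stats::rnorm(1, 0, config$durationJitterSD))
      nD <- max(round(d * fs), gapN + 8L)
      kInt <- fatigueIntensity(traj[j])
      shp <- repShape(nD, gapN,
                      rise = 0.5 - 0.15 * kInt,
                      power = 1 + config$fatigueSkew * kInt,
                      depth = .VALLEY_DEPTH)
      segments[[length(segments) + 1L]] <- shp
      segGyro[[length(segGyro) + 1L]] <- rep(gyroFactor[k + 1L], nD)
      segJit[[length(segJit) + 1L]] <-
        rep(exp(stats::rnorm(1, 0, config$amplitudeJitterSD)), nD)
      gt[[length(gt) + 1L]] <- data.frame(
        subject_id = subjectId, arm = arm, set_index = k, rep_index = j - 1L,
        start_sample = cursor, end_sample = cursor + nD,
        true_rpe = traj[j], is_fatigued = traj[j] >= 17,
        stringsAsFactors = FALSE)
      cursor <- cursor + nD
    }
    boundaries <- rbind(boundaries, c(setStart, cursor))
    rpeNodes <- rbind(rpeNodes, data.frame(idx = cursor, rpe = ep$end[k + 1L]))
    nPad <- if (k == nSets) leadN else restN
    segments[[length(segments) + 1L]] <- rep(0, nPad)
    segGyro[[length(segGyro) + 1L]] <- rep(1, nPad)
    segJit[[length(segJit) + 1L]] <- rep(1, nPad)
    cursor <- cursor + nPad
  }

  shape <- unlist(segments, use.names = FALSE)
  gyroScale <- unlist(segGyro, use.names = FALSE)
  ampJitter <- unlist(segJit, use.names = FALSE)
  n <- length(shape)

  nsd <- config$channelNoiseSD
  samples <- data.frame(t = (seq_len(n) - 1L) / fs)
  for (ch in names(.CHANNEL_AMP)) {
    grp <- substr(ch, 1L, 3L)
    scale <- if (grp == "gyr") gyroScale else 1
    samples[[ch]] <- .CHANNEL_AMP[[ch]] * subjAmp * ampJitter * scale * shape +
      stats::rnorm(n, 0, nsd[[grp]])
  }
  for (ch in c("mag_x", "mag_y", "mag_z")) {
    period <- stats::runif(1, 60, 120) * fs
    phase <- stats::runif(1, 0, 2 * pi)
    drift <- 0.8 * sin(2 * pi * seq_len(n) / period + phase)
    samples[[ch]] <- .MAG_BASE[[ch]] + drift +
      .MAG_COUPLING[[ch]] * subjAmp * shape + stats::rnorm(n, 0, nsd[["mag"]])
  }
  samples <- samples[c("t", IMU_CHANNELS)]

  # Heart rate tracks 10 x the instantaneous true RPE, piecewise linear
  # through the set start/end nodes, plus monitor noise, clipped to the cap.
  rpeNodes <- rpeNodes[!duplicated(rpeNodes$idx), ]
  rpeTrack <- stats::approx(rpeNodes$idx, rpeNodes$rpe, xout = seq_len(n) - 1L,
                            rule = 2)$y
  samples$heart_rate <- clamp(10 * rpeTrack + stats::rnorm(n, 0, config$hrNoiseSD),
                              30, config$hrCap)

  session <- CurlSession(subjectId = subjectId, arm = arm, samplingRate = fs,
                         samples = samples, setBoundaries = boundaries,
                         reportedRPE = as.integer(ep$end),
                         dumbbellMass = config$dumbbellMass)
  groundTruth <- do.call(rbind, gt)
  list(session = session, groundTruth = groundTruth)
}

#' Generate a full synthetic cohort
#'
#' One session per subject and arm, with per-session seeds derived from the
#' cohort seed by a counter so that enlarging the cohort never perturbs
#' already-generated sessions.
#'
#' @param config a [generatorConfig()].
#' @return list of `list(session=, groundTruth=)`, one element per
#'   subject-arm, named `"<subject>_<arm>"`; the configuration is attached as
#'   attribute `"config"`.
#' @export
generateCohort <- function(config = generatorConfig()) {
  validateGeneratorConfig(config)
  arms <- c("right", "left")[seq_len(min(config$armsPerSubject, 2L))]
  if (config$armsPerSubject > 2L)
    arms <- c(arms, paste0("right", seq_len(config$armsPerSubject - 2L)))
  out <- list()
  for (s in seq_len(config$nSubjects)) {
    sid <- sprintf("S%02d", s)
    for (a in seq_along(arms)) {
      counter <- (s - 1L) * 8L + a
      childSeed <- (config$seed + 104729L * counter) %% .Machine$integer.max
      out[[paste0(sid, "_", arms[a])]] <-
        generateSession(config, subjectId = sid, arm = arms[a],
                        seed = childSeed)
    }
  }
  attr(out, "config") <- config
  out
}

#' Pool the ground truth of a cohort into one table
#'
#' @param cohort result of [generateCohort()].
#' @return data.frame with one row per ground-truth repetition.
#' @export
groundTruthTable <- function(cohort) {
  do.call(rbind, c(lapply(cohort, `[[`, "groundTruth"),
                   list(make.row.names = FALSE)))
}
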