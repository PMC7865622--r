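test_that("repetition boundaries are recovered on an analytic waveform", {
  # ten noiseless raised-cosine repetitions of exactly 100 samples each:
  # troughs (hence boundaries) sit at multiples of 100
  fs <- 50
  period <- 100L
  nRep <- 10L
  t <- seq_len(period * nRep) - 1L
  x <- 1 - cos(2 * pi * (t %% period) / period)
  sess <- syntheticSession(x, channel = "acc_y", fs = fs)
  reps <- detectRepetitions(sess)
  expect_equal(nrow(reps), nRep)
  truth <- seq(0L, period * nRep, by = period)
  expect_true(all(abs(reps$start - truth[-length(truth)]) <= 5))
  expect_true(all(abs(reps$end - truth[-1]) <= 5))
  expect_equal(reps$set_index, rep(0L, nRep))
  expect_equal(reps$rep_index, 0:(nRep - 1L))
  expect_equal(reps$duration, (reps$end - reps$start) / fs)
})

test_that("segmentation of a generated session matches ground truth", {
  res <- generateSession(generatorConfig(), "S01", "right", seed = 42L)
  reps <- detectRepetitions(res$session)
  gt <- res$groundTruth
  expect_equal(nrow(reps), nrow(gt))          # all 80 repetitions found
  expect_equal(reps$set_index, gt$set_index)
  expect_true(all(abs(reps$start - gt$start_sample) <= 5))
  expect_true(all(abs(reps$end - gt$end_sample) <= 5))
})

test_that("flat or missing signals are handled explicitly", {
  sess <- syntheticSession(rep(0, 300))
  expect_warning(reps <- detectRepetitions(sess), "flat")
  expect_equal(nrow(reps), 0L)
  sess2 <- syntheticSession(1 - cos(2 * pi * seq(0, 6, length.out = 300)))
  expect_error(detectRepetitions(sess2, channel = "nope"), "not present")
})

test_that("completionTimeTable computes per-set increases and their mean", {
  reps <- data.frame(set_index = rep(1:3, each = 4),
                     duration = rep(c(2.0, 2.2, 2.5), each = 4))
  tab <- completionTimeTable(reps)
  expect_equal(tab$perSet$mean_duration, c(2.0, 2.2, 2.5))
  expect_true(is.na(tab$perSet$pct_increase[1]))
  expect_equal(tab$perSet$pct_increase[2:3], c(10, 25))
  expect_equal(tab$average, 17.5)
  # warm-up (set 0) must be ignored
  withWarm <- rbind(data.frame(set_index = 0L, duration = 99), reps)
  expect_equal(completionTimeTable(withWarm)$average, 17.5)
  expect_error(completionTimeTable(data.frame(set_index = 2L, duration = 1)),
               "first main set")
})

test_that("enduranceChangeTable tracks per-set amplitude change", {
  # two sets of noiseless repetitions whose amplitude halves in set 2
  period <- 100L
  oneSet <- function(amp, nRep)
    rep(amp * (1 - cos(2 * pi * (seq_len(period) - 1) / period)), nRep)
  x <- c(oneSet(10, 3), oneSet(5, 3))
  bnds <- matrix(c(0L, 300L, 300L, 600L), ncol = 2, byrow = TRUE)
  sess <- syntheticSession(x, channel = "gyr_z", boundaries = bnds,
                           reportedRPE = c(12L, 14L))
  reps <- detectRepetitions(sess, channel = "gyr_z")
  # shift set indices so set 1 is the first main set
  reps$set_index <- reps$set_index + 1L
  tab <- enduranceChangeTable(sess, reps, channel = "gyr_z")
  expect_equal(tab$perSet$pct_change[2], -50, tolerance = 0.02)
  expect_equal(tab$average, tab$perSet$pct_change[2])
})

test_that("averageSetChange averages and propagates missingness", {
  expect_equal(averageSetChange(c(2, 6, 17, 33)), 14.5)
  expect_equal(averageSetChange(c(1, NA, 3)), 2)
  expect_true(is.na(averageSetChange(c(NA_real_, NA_real_))))
})
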