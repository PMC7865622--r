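test_that("generatorConfig validates its arguments", {
  expect_s3_class(generatorConfig(), "GeneratorConfig")
  expect_error(generatorConfig(nSubjects = 0L), "nSubjects")
  expect_error(generatorConfig(samplingRate = -50), "samplingRate")
  expect_error(generatorConfig(setTimeInflation = c(0.1, 0.2)), "setTimeInflation")
  expect_error(generatorConfig(enduranceChange = 1:2), "enduranceChange")
  expect_error(generatorConfig(warmupRPERange = c(12, 8)), "warmupRPERange")
})

test_that("a default session follows the study protocol", {
  res <- generateSession(generatorConfig(), "S01", "right", seed = 42L)
  sess <- res$session
  gt <- res$groundTruth

  # 1 warm-up set + 5 main sets; 5 + 5x15 = 80 repetitions
  expect_equal(nSets(sess), 6L)
  expect_equal(nrow(gt), 80L)
  expect_equal(sum(gt$set_index >= 1L), 75L)
  expect_equal(as.integer(table(gt$set_index)), c(5L, rep(15L, 5L)))

  # ground-truth repetitions tile each set's boundary exactly
  bnds <- setBoundaries(sess)
  for (k in 0:5) {
    g <- gt[gt$set_index == k, ]
    expect_equal(g$start_sample[1], unname(bnds[k + 1, 1]))
    expect_equal(g$end_sample[nrow(g)], unname(bnds[k + 1, 2]))
    expect_equal(g$start_sample[-1], g$end_sample[-nrow(g)])
  }

  # a first-main-set repetition spans ~100 samples at 50 Hz (2.0 s)
  d1 <- with(gt[gt$set_index == 1L, ], end_sample - start_sample)
  expect_true(all(abs(d1 - 100) <= 8))

  # reported RPE: one integer per set, within the configured ranges,
  # non-decreasing
  rpe <- reportedRPE(sess)
  expect_length(rpe, 6L)
  expect_true(all(rpe == as.integer(rpe)))
  expect_gte(rpe[1], 8L); expect_lte(rpe[1], 12L)
  expect_gte(rpe[6], 17L); expect_lte(rpe[6], 20L)
  expect_true(all(diff(rpe) >= 0))

  # true RPE in ground truth is monotone within the session too
  expect_true(all(diff(gt$true_rpe) >= 0))
  expect_identical(gt$is_fatigued, gt$true_rpe >= 17)
})

test_that("set durations inflate according to setTimeInflation", {
  cfg <- generatorConfig()
  res <- generateSession(cfg, "S01", "right", seed = 42L)
  gt <- res$groundTruth
  meanDur <- vapply(1:5, function(k)
    mean(with(gt[gt$set_index == k, ], end_sample - start_sample)),
    numeric(1))
  obs <- 100 * (meanDur[2:5] - meanDur[1]) / meanDur[1]
  expect_true(all(abs(obs - 100 * cfg$setTimeInflation) <= 2))
})

test_that("heart rate tracks ten times the true RPE", {
  res <- generateSession(generatorConfig(), "S03", "left", seed = 9L)
  sess <- res$session
  gt <- res$groundTruth
  hr <- sensorData(sess)$heart_rate
  expect_true(all(hr >= 30 & hr <= 210))
  meanAbsErr <- mean(vapply(seq_len(nrow(gt)), function(i) {
    win <- (gt$start_sample[i] + 1L):gt$end_sample[i]
    abs(mean(hr[win]) - 10 * gt$true_rpe[i])
  }, numeric(1)))
  expect_lt(meanAbsErr, 10)
})

test_that("fatigued repetitions have positively skewed samples", {
  res <- generateSession(generatorConfig(), "S01", "right", seed = 42L)
  s <- sensorData(res$session)
  gt <- res$groundTruth
  skewOfSet <- function(k) {
    g <- gt[gt$set_index == k, ]
    mean(vapply(seq_len(nrow(g)), function(i)
      sampleSkewness(s$acc_y[(g$start_sample[i] + 1L):g$end_sample[i]]),
      numeric(1)))
  }
  # the final (fatigued) set is more positively skewed than the first
  expect_gt(skewOfSet(5L), skewOfSet(1L))
})

test_that("generation is deterministic and seed-sensitive", {
  cfg <- generatorConfig()
  a <- generateSession(cfg, "S01", "right", seed = 5L)
  b <- generateSession(cfg, "S01", "right", seed = 5L)
  c_ <- generateSession(cfg, "S01", "right", seed = 6L)
  expect_identical(sensorData(a$session), sensorData(b$session))
  expect_identical(a$groundTruth, b$groundTruth)
  expect_false(identical(sensorData(a$session), sensorData(c_$session)))
})

test_that("enlarging a cohort does not perturb earlier sessions", {
  small <- generateCohort(smallConfig(nSubjects = 2L))
  large <- generateCohort(smallConfig(nSubjects = 3L))
  expect_identical(names(small), c("S01_right", "S02_right"))
  expect_identical(sensorData(small$S01_right$session),
                   sensorData(large$S01_right$session))
  expect_identical(sensorData(small$S02_right$session),
                   sensorData(large$S02_right$session))
})

test_that("groundTruthTable pools every session's ground truth", {
  coh <- generateCohort(smallConfig())
  gt <- groundTruthTable(coh)
  expect_equal(nrow(gt), 2L * 80L)
  expect_setequal(unique(gt$subject_id), c("S01", "S02"))
})

test_that("sessions survive a CSV/JSON round trip", {
  sess <- sessionFixture()
  dir <- tempfile("io_"); dir.create(dir)
  csv <- file.path(dir, "S01_right.csv")
  writeSession(sess, csv)
  back <- readSession(csv)
  expect_identical(subjectId(back), subjectId(sess))
  expect_identical(arm(back), arm(sess))
  expect_equal(samplingRate(back), samplingRate(sess))
  expect_equal(setBoundaries(back), setBoundaries(sess))
  expect_identical(reportedRPE(back), reportedRPE(sess))
  expect_equal(dumbbellMass(back), dumbbellMass(sess))
  expect_equal(sensorData(back)$acc_y, sensorData(sess)$acc_y,
               tolerance = 1e-10)
  unlink(dir, recursive = TRUE)
})
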