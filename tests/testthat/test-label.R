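test_that("hrToRPE divides by ten and rejects bad input", {
  expect_equal(hrToRPE(145), 14.5)
  expect_equal(hrToRPE(c(60, 210)), c(6, 21))
  expect_error(hrToRPE(0), "positive")
  expect_error(hrToRPE(-10), "positive")
  expect_error(hrToRPE(NA_real_), "positive")
})

test_that("isDivergent uses a strict inequality at the tolerance", {
  expect_true(isDivergent(17, 145))        # |170 - 145| = 25 > 10
  expect_false(isDivergent(15, 160))       # exactly 10: convergent
  expect_false(isDivergent(15, 150))
  expect_true(isDivergent(15, 160.5))
  expect_false(isDivergent(15, 165, tolerance = 15))
  expect_equal(isDivergent(c(17, 15), c(145, 150)), c(TRUE, FALSE))
})

test_that("fuseRPE averages divergent pairs and rounds half-up", {
  # divergent: (17 + 14.5)/2 = 15.75 -> 16
  expect_identical(fuseRPE(17, 145), 16L)
  expect_equal(fuseRPE(17, 145, rounded = FALSE), 15.75)
  # convergent: reported value passes through
  expect_identical(fuseRPE(15, 150), 15L)
  expect_equal(fuseRPE(15, 150, rounded = FALSE), 15)
  # exact .5 rounds up, not to even: (16 + 13)/2 = 14.5 -> 15
  expect_identical(fuseRPE(16, 130), 15L)
  # clamped to the Borg scale
  expect_identical(fuseRPE(20, 250), 20L)
  expect_lte(fuseRPE(20, 300), 20L)
  # vectorized
  expect_identical(fuseRPE(c(17, 15), c(145, 150)), c(16L, 15L))
})

test_that("normalizeRPE rescales onto [0, 1] with max fixed at 20", {
  expect_equal(normalizeRPE(20, 8), 1)
  expect_equal(normalizeRPE(8, 8), 0)
  expect_equal(normalizeRPE(14, 8), 0.5)
  # values below the session minimum clip to 0
  expect_equal(normalizeRPE(7, 8), 0)
  expect_error(normalizeRPE(15, 20), "setMin")
  expect_error(normalizeRPE(15, 5), "setMin")
})

test_that("binarizeRPE splits the Borg scale at 17", {
  expect_identical(binarizeRPE(17), "fatigue")
  expect_identical(binarizeRPE(16), "non_fatigue")
  expect_identical(binarizeRPE(c(6, 16, 17, 20)),
                   c("non_fatigue", "non_fatigue", "fatigue", "fatigue"))
  expect_error(binarizeRPE(5), "out of range")
  expect_error(binarizeRPE(21), "out of range")
})

test_that("labelRepetitions fuses per-repetition heart rate with set RPE", {
  # constant heart rate exactly convergent with the reported RPE
  sess <- syntheticSession(rep(c(0, 1, 2, 1), 50), heartRate = 120,
                           reportedRPE = 12L)
  reps <- data.frame(subject_id = "X01", arm = "right", set_index = 0L,
                     rep_index = 0:1, start = c(0L, 100L),
                     end = c(100L, 200L), duration = 2)
  lab <- labelRepetitions(sess, reps)
  expect_identical(lab$reported_rpe, c(12L, 12L))
  expect_equal(lab$mean_hr, c(120, 120))
  expect_identical(lab$fused_rpe, c(12L, 12L))
  expect_equal(lab$normalized_rpe, rep((12 - 12) / (20 - 12), 2))
  expect_identical(lab$is_fatigued, c(FALSE, FALSE))
  expect_error(labelRepetitions(sess, reps[0, ]), "no repetitions")
})

test_that("generated cohorts keep the divergence rate below 10 percent", {
  fm <- featureMatrixFixture()
  cd <- SummarizedExperiment::colData(fm)
  divRate <- mean(isDivergent(cd$reported_rpe, cd$mean_hr))
  expect_lt(divRate, 0.10)
})
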