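test_that("confusionCounts and classificationMetrics match hand values", {
  truth <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  pred <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  cm <- confusionCounts(truth, pred)
  expect_equal(cm, c(tp = 2L, fp = 1L, fn = 1L, tn = 1L))
  m <- classificationMetrics(cm)
  expect_equal(unname(m["precision"]), 2 / 3)
  expect_equal(unname(m["recall"]), 2 / 3)
  expect_equal(unname(m["accuracy"]), 3 / 5)
  expect_equal(unname(m["f1"]), 2 / 3)
  expect_equal(unname(classificationMetrics(c(tp = 9, fp = 1, fn = 1,
                                              tn = 9))),
               rep(0.9, 4))
})

test_that("zero denominators yield NA metrics, never imputed values", {
  # no predicted positives: precision undefined
  m <- classificationMetrics(confusionCounts(c(TRUE, FALSE), c(FALSE, FALSE)))
  expect_true(is.na(m["precision"]))
  expect_false(is.na(m["recall"]))
  # no true positives in truth: recall undefined
  m2 <- classificationMetrics(confusionCounts(c(FALSE, FALSE), c(TRUE, FALSE)))
  expect_true(is.na(m2["recall"]))
})

test_that("metrics agree with brute-force counting on random labelings", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    truth <- runif(n) < runif(1)
    pred <- runif(n) < runif(1)
    cm <- confusionCounts(truth, pred)
    # brute force: walk every pair
    bf <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
    for (j in seq_len(n)) {
      key <- if (pred[j] && truth[j]) "tp" else if (pred[j]) "fp"
             else if (truth[j]) "fn" else "tn"
      bf[key] <- bf[key] + 1L
    }
    expect_identical(cm, bf)
    m <- classificationMetrics(cm)
    if (!is.na(m["accuracy"]))
      expect_equal(unname(m["accuracy"]), mean(truth == pred))
  }
})

test_that("stratifiedFolds balances both classes across folds", {
  set.seed(4)
  y <- rep(c(TRUE, FALSE), times = c(23, 52))
  fold <- curlfatigue:::stratifiedFolds(y, 5L)
  expect_length(fold, length(y))
  expect_setequal(unique(fold), 1:5)
  for (cls in c(TRUE, FALSE)) {
    counts <- table(fold[y == cls])
    expect_lte(max(counts) - min(counts), 1L)
  }
})

test_that("cross-subject LOOCV holds out each subject exactly once", {
  fm <- featureMatrixFixture()
  feats <- c("gyr_x_mean", "gyr_z_sd", "acc_y_aad", "exerted_force_mean")
  specs <- defaultModelSpecs()[c("GLM", "DT")]
  rep_ <- crossSubjectLOOCV(fm, feats, specs)
  expect_s4_class(rep_, "EvalReport")
  expect_equal(protocol(rep_), "cross_subject")
  folds <- foldMetrics(rep_)
  subjects <- sort(unique(as.character(
    SummarizedExperiment::colData(fm)$subject_id)))
  # one fold per subject per model, each subject tested exactly once
  for (nm in names(specs)) {
    sub <- folds[folds$model == nm, ]
    expect_identical(sort(sub$subject), subjects)
    # fold test sizes sum to the full cohort: no repetition lost or reused
    expect_equal(sum(sub$tp + sub$fp + sub$fn + sub$tn), ncol(fm))
  }
  m <- evalMetrics(rep_)
  expect_true(all(m$accuracy >= 0 & m$accuracy <= 1, na.rm = TRUE))
})

test_that("subject-specific evaluation aggregates fold metrics per subject", {
  fm <- featureMatrixFixture()
  feats <- c("gyr_x_mean", "gyr_z_sd", "acc_y_aad")
  specs <- defaultModelSpecs()["GLM"]
  rep_ <- subjectSpecificEval(fm, feats, specs, kFolds = 5L, seed = 2L)
  expect_equal(protocol(rep_), "subject_specific")
  folds <- foldMetrics(rep_)
  # 2 subjects x 5 folds x 1 model
  expect_equal(nrow(folds), 10L)
  # every repetition of a subject is tested exactly once across its folds
  for (subj in unique(folds$subject)) {
    sub <- folds[folds$subject == subj, ]
    nSubj <- sum(SummarizedExperiment::colData(fm)$subject_id == subj)
    expect_equal(sum(sub$tp + sub$fp + sub$fn + sub$tn), nSubj)
  }
  # the report is reproducible for a fixed seed
  rep2 <- subjectSpecificEval(fm, feats, specs, kFolds = 5L, seed = 2L)
  expect_equal(evalMetrics(rep_), evalMetrics(rep2))
})

test_that("evaluation results do not depend on repetition column order", {
  fm <- featureMatrixFixture()
  set.seed(31)
  fmShuffled <- fm[, sample(ncol(fm))]
  feats <- c("gyr_x_mean", "gyr_z_sd")
  specs <- defaultModelSpecs()["GLM"]
  r1 <- crossSubjectLOOCV(fm, feats, specs)
  r2 <- crossSubjectLOOCV(fmShuffled, feats, specs)
  expect_equal(evalMetrics(r1), evalMetrics(r2))
  s1 <- subjectSpecificEval(fm, feats, specs, seed = 7L)
  s2 <- subjectSpecificEval(fmShuffled, feats, specs, seed = 7L)
  expect_equal(evalMetrics(s1), evalMetrics(s2))
})

test_that("writeEvalReport serializes JSON and CSV artifacts", {
  fm <- featureMatrixFixture()
  rep_ <- crossSubjectLOOCV(fm, c("gyr_x_mean", "gyr_z_sd"),
                            defaultModelSpecs()["GLM"])
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  writeEvalReport(rep_, jsonPath = jp, csvPath = cp)
  js <- jsonlite::read_json(jp)
  expect_equal(js$protocol, "cross_subject")
  expect_true("metrics" %in% names(js))
  csv <- utils::read.csv(cp)
  expect_identical(csv$model, "GLM")
  expect_true(csv$accuracy >= 0 && csv$accuracy <= 100)
  unlink(c(jp, cp))
})
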