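#' @include AllClasses.R
#' @include models.R
NULL

#' Confusion counts with fatigue as the positive class
#'
#' @param truth,pred logical vectors (`TRUE` = fatigue).
#' @return named integer vector `c(tp=, fp=, fn=, tn=)`.
#' @export
confusionCounts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  truth <- as.logical(truth); pred <- as.logical(pred)
  c(tp = sum(pred & truth), fp = sum(pred & !truth),
    fn = sum(!pred & truth), tn = sum(!pred & !truth))
}

#' Confusion-matrix metrics
#'
#' Accuracy `(tp+tn)/(tp+fp+fn+tn)`, precision `tp/(tp+fp)`, recall
#' `tp/(tp+fn)` and F1 `2PR/(P+R)`, with fatigue as the positive class. A
#' metric whose denominator is zero is reported as `NA` (undefined), never
#' imputed.
#'
#' @param cm named counts as from [confusionCounts()] (`tp`, `fp`, `fn`,
#'   `tn`).
#' @return named numeric vector `c(precision=, recall=, accuracy=, f1=)`.
#' @examples
#' classificationMetrics(c(tp = 9, fp = 1, fn = 1, tn = 9)) # all 0.9
#' @export
classificationMetrics <- function(cm) {
  tp <- cm[["tp"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]; tn <- cm[["tn"]]
  total <- tp + fp + fn + tn
  accuracy <- if (total > 0) (tp + tn) / total else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  c(precision = precision, recall = recall, accuracy = accuracy, f1 = f1)
}

#' @keywords internal
stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    ix <- which(y == cls)
    ix <- sample(ix)
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

# Rows are put in a canonical order (subject, then repetition key) so that
# reports do not depend on the column order of the input experiment.
#' @keywords internal
fmDesign <- function(fm, featureNames) {
  mat <- t(SummarizedExperiment::assay(fm, "features")[featureNames, ,
                                                       drop = FALSE])
  cd <- SummarizedExperiment::colData(fm)
  ord <- order(as.character(cd$subject_id), colnames(fm))
  list(X = mat[ord, , drop = FALSE], y = as.logical(cd$is_fatigued)[ord],
       subject = as.character(cd$subject_id)[ord])
}

#' @keywords internal
runFold <- function(spec, X, y, trainIdx, testIdx) {
  model <- trainModel(spec, X[trainIdx, , drop = FALSE], y[trainIdx])
  pred <- predictModel(model, X[testIdx, , drop = FALSE])
  cm <- confusionCounts(y[testIdx], pred$label)
  c(cm, classificationMetrics(cm))
}

#' Subject-specific evaluation
#'
#' For every subject independently (both arms pooled), a stratified k-fold
#' cross-validation over that subject's repetitions; fold metrics are
#' averaged per subject, then unweighted across subjects. Subjects with
#' fewer than `kFolds` repetitions of either class are skipped with a
#' warning. Undefined fold metrics are excluded from the averages.
#'
#' @param fm a [RepFeatureExperiment].
#' @param features character vector of feature names to use (e.g.
#'   [selectedFeatures()] of a [SelectionResult]).
#' @param specs named list of [modelSpec()] objects.
#' @param kFolds folds per subject (default 5).
#' @param seed seed for the fold assignment.
#' @return an [EvalReport] with protocol `"subject_specific"`.
#' @export
subjectSpecificEval <- function(fm, features, specs = defaultModelSpecs(),
                                kFolds = 5L, seed = 1L) {
  d <- fmDesign(fm, features)
  subjects <- sort(unique(d$subject))
  rows <- list()
  # draw every fold assignment up front so training (which seeds the RNG
  # itself) cannot influence the splits
  set.seed(seed)
  foldOf <- list()
  for (subj in subjects) {
    y <- d$y[d$subject == subj]
    if (min(table(factor(y, levels = c(FALSE, TRUE)))) < kFolds) {
      warning("subject ", subj, " skipped: fewer than ", kFolds,
              " repetitions of one class", call. = FALSE)
      next
    }
    foldOf[[subj]] <- stratifiedFolds(y, kFolds)
  }
  for (subj in names(foldOf)) {
    ix <- which(d$subject == subj)
    fold <- foldOf[[subj]]
    for (f in seq_len(kFolds)) {
      trainIdx <- ix[fold != f]; testIdx <- ix[fold == f]
      for (nm in names(specs)) {
        res <- runFold(specs[[nm]], d$X, d$y, trainIdx, testIdx)
        rows[[length(rows) + 1L]] <-
          data.frame(subject = subj, fold = f, model = nm, t(res))
      }
    }
  }
  if (!length(rows))
    stop("evaluation error: no eligible subjects", call. = FALSE)
  folds <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  metrics <- aggregateMetrics(folds, bySubject = TRUE)
  new("EvalReport", protocol = "subject_specific", metrics = metrics,
      folds = folds,
      config = list(features = features, kFolds = kFolds, seed = seed,
                    models = names(specs)))
}

#' Leave-one-subject-out cross-subject evaluation
#'
#' One fold per subject: train on all other subjects, test on the held-out
#' subject. Both arms of a subject always stay on the same side of every
#' split, so no subject's data can leak between train and test. Fold metrics
#' are averaged unweighted over folds; a test subject with a single class
#' yields partially undefined metrics, included as missing.
#'
#' @inheritParams subjectSpecificEval
#' @return an [EvalReport] with protocol `"cross_subject"`.
#' @export
crossSubjectLOOCV <- function(fm, features, specs = defaultModelSpecs()) {
  d <- fmDesign(fm, features)
  subjects <- sort(unique(d$subject))
  if (length(subjects) < 2L)
    stop("evaluation error: need at least 2 subjects", call. = FALSE)
  rows <- list()
  for (f in seq_along(subjects)) {
    testIdx <- which(d$subject == subjects[f])
    trainIdx <- which(d$subject != subjects[f])
    for (nm in names(specs)) {
      res <- runFold(specs[[nm]], d$X, d$y, trainIdx, testIdx)
      rows[[length(rows) + 1L]] <-
        data.frame(subject = subjects[f], fold = f, model = nm, t(res))
    }
  }
  folds <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  metrics <- aggregateMetrics(folds, bySubject = FALSE)
  new("EvalReport", protocol = "cross_subject", metrics = metrics,
      folds = folds,
      config = list(features = features, nFolds = length(subjects),
                    models = names(specs)))
}

# Unweighted mean over folds (and then subjects, for the subject-specific
# protocol); undefined (NA) fold metrics are excluded, not imputed.
#' @keywords internal
aggregateMetrics <- function(folds, bySubject) {
  cols <- c("precision", "recall", "accuracy", "f1")
  models <- unique(folds$model)
  out <- lapply(models, function(nm) {
    sub <- folds[folds$model == nm, , drop = FALSE]
    if (bySubject) {
      perSubj <- lapply(split(sub, sub$subject), function(ss)
        colMeans(ss[cols], na.rm = TRUE))
      vals <- colMeans(do.call(rbind, perSubj), na.rm = TRUE)
    } else {
      vals <- colMeans(sub[cols], na.rm = TRUE)
    }
    data.frame(model = nm, t(vals))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Serialize an evaluation report
#'
#' Writes the full report (protocol, per-model aggregates, per-fold
#' breakdown, configuration) as JSON and, optionally, the per-model metric
#' table as a CSV with percentages (rows = models, columns = precision,
#' recall, accuracy, F1).
#'
#' @param report an [EvalReport].
#' @param jsonPath JSON output path (`NULL` to skip).
#' @param csvPath CSV output path (`NULL` to skip).
#' @return invisibly, the written paths.
#' @export
writeEvalReport <- function(report, jsonPath = NULL, csvPath = NULL) {
  stopifnot(is(report, "EvalReport"))
  if (!is.null(jsonPath))
    jsonlite::write_json(
      list(protocol = protocol(report), metrics = evalMetrics(report),
           folds = foldMetrics(report), config = report@config),
      jsonPath, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(csvPath)) {
    m <- evalMetrics(report)
    for (col in c("precision", "recall", "accuracy", "f1"))
      m[[col]] <- round(100 * m[[col]], 1)
    utils::write.csv(m, csvPath, row.names = FALSE)
  }
  invisible(c(json = jsonPath, csv = csvPath))
}
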