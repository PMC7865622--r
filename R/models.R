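#' @include AllClasses.R
#' @include mlp.R
NULL

MODEL_FAMILIES <- c("GLM", "LR", "RF", "DT", "FNN")

#' Specify one classifier
#'
#' The five families evaluated by the pipeline, disambiguated as:
#' \describe{
#'   \item{GLM}{binomial generalized linear model with probit link, no
#'     regularization ([stats::glm()]).}
#'   \item{LR}{logistic regression (logit link) with L2/ridge penalty via
#'     [glmnet::glmnet()], penalty `1/n`.}
#'   \item{RF}{random forest, 100 trees, `sqrt(p)` candidate features per
#'     split ([randomForest::randomForest()]).}
#'   \item{DT}{CART decision tree with default cost-complexity
#'     ([rpart::rpart()]).}
#'   \item{FNN}{feed-forward neural network with two hidden layers (32, 16
#'     rectified-linear units), logistic output, early stopping on a 10
#'     percent validation split, at most 500 epochs.}
#' }
#'
#' @param family one of `"GLM"`, `"LR"`, `"RF"`, `"DT"`, `"FNN"`.
#' @param hyperparameters named list overriding family defaults.
#' @param seed integer seed making training deterministic.
#' @param standardize centre/scale features with training-set statistics
#'   before fitting (default `TRUE`; tree families are unaffected by it).
#' @return list of class `"ModelSpec"`.
#' @export
modelSpec <- function(family, hyperparameters = list(), seed = 1L,
                      standardize = TRUE) {
  family <- match.arg(family, MODEL_FAMILIES)
  defaults <- switch(family,
    GLM = list(),
    LR = list(lambdaScale = 1),
    RF = list(ntree = 100L),
    DT = list(),
    FNN = list(hidden = c(32L, 16L), maxEpochs = 500L, learningRate = 0.01,
               validationFraction = 0.1, patience = 25L))
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(family = family, hyperparameters = hp,
                 seed = as.integer(seed), standardize = isTRUE(standardize)),
            class = "ModelSpec")
}

#' The five default model specifications
#'
#' @param seed shared training seed.
#' @return named list of [modelSpec()] objects (GLM, LR, RF, DT, FNN).
#' @export
defaultModelSpecs <- function(seed = 1L) {
  out <- lapply(MODEL_FAMILIES, modelSpec, seed = seed)
  names(out) <- MODEL_FAMILIES
  out
}

#' Train a fatigue classifier
#'
#' @param spec a [modelSpec()].
#' @param features numeric matrix or data.frame, rows = repetitions,
#'   columns = (selected) features. No missing values.
#' @param labels logical (or coercible) fatigue labels, one per row; both
#'   classes must be present.
#' @return list of class `"TrainedModel"` carrying the fitted object, the
#'   feature list it was trained on, and the standardization statistics.
#' @export
trainModel <- function(spec, features, labels) {
  stopifnot(inherits(spec, "ModelSpec"))
  X <- as.matrix(features)
  y <- as.logical(labels)
  if (anyNA(X) || anyNA(y))
    stop("training error: missing values in features or labels",
         call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training error: training set contains a single class",
         call. = FALSE)
  if (spec$standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  } else {
    center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")
  hp <- spec$hyperparameters
  set.seed(spec$seed)
  fit <- switch(spec$family,
    GLM = {
      df <- data.frame(Xs, .y = y, check.names = FALSE)
      suppressWarnings(stats::glm(.y ~ ., data = df,
                                  family = stats::binomial("probit")))
    },
    LR = glmnet::glmnet(Xs, factor(y), family = "binomial", alpha = 0,
                        lambda = hp$lambdaScale / nrow(Xs),
                        standardize = FALSE),
    RF = randomForest::randomForest(Xs, factor(y), ntree = hp$ntree,
                                    mtry = max(1L, floor(sqrt(ncol(Xs))))),
    DT = rpart::rpart(.y ~ .,
                      data = data.frame(Xs, .y = factor(y),
                                        check.names = FALSE),
                      method = "class"),
    FNN = mlpTrain(Xs, as.numeric(y), hidden = hp$hidden,
                   maxEpochs = hp$maxEpochs, learningRate = hp$learningRate,
                   validationFraction = hp$validationFraction,
                   patience = hp$patience))
  structure(list(spec = spec, fit = fit, featureNames = colnames(X),
                 center = center, scale = scale,
                 fingerprint = c(nrow = nrow(X), ncol = ncol(X))),
            class = "TrainedModel")
}

#' Predict fatigue labels
#'
#' @param model a `"TrainedModel"` from [trainModel()].
#' @param features matrix or data.frame with exactly the feature columns the
#'   model was trained on.
#' @param threshold score threshold for the positive (fatigue) class.
#' @return list with `label` (logical, `TRUE` = fatigue) and `score`
#'   (probability of fatigue in `[0, 1]`).
#' @export
predictModel <- function(model, features, threshold = 0.5) {
  stopifnot(inherits(model, "TrainedModel"))
  X <- as.matrix(features)
  if (is.null(colnames(X)) ||
      !identical(colnames(X), model$featureNames))
    stop("prediction error: feature columns do not match training schema",
         call. = FALSE)
  Xs <- sweep(sweep(X, 2L, model$center, "-"), 2L, model$scale, "/")
  score <- switch(model$spec$family,
    GLM = {
      df <- data.frame(Xs, check.names = FALSE)
      suppressWarnings(unname(stats::predict(model$fit, newdata = df,
                                             type = "response")))
    },
    LR = as.vector(stats::predict(model$fit, newx = Xs, type = "response")),
    RF = unname(stats::predict(model$fit, newdata = Xs,
                               type = "prob")[, "TRUE"]),
    DT = unname(stats::predict(model$fit,
                               newdata = data.frame(Xs, check.names = FALSE),
                               type = "prob")[, "TRUE"]),
    FNN = mlpPredictProb(model$fit, Xs))
  list(label = score >= threshold, score = score)
}
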