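#' @include AllClasses.R
NULL

#' Spearman rank correlation with two-sided p-value
#'
#' Rank correlation using average ranks for ties. The p-value is two-sided;
#' with no ties and small n it comes from the exact null distribution of the
#' rank statistic, otherwise from the asymptotic approximation (both via
#' [stats::cor.test()]).
#'
#' @param x,y paired numeric vectors, length >= 5, non-constant.
#' @return named numeric vector `c(rho=, p=)`.
#' @export
spearmanCor <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("input error: lengths differ", call. = FALSE)
  if (n < 5L) stop("input error: need at least 5 pairs", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("input error: constant input", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         alternative = "two.sided"))
  c(rho = unname(ct$estimate), p = ct$p.value)
}

#' Screen features against the fused RPE label
#'
#' Correlates every feature with the fused Borg rating within the chosen
#' subset (all repetitions, or the fatigue-only subset) and flags features
#' whose two-sided Spearman p-value is below the significance allowance.
#' Constant features are reported with missing correlation and flagged
#' insignificant rather than raising an error.
#'
#' @param fm a [RepFeatureExperiment].
#' @param subset `"complete"` or `"fatigue_only"`.
#' @param alpha significance allowance (default 0.1).
#' @param target colData column used as correlation target (default
#'   `"fused_rpe"`, the raw Borg scale on which all thresholds live).
#' @return data.frame: `feature`, `rho`, `p`, `significant`.
#' @export
screenFeatures <- function(fm, subset = c("complete", "fatigue_only"),
                           alpha = 0.1, target = "fused_rpe") {
  stopifnot(is(fm, "RepFeatureExperiment"))
  subset <- match.arg(subset)
  cd <- SummarizedExperiment::colData(fm)
  keep <- if (subset == "fatigue_only") which(cd$is_fatigued) else
    seq_len(ncol(fm))
  if (!length(keep))
    stop("selection error: empty subset after filtering", call. = FALSE)
  y <- cd[[target]][keep]
  mat <- SummarizedExperiment::assay(fm, "features")[, keep, drop = FALSE]
  res <- t(vapply(rownames(mat), function(f) {
    x <- mat[f, ]
    if (length(unique(x)) < 2L || length(unique(y)) < 2L)
      return(c(rho = NA_real_, p = NA_real_))
    spearmanCor(x, y)
  }, numeric(2L)))
  data.frame(feature = rownames(mat), rho = res[, "rho"], p = res[, "p"],
             significant = !is.na(res[, "p"]) & res[, "p"] < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect two significance flag sets
#'
#' The overlap rule of the dual screen: a feature is kept only if it is
#' significant in both the fatigue subset and the complete dataset. Both
#' inputs must cover the same feature universe; the result keeps the order
#' of the first.
#'
#' @param flagsFatigue,flagsComplete named logical vectors over the same
#'   features.
#' @return character vector of selected feature names.
#' @export
overlapFeatures <- function(flagsFatigue, flagsComplete) {
  if (is.null(names(flagsFatigue)) || is.null(names(flagsComplete)) ||
      !setequal(names(flagsFatigue), names(flagsComplete)))
    stop("input error: mismatched feature universes", call. = FALSE)
  flagsComplete <- flagsComplete[names(flagsFatigue)]
  names(flagsFatigue)[flagsFatigue & flagsComplete]
}

#' Dual Spearman screening with overlap selection
#'
#' Runs [screenFeatures()] on the fatigue-only subset and on the complete
#' dataset and selects the overlap of the two significant sets.
#'
#' @inheritParams screenFeatures
#' @return a [SelectionResult].
#' @export
selectFeatures <- function(fm, alpha = 0.1, target = "fused_rpe") {
  fat <- screenFeatures(fm, "fatigue_only", alpha, target)
  com <- screenFeatures(fm, "complete", alpha, target)
  tb <- data.frame(
    feature = fat$feature,
    signal = rep(FEATURE_SIGNALS, each = 3L),
    statistic = rep(FEATURE_STATS, times = length(FEATURE_SIGNALS)),
    rho_fatigue = fat$rho, p_fatigue = fat$p, sig_fatigue = fat$significant,
    rho_complete = com$rho, p_complete = com$p,
    sig_complete = com$significant,
    stringsAsFactors = FALSE)
  tb$selected <- tb$sig_fatigue & tb$sig_complete
  new("SelectionResult", table = tb, alpha = alpha)
}

#' Reference significance flags
#'
#' The published per-feature significance pattern of the dual screen in the
#' original wrist-IMU concentration-curl study, shipped as a plain-text
#' fixture so the overlap logic can be exercised independently of any
#' generated cohort. Intersecting its two flag columns yields the 16
#' selected features (6 means, 5 SDs, 5 AADs).
#'
#' @return data.frame: `feature`, `signal`, `statistic`, `sig_fatigue`,
#'   `sig_complete`.
#' @export
referenceSignificanceFlags <- function() {
  path <- system.file("extdata", "reference_significance_flags.csv",
                      package = "curlfatigue", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$sig_fatigue <- as.logical(df$sig_fatigue)
  df$sig_complete <- as.logical(df$sig_complete)
  df
}

#' Reference per-set change tables
#'
#' The published per-set percentage changes (completion time per set, and
#' endurance as angular-velocity amplitude per set, both relative to the
#' first main set) for the channels the original study tabulates, as
#' plain-text fixtures. Row averages can be recomputed with
#' [averageSetChange()].
#'
#' @param type `"completion_time"` or `"endurance"`.
#' @return data.frame with columns `axis_sensor`, `set2`..`set5`,
#'   `avg_printed`.
#' @export
referenceSetChanges <- function(type = c("completion_time", "endurance")) {
  type <- match.arg(type)
  path <- system.file("extdata", paste0("reference_", type, "_changes.csv"),
                      package = "curlfatigue", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
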