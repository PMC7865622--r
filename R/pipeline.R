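#' @include evaluate.R
#' @include select.R
#' @include session-io.R
NULL

#' Pipeline configuration
#'
#' Bundles every stage's parameters: the generator (or a directory of
#' externally supplied session files in the package schema), segmentation
#' parameters, the label-fusion tolerance, the selection allowance, the
#' model list, the evaluation protocols, the output directory and a global
#' seed.
#'
#' @param generator a [generatorConfig()], or a character path to a
#'   directory of session CSV/JSON pairs to consume instead of simulating.
#' @param segmentation list: `channel`, `smoothingWindow`, `minSeparation`,
#'   `prominenceFraction`.
#' @param labelTolerance divergence tolerance in bpm.
#' @param selectionAlpha significance allowance for the dual screen.
#' @param models character vector of model families to run.
#' @param protocols subset of `c("subject_specific", "cross_subject")`.
#' @param outputDir directory for all artifacts.
#' @param seed global seed (propagated to the generator and model training).
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(generator = generatorConfig(),
                           segmentation = list(channel = "acc_y",
                                               smoothingWindow = 0.3,
                                               minSeparation = 1.0,
                                               prominenceFraction = 0.2),
                           labelTolerance = 10,
                           selectionAlpha = 0.1,
                           models = MODEL_FAMILIES,
                           protocols = c("subject_specific", "cross_subject"),
                           outputDir = tempfile("curlfatigue_run_"),
                           seed = 101L) {
  if (inherits(generator, "GeneratorConfig")) {
    generator$seed <- as.integer(seed)
    validateGeneratorConfig(generator)
  } else if (!is.character(generator)) {
    stop("configuration error: generator must be a GeneratorConfig or a path",
         call. = FALSE)
  }
  stopifnot(all(protocols %in% c("subject_specific", "cross_subject")),
            all(models %in% MODEL_FAMILIES))
  structure(list(generator = generator, segmentation = segmentation,
                 labelTolerance = labelTolerance,
                 selectionAlpha = selectionAlpha, models = models,
                 protocols = protocols, outputDir = outputDir,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipelineConfig()] arguments; `generator` may
#' be a mapping of [generatorConfig()] arguments or a directory path.
#'
#' @param path YAML file.
#' @return a `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- y$generator
  if (is.list(gen)) gen <- do.call(generatorConfig, gen)
  if (is.null(gen)) gen <- generatorConfig()
  args <- y[setdiff(names(y), "generator")]
  do.call(pipelineConfig, c(list(generator = gen), args))
}

#' Run the fatigue-detection pipeline
#'
#' Orchestrates the stages end to end: simulate (or load) sessions, segment
#' repetitions, fuse labels, extract the 33 features, run the dual Spearman
#' screen, and evaluate the configured models under the configured
#' protocols. Every stage writes its artifact under the output directory and
#' later stages reload from disk, so a single stage can be re-run against
#' saved inputs. A run manifest (configuration, seed, package version, file
#' checksums) is written last; rerunning with the same configuration
#' reproduces identical artifacts.
#'
#' @param config a [pipelineConfig()] (or [readPipelineConfig()] output).
#' @param stage `"all"` or one of `"simulate"`, `"segment"`, `"label"`,
#'   `"features"`, `"select"`, `"evaluate"`; a single stage expects the
#'   preceding stages' artifacts in `config$outputDir`.
#' @param verbose print stage progress.
#' @return invisibly, a named list of artifact paths (and, for in-memory
#'   convenience, the selection result and evaluation reports).
#' @export
runPipeline <- function(config, stage = "all", verbose = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- match.arg(stage, c("all", "simulate", "segment", "label",
                              "features", "select", "evaluate"))
  dir <- config$outputDir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  say <- function(...) if (verbose) message("[curlfatigue] ", ...)
  paths <- list(sessions = file.path(dir, "sessions"),
                reps = file.path(dir, "repetitions.csv"),
                labeled = file.path(dir, "labeled_repetitions.csv"),
                features = file.path(dir, "feature_matrix.csv"),
                selection = file.path(dir, "selection.csv"),
                manifest = file.path(dir, "manifest.json"))
  stages <- if (stage == "all")
    c("simulate", "segment", "label", "features", "select", "evaluate")
  else stage
  result <- list(paths = paths)

  currentStage <- "setup"
  tryCatch({
    if ("simulate" %in% stages) {
      currentStage <- "simulate"; say("simulate")
      if (is.character(config$generator)) {
        # external recordings: copy-through by reading and rewriting so all
        # later stages consume one canonical location
        sessions <- readCohortSessions(config$generator)
        if (!dir.exists(paths$sessions)) dir.create(paths$sessions)
        for (nm in names(sessions))
          writeSession(sessions[[nm]],
                       file.path(paths$sessions, paste0(nm, ".csv")))
      } else {
        cohort <- generateCohort(config$generator)
        writeCohort(cohort, paths$sessions)
      }
    }
    sessions <- NULL
    loadSessions <- function() {
      if (is.null(sessions)) sessions <<- readCohortSessions(paths$sessions)
      sessions
    }
    if ("segment" %in% stages) {
      currentStage <- "segment"; say("segment")
      sg <- config$segmentation
      reps <- lapply(loadSessions(), function(s)
        detectRepetitions(s, channel = sg$channel,
                          smoothingWindow = sg$smoothingWindow,
                          minSeparation = sg$minSeparation,
                          prominenceFraction = sg$prominenceFraction))
      utils::write.csv(do.call(rbind, c(reps, list(make.row.names = FALSE))),
                       paths$reps, row.names = FALSE)
    }
    if ("label" %in% stages) {
      currentStage <- "label"; say("label")
      reps <- utils::read.csv(paths$reps)
      ses <- loadSessions()
      labeled <- lapply(ses, function(s) {
        sub <- reps[reps$subject_id == subjectId(s) & reps$arm == arm(s), ]
        labelRepetitions(s, sub, tolerance = config$labelTolerance)
      })
      utils::write.csv(do.call(rbind, c(labeled, list(make.row.names = FALSE))),
                       paths$labeled, row.names = FALSE)
    }
    if ("features" %in% stages) {
      currentStage <- "features"; say("features")
      labeled <- utils::read.csv(paths$labeled)
      ses <- loadSessions()
      labeledList <- lapply(ses, function(s)
        labeled[labeled$subject_id == subjectId(s) & labeled$arm == arm(s), ])
      fmat <- buildFeatureMatrix(ses, labeledList)
      writeFeatureMatrix(fmat, paths$features)
    }
    if ("select" %in% stages) {
      currentStage <- "select"; say("select")
      fmat <- readFeatureMatrix(paths$features)
      sel <- selectFeatures(fmat, alpha = config$selectionAlpha)
      utils::write.csv(selectionTable(sel), paths$selection,
                       row.names = FALSE)
      result$selection <- sel
    }
    if ("evaluate" %in% stages) {
      currentStage <- "evaluate"; say("evaluate")
      fmat <- readFeatureMatrix(paths$features)
      selTab <- utils::read.csv(paths$selection)
      feats <- selTab$feature[selTab$selected]
      if (!length(feats)) {
        warning("no features selected; falling back to all 33", call. = FALSE)
        feats <- selTab$feature
      }
      specs <- lapply(config$models, modelSpec, seed = config$seed)
      names(specs) <- config$models
      result$reports <- list()
      for (prot in config$protocols) {
        report <- if (prot == "subject_specific")
          subjectSpecificEval(fmat, feats, specs, seed = config$seed)
        else crossSubjectLOOCV(fmat, feats, specs)
        writeEvalReport(report,
                        jsonPath = file.path(dir, paste0("eval_", prot, ".json")),
                        csvPath = file.path(dir, paste0("eval_", prot, ".csv")))
        result$reports[[prot]] <- report
      }
    }
  }, error = function(e) {
    stop("pipeline aborted at stage [", currentStage, "]: ",
         conditionMessage(e), call. = FALSE)
  })

  manifest <- list(
    config = unclass(config[setdiff(names(config), "generator")]),
    generator = if (is.character(config$generator)) config$generator
                else unclass(config$generator),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("curlfatigue")),
    files = as.list(tools::md5sum(sort(c(
      list.files(paths$sessions, full.names = TRUE),
      Filter(file.exists, unlist(paths[c("reps", "labeled", "features",
                                         "selection")])),
      list.files(dir, pattern = "^eval_.*\\.(json|csv)$",
                 full.names = TRUE))))))
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(result)
}
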