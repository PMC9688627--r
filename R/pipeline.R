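# End-to-end orchestration: cohort -> per-channel features -> selection
# chain -> classifier comparison -> final model training -> evaluation,
# with every artifact and seed recorded in a manifest.

#' Pipeline configuration
#'
#' Exactly one input source: a [CohortSpec-class] for a synthetic run,
#' or a vector of EDF paths with labelled recordings.
#'
#' @param cohortSpec a [cohortSpec()] or NULL.
#' @param paths character vector of EDF files or NULL.
#' @param selection a [selectionConfig()].
#' @param compareKinds classifier kinds entering the comparison.
#' @param finalKinds classifiers trained and kept (default LSTM and
#'   CNNGRU).
#' @param train a [trainConfig()] for the final models.
#' @param compareTrain a [trainConfig()] for the fold-wise comparison
#'   (fewer epochs by default, since it trains k models per kind).
#' @param params [featureParams()].
#' @param outDir run directory.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(cohortSpec = NULL, paths = NULL,
                           selection = selectionConfig(),
                           compareKinds = c("LR", "SVM_RBF", "MLP",
                                            "CNN", "LSTM", "CNNGRU"),
                           finalKinds = c("LSTM", "CNNGRU"),
                           train = trainConfig(),
                           compareTrain = trainConfig(epochs = 20),
                           params = featureParams(),
                           outDir = tempfile("eegrun")) {
  if (is.null(cohortSpec) == is.null(paths))
    stop("exactly one input source: give cohortSpec XOR paths")
  structure(list(cohortSpec = cohortSpec, paths = paths,
                 selection = selection, compareKinds = compareKinds,
                 finalKinds = finalKinds, train = train,
                 compareTrain = compareTrain, params = params,
                 outDir = outDir),
            class = "PipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the four-step pipeline
#'
#' Executes, in order: (1) span and electrode selection, (2) feature
#' ranking and combination selection, (3) classifier comparison and
#' final model training with checkpointing, (4) evaluation of the
#' frozen chain on the cohort. All tables, checkpoints, reports and a
#' manifest (config, seeds, versions, file checksums) are written to
#' the run directory; a rerun with the same config reproduces them.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, a list with the selection report, comparison,
#'   trained models and eval reports; side effect: the populated run
#'   directory.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outDir, ...)

  cohort <- .stage("input", {
    if (!is.null(config$cohortSpec)) generateCohort(config$cohortSpec)
    else lapply(config$paths, readRecording)
  })

  chanFeat <- .stage("features", {
    channelFeatures(cohort, max(config$selection$spans), config$params)
  })

  sel <- .stage("selection", {
    runSelection(cohort, config$selection, chanFeat = chanFeat,
                 params = config$params)
  })
  write.csv(cvTable(sel$spanResults), out("cv_spans.csv"),
            row.names = FALSE)
  write.csv(cvTable(sel$regionResults), out("cv_regions.csv"),
            row.names = FALSE)
  write.csv(cvTable(sel$combResults), out("cv_combinations.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(span = sel$span, region = sel$region,
         electrodes = sel$electrodes, combination = sel$combination,
         features = sel$features, miRanking = sel$miRanking),
    out("selection.json"), auto_unbox = TRUE, digits = NA)

  fv <- featureVectors(chanFeat[chanFeat$window <= sel$span, ],
                       electrodes = sel$electrodes)
  writeFeatureTable(fv, out("features_long.csv"))

  cmp <- .stage("compare", {
    specs <- lapply(config$compareKinds, function(kd)
      modelSpec(kd, inputShape = c(length(sel$features), 1L),
                seed = config$selection$seed))
    compareClassifiers(fv, specs, k = config$selection$kFolds,
                       seed = config$selection$seed,
                       config = config$compareTrain,
                       features = sel$features)
  })
  write.csv(cvTable(cmp$results), out("cv_classifiers.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(cmp$pvalues), out("classifier_pvalues.csv"))

  trainedAll <- .stage("train", {
    lapply(setNames(config$finalKinds, config$finalKinds),
           function(kd) {
      spec <- modelSpec(kd, inputShape = c(length(sel$features), 1L),
                        seed = config$selection$seed)
      tm <- trainModel(buildModel(spec),
                       as.matrix(fv[, sel$features, drop = FALSE]),
                       fv$y, config$train)
      saveCheckpoint(tm, out(paste0("checkpoint_", kd, ".rds")))
      tm
    })
  })

  reports <- .stage("evaluate", {
    lapply(trainedAll, function(tm)
      externalValidate(tm, cohort, sel, params = config$params))
  })
  for (kd in names(reports)) {
    rp <- reports[[kd]]
    jsonlite::write_json(
      list(counts = unclass(rp$counts), metrics = as.list(rp$metrics),
           auc = rp$auc),
      out(paste0("eval_", kd, ".json")), auto_unbox = TRUE, digits = NA)
    write.csv(rp$roc, out(paste0("roc_", kd, ".csv")),
              row.names = FALSE)
  }

  cfgPath <- out("config.json")
  jsonlite::write_json(.configAsList(config), cfgPath,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  files <- setdiff(list.files(config$outDir), "manifest.json")
  manifest <- list(
    config = jsonlite::read_json(cfgPath),
    configHash = unname(tools::md5sum(cfgPath)),
    rVersion = as.character(getRversion()),
    packageVersion = as.character(utils::packageVersion("restingEEG")),
    files = as.list(setNames(
      unname(tools::md5sum(file.path(config$outDir, files))), files)))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(selection = sel, comparison = cmp,
                 trained = trainedAll, reports = reports,
                 dir = config$outDir))
}

.configAsList <- function(config) {
  cs <- config$cohortSpec
  list(
    cohortSpec = if (is.null(cs)) NULL else list(
      nCtl = cs@nCtl, nDep = cs@nDep, channels = cs@channels,
      fs = cs@fs, duration = cs@duration, betaCtl = cs@betaCtl,
      betaDep = cs@betaDep, alphaAmpCtl = cs@alphaAmpCtl,
      alphaAmpDep = cs@alphaAmpDep,
      discriminativeChannels = cs@discriminativeChannels,
      noiseSd = cs@noiseSd, leadIn = cs@leadIn, seed = cs@seed),
    paths = config$paths,
    selection = unclass(config$selection),
    compareKinds = config$compareKinds,
    finalKinds = config$finalKinds,
    train = unclass(config$train),
    compareTrain = unclass(config$compareTrain),
    params = unclass(config$params))
}
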