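# End-to-end orchestration: simulate -> denoise -> redundancy filter ->
# normalize -> features -> (tune) -> train -> evaluate.

#' Configure an end-to-end pipeline run
#'
#' Stage toggles plus per-stage parameter blocks and a global seed that
#' propagates to every stochastic stage. Stages always execute in the
#' fixed order denoise, redundancy filter, normalize, features, tune,
#' train, evaluate.
#'
#' @param outDir run directory for artifacts.
#' @param n number of synthetic samples to simulate.
#' @param stages character subset of
#'   `c("denoise", "redundancy", "normalize", "features", "tune", "train",
#'   "evaluate")`.
#' @param seed global seed.
#' @param dataset named list of [makeDataset()] overrides.
#' @param denoise a [denoiseConfig()].
#' @param redundancyThreshold relative-entropy threshold for the frame
#'   filter (bits).
#' @param cnn a [cnnConfig()].
#' @param tune named list of [optimizeHyperparameters()] overrides
#'   (e.g. nParticles, nIterations, searchEpochs).
#' @return List of class `PipelineConfig`.
#' @export
pipelineConfig <- function(outDir = tempfile("noduleCAD_run_"), n = 60L,
                           stages = c("denoise", "redundancy", "normalize",
                                      "features", "train", "evaluate"),
                           seed = 1L, dataset = list(),
                           denoise = denoiseConfig(),
                           redundancyThreshold = 0.01,
                           cnn = cnnConfig(inputSize = c(32L, 32L)),
                           tune = list()) {
  allStages <- c("denoise", "redundancy", "normalize", "features", "tune",
                 "train", "evaluate")
  stages <- intersect(allStages, stages)
  if (!length(stages)) stop("no stages enabled")
  structure(list(outDir = outDir, n = as.integer(n), stages = stages,
                 seed = as.integer(seed), dataset = dataset,
                 denoise = denoise,
                 redundancyThreshold = redundancyThreshold,
                 cnn = cnn, tune = tune),
            class = "PipelineConfig")
}

#' Run the nodule CAD pipeline end to end
#'
#' Simulates a phantom cohort, then executes the enabled stages in fixed
#' order, writing every artifact (kept-frame indices, feature table,
#' metrics report, stage log) under the run directory together with a
#' manifest listing each artifact's MD5 checksum. A stage failure aborts
#' the run with the failing stage named; artifacts written so far are
#' retained.
#'
#' @param config a [pipelineConfig()].
#' @return List with the run artifacts: `samples`, `keptFrames`,
#'   `features`, `model`, `metrics`, `outDir`, `timings`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(config$outDir, "log.txt")
  timings <- list()
  logLine <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    cat(msg, "\n", file = logFile, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    logLine(sprintf("stage %-10s done in %.2fs", name, timings[[name]]))
    out
  }
  on <- function(nm) nm %in% config$stages

  samples <- stage("simulate", do.call(makeDataset, c(
    list(n = config$n, seed = config$seed), config$dataset)))

  if (on("denoise")) {
    samples <- stage("denoise", lapply(samples, function(s) {
      s@image <- denoiseVolume(sampleImage(s), config$denoise)
      s
    }))
  }

  kept <- seq_along(samples)
  if (on("redundancy")) {
    kept <- stage("redundancy", eliminateRedundantFrames(
      lapply(samples, sampleImage), config$redundancyThreshold))
    samples <- samples[kept]
    utils::write.csv(data.frame(keptIndex = kept),
                     file.path(config$outDir, "kept_frames.csv"),
                     row.names = FALSE)
  }

  if (on("normalize")) {
    samples <- stage("normalize", lapply(samples, function(s) {
      s@image <- zscoreNormalize(sampleImage(s))
      s
    }))
  }

  feats <- NULL
  if (on("features")) {
    feats <- stage("features", featureMatrix(samples))
    df <- data.frame(id = seq_along(samples),
                     label = vapply(samples, sampleLabel, ""), feats,
                     check.names = FALSE)
    utils::write.csv(df, file.path(config$outDir, "features.csv"),
                     row.names = FALSE)
  }

  cnnCfg <- config$cnn
  split <- splitDataset(samples, 0.8, seed = config$seed)
  model <- NULL
  if (on("tune")) {
    tuned <- stage("tune", do.call(optimizeHyperparameters, c(
      list(samples = samples[split$train], baseConfig = cnnCfg,
           seed = config$seed), config$tune)))
    cnnCfg <- tuned$bestConfig
    utils::write.csv(tuned$trace, file.path(config$outDir, "trace.csv"),
                     row.names = FALSE)
  }
  if (on("train")) {
    cnnCfg$seed <- config$seed
    class(cnnCfg) <- "CnnConfig"
    model <- stage("train", trainModel(buildModel(cnnCfg),
                                       samples[split$train]))
  }

  metrics <- NULL
  if (on("evaluate")) {
    if (is.null(model)) stop("pipeline stage 'evaluate' failed: no model")
    metrics <- stage("evaluate", {
      pred <- predictCnn(model, samples[split$test])
      truth <- vapply(samples[split$test], sampleLabel, "")
      m <- classificationMetrics(confusionCounts(pred$labels, truth))
      jsonlite::write_json(
        m[c("accuracy", "sensitivity", "specificity", "precision",
            "fScore", "n", "undefined")],
        file.path(config$outDir, "metrics.json"),
        auto_unbox = TRUE, digits = NA, na = "null")
      m
    })
  }

  arts <- list.files(config$outDir, full.names = TRUE)
  arts <- arts[!basename(arts) %in% "artifact_manifest.csv"]
  if (length(arts))
    utils::write.csv(data.frame(file = basename(arts),
                                md5 = unname(tools::md5sum(arts))),
                     file.path(config$outDir, "artifact_manifest.csv"),
                     row.names = FALSE)
  logLine("pipeline complete")
  list(samples = samples, keptFrames = kept, features = feats,
       model = model, metrics = metrics, outDir = config$outDir,
       timings = timings)
}
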