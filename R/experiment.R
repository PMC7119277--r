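#' Run a configured end-to-end experiment
#'
#' Executes simulate (or load) -> preprocess -> build -> train/evaluate ->
#' interpret as configured and writes every artifact into a run directory:
#' the resolved config, the model description with its parameter count,
#' per-epoch history, holdout metrics and confusion matrix, and (optionally)
#' the gene-effect matrix and marker set. Re-running with the same config
#' reproduces all outputs bit-for-bit.
#'
#' Config keys (YAML file or nested list): `seed`; `data` (either
#' `simulate: <list of [syntheticDesign()] arguments>` or `expression:` +
#' `labels:` file paths plus optional `orientation`, `log_already_applied`,
#' `mean_threshold`, `sd_threshold`, `target_len`); `model` (`type`:
#' `"1d"`, `"2d_vanilla"`, `"2d_hybrid"` or `"brca_1d"`, `grid_rows`,
#' `grid_cols`, plus architecture arguments); `train` (`train_fraction` and
#' [trainConfig()] arguments); `interpret` (`enabled`, `threshold`).
#'
#' @param config path to a YAML file or a nested list.
#' @param outdir run directory (default: a timestamped directory under
#'   `tempdir()`).
#' @return the run directory path, invisibly; the main objects are returned
#'   as attributes `"model"`, `"metrics"` and `"markers"`.
#' @export
runExperiment <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validateExperimentConfig(config)
  if (is.null(outdir))
    outdir <- file.path(tempdir(),
                        paste0("run_", format(Sys.time(), "%Y%m%d_%H%M%S")))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  log <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(log), add = TRUE)
  say <- function(...) writeLines(sprintf(...), log)
  say("seed: %d", seed)
  yaml::write_yaml(config, file.path(outdir, "config.yaml"))

  # ---- data ----
  dcfg <- config$data
  if (!is.null(dcfg$simulate)) {
    design <- do.call(syntheticDesign,
                      c(dcfg$simulate, list(seed = seed + 1L)))
    x <- simulatePanCancer(design)
    say("simulated %d samples x %d genes", ncol(x), nrow(x))
  } else {
    x <- readExpressionTable(dcfg$expression,
                             orientation = dcfg$orientation %||%
                               "samples_in_rows",
                             logTransformed = isTRUE(dcfg$log_already_applied),
                             labelFile = dcfg$labels)
    say("loaded %d samples x %d genes", ncol(x), nrow(x))
  }
  x <- preprocessExpression(
    x, meanThreshold = dcfg$mean_threshold %||% 0.5,
    sdThreshold = dcfg$sd_threshold %||% 0.8,
    targetLen = dcfg$target_len)
  say("after preprocessing: %d genes (%d padding)", nrow(x), nPadding(x))
  labels <- sampleLabels(x)
  if (is.null(labels)) stop("config error: data provides no labels")
  classNames <- orderClasses(labels)

  # ---- model ----
  mcfg <- config$model
  inputLen <- nrow(x)
  rows <- as.integer(mcfg$grid_rows %||% 100L)
  cols <- as.integer(mcfg$grid_cols %||% ceiling(inputLen / rows))
  arch <- switch(mcfg$type,
    "1d" = arch1DCNN(inputLen = inputLen,
                     nFilters = mcfg$n_filters %||% 32L,
                     kernelLen = mcfg$kernel_len %||% 71L,
                     denseUnits = mcfg$dense_units %||% 128L,
                     nClasses = length(classNames)),
    "brca_1d" = archBRCA1DCNN(nClasses = length(classNames),
                              inputLen = inputLen,
                              nFilters = mcfg$n_filters %||% 32L,
                              kernelLen = mcfg$kernel_len %||% 71L),
    "2d_vanilla" = arch2DVanillaCNN(inputRows = rows, inputCols = cols,
                                    nFilters = mcfg$n_filters %||% 32L,
                                    denseUnits = mcfg$dense_units %||% 128L,
                                    nClasses = length(classNames)),
    "2d_hybrid" = arch2DHybridCNN(inputRows = rows, inputCols = cols,
                                  nFilters = mcfg$n_filters %||% 32L,
                                  denseUnits = mcfg$dense_units %||% 128L,
                                  nClasses = length(classNames)))
  if (is(arch, "Conv2DVanillaArchitecture") ||
      is(arch, "Conv2DHybridArchitecture")) {
    if (rows * cols != inputLen)
      stop(sprintf("config error: grid %d x %d != input length %d",
                   rows, cols, inputLen))
  }
  model <- buildModel(arch, classNames = classNames, seed = seed + 2L)
  desc <- describeModel(model)
  say("model %s: %d trainable parameters", mcfg$type, attr(desc, "total"))
  utils::write.table(
    rbind(desc, data.frame(layer = "TOTAL", outputShape = "",
                           nParameters = attr(desc, "total"))),
    file.path(outdir, "model_description.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- train / evaluate ----
  tcfg <- config$train %||% list()
  cfgArgs <- tcfg[intersect(names(tcfg),
                            c("maxEpochs", "batchSize", "patience", "lr"))]
  cfg <- do.call(trainConfig, c(cfgArgs, list(seed = seed + 3L)))
  sp <- holdoutSplit(labels, tcfg$train_fraction %||% 0.8, seed = seed + 4L)
  X <- modelInput(x)
  model <- trainModel(model, X[sp$train, , drop = FALSE],
                      labels[sp$train],
                      validation = list(x = X[sp$validation, , drop = FALSE],
                                        labels = labels[sp$validation]),
                      config = cfg)
  utils::write.table(model@history, file.path(outdir, "history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pred <- predict(model, X[sp$validation, , drop = FALSE])
  metrics <- computeMetrics(labels[sp$validation], pred, classNames)
  say("holdout accuracy: %.4f", metrics@accuracy)
  utils::write.table(metrics@perClass, file.path(outdir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  confusionHeatmap(metrics, file.path(outdir, "confusion.png"))

  # ---- interpret ----
  markers <- NULL
  icfg <- config$interpret %||% list(enabled = FALSE)
  if (isTRUE(icfg$enabled)) {
    gem <- geneEffectMatrix(model, x)
    writeGeneEffectMatrix(gem, file.path(outdir, "gene_effect.tsv"))
    markers <- selectMarkers(gem, icfg$threshold %||% 0.5)
    writeMarkerSet(markers, file.path(outdir, "markers.tsv"))
    say("markers: %d total, %d unique genes", markerCount(markers),
        length(uniqueGenes(markers)))
  }
  invisible(structure(outdir, model = model, metrics = metrics,
                      markers = markers))
}

.validateExperimentConfig <- function(config) {
  if (!is.list(config)) stop("config error: config must be a list")
  if (is.null(config$data) ||
      (is.null(config$data$simulate) && is.null(config$data$expression)))
    stop("config error: data must provide either 'simulate' or 'expression'")
  if (is.null(config$model) || is.null(config$model$type))
    stop("config error: model$type is required")
  if (!config$model$type %in% c("1d", "brca_1d", "2d_vanilla", "2d_hybrid"))
    stop(sprintf("config error: unknown model type '%s'", config$model$type))
  if (!is.null(config$model$n_classes) && !is.null(config$data$simulate)) {
    d <- config$data$simulate
    nClasses <- (d$nTissues %||% 11L) * (d$cancersPerTissue %||% 3L) +
      as.integer((d$normalsPerTissue %||% 6L) > 0)
    if (config$model$n_classes != nClasses)
      stop(sprintf(
        "config error: model$n_classes = %d but the design yields %d classes",
        config$model$n_classes, nClasses))
  }
  invisible(TRUE)
}
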