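# End-to-end pipeline drivers: read -> unify -> flag duplicates -> size
# threshold -> biovolume -> write LabelChecker CSV, plus training and
# prediction over whole run directories. Raw inputs are never modified.

#' Pipeline configuration
#'
#' Collects the per-component settings and switches. Every data-cleaning
#' component and the biovolume calculation can be individually enabled or
#' disabled; the reserved air-bubble flag is a disabled stub (no published
#' algorithm).
#'
#' @param duplicates,sizeThreshold,biovolume enable/disable each component
#'   (\code{sizeThreshold} is implied by a non-NULL \code{sizeConfig}).
#' @param duplicateCfg a [duplicateConfig()].
#' @param sizeConfig a [sizeThresholdConfig()] or NULL.
#' @param biovolumeCfg a [biovolumeConfig()].
#' @param calibration um/px override for files without a calibration column.
#' @param dialect forced dialect id, or NULL to auto-detect.
#' @param bubbles reserved; must stay FALSE (trial feature, disabled).
#' @return list of class \code{"PipelineConfig"}
#' @export
pipelineConfig <- function(duplicates = TRUE, sizeThreshold = TRUE,
                           biovolume = TRUE,
                           duplicateCfg = duplicateConfig(),
                           sizeConfig = NULL,
                           biovolumeCfg = biovolumeConfig(),
                           calibration = NULL, dialect = NULL,
                           bubbles = FALSE) {
  if (isTRUE(bubbles))
    warning("air-bubble detection is a disabled stub; ignoring bubbles=TRUE")
  if (!duplicates && !sizeThreshold && !biovolume)
    stop("at least one pipeline component must be enabled")
  structure(list(duplicates = duplicates, sizeThreshold = sizeThreshold,
                 biovolume = biovolume, duplicateCfg = duplicateCfg,
                 sizeConfig = sizeConfig, biovolumeCfg = biovolumeCfg,
                 calibration = calibration, dialect = dialect,
                 bubbles = FALSE),
            class = "PipelineConfig")
}

.findRunCsvs <- function(inputDir) {
  files <- list.files(inputDir, pattern = "\\.csv$", full.names = TRUE)
  skip <- grepl("^LabelChecker_", basename(files)) |
    grepl("_(groundtruth|summary)\\.csv$", basename(files))
  files[!skip]
}

#' Preprocess every run in a directory
#'
#' For each property CSV in \code{inputDir} (files prefixed
#' \code{LabelChecker_} and ground-truth/summary files are skipped): read
#' and unify, flag duplicates, apply the size threshold, compute biovolume
#' from the collage images, and write \code{LabelChecker_<run>.csv} plus a
#' per-run summary text file into \code{outputDir}. Failures are isolated
#' per run and reported in the returned summary.
#'
#' @param inputDir directory with run CSVs and collage images.
#' @param outputDir output directory (created; may equal inputDir).
#' @param config a [pipelineConfig()].
#' @return data.frame with one row per run: run name, particle count,
#'   duplicate/small/large counts, output path, and an error message for
#'   failed runs.
#' @export
runPreprocess <- function(inputDir, outputDir = inputDir,
                          config = pipelineConfig()) {
  csvs <- .findRunCsvs(inputDir)
  if (length(csvs) == 0L) stop("no run CSV files found in ", inputDir)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  summaries <- lapply(csvs, function(f) {
    res <- tryCatch(.preprocessOne(f, inputDir, outputDir, config),
                    error = function(e) data.frame(
                      run = tools::file_path_sans_ext(basename(f)),
                      particles = NA_integer_, duplicates = NA_integer_,
                      small = NA_integer_, large = NA_integer_,
                      output = NA_character_,
                      error = conditionMessage(e),
                      stringsAsFactors = FALSE))
    res
  })
  do.call(rbind, summaries)
}

.preprocessOne <- function(csvPath, inputDir, outputDir, config) {
  dialect <- if (!is.null(config$dialect))
    vspDialects()[[config$dialect]] else NULL
  tab <- readRun(csvPath, dialect = dialect,
                 calibration = config$calibration)
  n <- nParticles(tab)
  labels <- labelColumns(n)

  dupFlags <- if (config$duplicates)
    flagDuplicates(tab, config$duplicateCfg) else NULL
  sizeFlags <- if (config$sizeThreshold && !is.null(config$sizeConfig))
    applySizeThreshold(tab, config$sizeConfig) else NULL
  labels$Preprocessing <- combineFlags(dupFlags, sizeFlags)
  if (length(labels$Preprocessing) != n)
    labels$Preprocessing <- character(n)

  if (config$biovolume) {
    bv <- computeRunBiovolume(tab, inputDir, cfg = config$biovolumeCfg,
                              calibration = config$calibration)
    labels$Biovolume <- bv$Biovolume
    labels$SurfaceArea <- bv$SurfaceArea
  }

  out <- writeLabelCheckerCsv(tab, labels, outputDir)
  counts <- c(duplicates = sum(labels$Preprocessing == "duplicate"),
              small = sum(labels$Preprocessing == "small"),
              large = sum(labels$Preprocessing == "large"))
  summaryPath <- file.path(outputDir,
                           paste0(runName(tab), "_summary.txt"))
  writeLines(c(paste0("run: ", runName(tab)),
               paste0("particles: ", n),
               paste0("dialect: ", dialect(tab)@versionId),
               paste0("duplicates: ", counts["duplicates"]),
               paste0("small: ", counts["small"]),
               paste0("large: ", counts["large"])),
             summaryPath)
  data.frame(run = runName(tab), particles = n,
             duplicates = unname(counts["duplicates"]),
             small = unname(counts["small"]),
             large = unname(counts["large"]),
             output = out, error = NA_character_, stringsAsFactors = FALSE)
}

.loadVignettes <- function(table, imageDir) {
  df <- particleData(table)
  cache <- new.env(parent = emptyenv())
  lapply(seq_len(nrow(df)), function(i) {
    f <- df$CollageFile[i]
    if (is.na(f) || !nzchar(f)) return(matrix(0, 2, 2))
    key <- paste0("c", f)
    if (!exists(key, envir = cache)) {
      path <- file.path(imageDir, f)
      img <- if (file.exists(path))
        EBImage::imageData(EBImage::readImage(path)) else NULL
      if (!is.null(img) && length(dim(img)) == 3L) img <- img[, , 1L]
      assign(key, img, envir = cache)
    }
    collage <- get(key, envir = cache)
    if (is.null(collage)) return(matrix(0, 2, 2))
    extractVignette(collage, df$ImageX[i], df$ImageY[i], df$ImageW[i],
                    df$ImageH[i])
  })
}

#' Train a classifier from labelled LabelChecker runs
#'
#' Reads every \code{LabelChecker_*.csv} in \code{inputDir}, pools the
#' labelled rows, applies the training-table filters, splits
#' stratified-by-class, trains the dual-input model and writes the model
#' directory (parameters, class list, feature schema, standardisation
#' statistics, history) plus a per-class classification report CSV.
#'
#' @param inputDir directory with LabelChecker CSVs and collage images.
#' @param modelDir output directory for the model.
#' @param cfg a [trainConfig()].
#' @param verbose print epoch progress.
#' @return the trained model, invisibly.
#' @export
trainFromRuns <- function(inputDir, modelDir, cfg = trainConfig(),
                          verbose = FALSE) {
  files <- list.files(inputDir, pattern = "^LabelChecker_.*\\.csv$",
                      full.names = TRUE)
  if (length(files) == 0L) stop("no LabelChecker CSVs in ", inputDir)
  tabs <- lapply(files, readLabelCheckerCsv)
  df <- do.call(rbind, lapply(tabs, function(z) particleData(z$table)))
  labels <- do.call(rbind, lapply(tabs, `[[`, "labels"))
  vigs <- do.call(c, lapply(tabs, function(z)
    .loadVignettes(z$table, inputDir)))
  tab <- new("ParticleTable", data = df, dialect = vspDialects()$canonical,
             runName = "pooled", sourcePath = "")
  ts <- prepareTrainingTable(tab, labels, cfg, images = vigs)
  model <- buildModel(ncol(ts$features), length(levels(ts$classes)), cfg)
  model$classList <- levels(ts$classes)
  model$featureNames <- ts$keptColumns
  model$center <- ts$center
  model$scale <- ts$scale
  sp <- stratifiedSplit(ts$classes, cfg$valFraction, cfg$seed)
  trainSet <- list(images = ts$images[, , sp$train, drop = FALSE],
                   features = ts$features[sp$train, , drop = FALSE],
                   classes = ts$classes[sp$train])
  valSet <- list(images = ts$images[, , sp$val, drop = FALSE],
                 features = ts$features[sp$val, , drop = FALSE],
                 classes = ts$classes[sp$val])
  model <- trainModel(model, trainSet, valSet, cfg, verbose = verbose)
  saveModel(model, modelDir)
  probs <- predictProbabilities(model, valSet$images, valSet$features)
  rep <- classificationReport(model$classList[max.col(probs)],
                              as.character(valSet$classes))
  data.table::fwrite(rep, file.path(modelDir, "classification_report.csv"))
  invisible(model)
}

#' Save / load a trained model directory
#'
#' The directory holds the network parameters (RDS), the class list,
#' feature schema and standardisation statistics (CSV), the training
#' configuration (JSON) and the training history (CSV).
#'
#' @param model a trained model.
#' @param modelDir directory to create.
#' @return \code{saveModel}: \code{modelDir}, invisibly; \code{loadModel}:
#'   the model.
#' @export
saveModel <- function(model, modelDir) {
  dir.create(modelDir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model$params, file.path(modelDir, "weights.rds"))
  writeLines(model$classList, file.path(modelDir, "classes.txt"))
  data.table::fwrite(data.frame(feature = model$featureNames,
                                center = model$center,
                                scale = model$scale),
                     file.path(modelDir, "feature_schema.csv"))
  jsonlite::write_json(unclass(model$cfg),
                       file.path(modelDir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(model$history))
    data.table::fwrite(model$history, file.path(modelDir, "history.csv"))
  invisible(modelDir)
}

#' @rdname saveModel
#' @export
loadModel <- function(modelDir) {
  cfgList <- jsonlite::read_json(file.path(modelDir, "config.json"),
                                 simplifyVector = TRUE)
  cfg <- do.call(trainConfig, cfgList[names(cfgList) %in%
                                        names(formals(trainConfig))])
  schema <- read.csv(file.path(modelDir, "feature_schema.csv"),
                     stringsAsFactors = FALSE)
  classes <- readLines(file.path(modelDir, "classes.txt"))
  model <- buildModel(nrow(schema), length(classes), cfg)
  model$params <- readRDS(file.path(modelDir, "weights.rds"))
  model$classList <- classes
  model$featureNames <- schema$feature
  model$center <- setNames(schema$center, schema$feature)
  model$scale <- setNames(schema$scale, schema$feature)
  hPath <- file.path(modelDir, "history.csv")
  if (file.exists(hPath))
    model$history <- read.csv(hPath, stringsAsFactors = FALSE)
  model
}

#' Predict labels for every run in a directory
#'
#' Applies a trained model to each \code{LabelChecker_*.csv}: fills
#' \code{LabelPredicted}/\code{ProbabilityScore} for unflagged rows, never
#' touches \code{LabelTrue} or \code{PreprocessingTrue}, and rewrites the
#' file in place in \code{outputDir}.
#'
#' @param inputDir directory with LabelChecker CSVs and collage images.
#' @param modelDir a [saveModel()] directory.
#' @param outputDir where updated CSVs go (defaults to inputDir).
#' @return data.frame summary (run, predictions written).
#' @export
predictRuns <- function(inputDir, modelDir, outputDir = inputDir) {
  model <- loadModel(modelDir)
  files <- list.files(inputDir, pattern = "^LabelChecker_.*\\.csv$",
                      full.names = TRUE)
  if (length(files) == 0L) stop("no LabelChecker CSVs in ", inputDir)
  out <- lapply(files, function(f) {
    z <- readLabelCheckerCsv(f)
    vigs <- .loadVignettes(z$table, inputDir)
    labels <- tryCatch(predictParticles(model, z$table, z$labels, vigs),
                       warning = function(w) {
                         warning(w)
                         z$labels
                       })
    writeLabelCheckerCsv(z$table, labels, outputDir)
    data.frame(run = runName(z$table),
               predictions = sum(nzchar(labels$LabelPredicted)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
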