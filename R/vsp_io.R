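# Reading/writing VSP particle CSVs and the LabelChecker output format.
#
# The LabelChecker format is the run's original (unified) columns followed by
# exactly seven appended columns holding the preprocessing flag, its
# user-validated copy, the predicted label with its probability, the true
# (validated) label, and the biovolume / surface-area estimates.

.labelColumnNames <- c("Preprocessing", "PreprocessingTrue", "LabelPredicted",
                       "ProbabilityScore", "LabelTrue", "Biovolume",
                       "SurfaceArea")
.preprocessingLevels <- c("", "duplicate", "small", "large", "bubble")

#' Names of the seven appended label columns
#' @return character(7)
#' @examples labelColumnNames()
#' @export
labelColumnNames <- function() .labelColumnNames

#' Empty label columns for n particles
#'
#' Builds the seven-column label block appended to a LabelChecker CSV:
#' \code{Preprocessing} (automatic flag: "", "duplicate", "small", "large" or
#' "bubble"), \code{PreprocessingTrue} (user-validated flag),
#' \code{LabelPredicted} + \code{ProbabilityScore} (classifier output),
#' \code{LabelTrue} (validated class label), \code{Biovolume} (um^3) and
#' \code{SurfaceArea} (um^2).
#'
#' @param n number of particle rows.
#' @return data.frame with 7 columns and \code{n} rows.
#' @examples labelColumns(3)
#' @export
labelColumns <- function(n) {
  data.frame(Preprocessing = character(n), PreprocessingTrue = character(n),
             LabelPredicted = character(n),
             ProbabilityScore = rep(NA_real_, n),
             LabelTrue = character(n), Biovolume = rep(NA_real_, n),
             SurfaceArea = rep(NA_real_, n), stringsAsFactors = FALSE)
}

.checkLabelColumns <- function(labels, n = NULL) {
  if (!is.data.frame(labels) ||
      !identical(names(labels), .labelColumnNames))
    stop("labels must be a data.frame with exactly the seven columns: ",
         paste(.labelColumnNames, collapse = ", "))
  if (!is.null(n) && nrow(labels) != n)
    stop("labels (", nrow(labels), " rows) are not aligned 1:1 with the ",
         "particle records (", n, " rows)")
  bad <- !(labels$Preprocessing %in% .preprocessingLevels)
  if (any(bad))
    stop("invalid Preprocessing flag(s): ",
         paste(unique(labels$Preprocessing[bad]), collapse = ", "))
  hasPred <- nzchar(labels$LabelPredicted)
  if (any(hasPred != !is.na(labels$ProbabilityScore)))
    stop("ProbabilityScore must be set exactly when LabelPredicted is set")
  p <- labels$ProbabilityScore
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("ProbabilityScore must lie in [0, 1]")
  invisible(labels)
}

#' Read one FlowCam run CSV
#'
#' Loads a per-particle property CSV exported by any supported
#' VisualSpreadsheet version, renames columns to canonical names, and wraps
#' the result in a [ParticleTable-class]. The source file is never modified
#' (non-destructive contract) and row order is preserved.
#'
#' @param csvPath path to the property CSV (one header row, comma separated,
#'   "." decimal mark, UTF-8).
#' @param dialect optional [VspDialect-class]; auto-detected when NULL.
#' @param runName run name; defaults to the file stem.
#' @param calibration optional calibration constant (um/px) used when the
#'   file carries no CalibrationFactor column.
#' @return a [ParticleTable-class]
#' @seealso [detectDialect()], [writeLabelCheckerCsv()]
#' @export
readRun <- function(csvPath, dialect = NULL, runName = NULL,
                    calibration = NULL) {
  if (!file.exists(csvPath)) stop("file not found: ", csvPath)
  df <- tryCatch(
    read.csv(csvPath, check.names = FALSE, stringsAsFactors = FALSE,
             fileEncoding = "UTF-8"),
    error = function(e) stop("cannot parse '", csvPath, "': ",
                             conditionMessage(e)))
  if (ncol(df) == 0L) stop("empty header in ", csvPath)
  if (is.null(dialect))
    dialect <- suppressWarnings(detectDialect(names(df)))
  names(df) <- unifyHeader(names(df), dialect)
  if (!"CalibrationFactor" %in% names(df) && !is.null(calibration))
    df$CalibrationFactor <- calibration
  if (is.null(runName))
    runName <- sub("^LabelChecker_", "",
                   tools::file_path_sans_ext(basename(csvPath)))
  new("ParticleTable", data = df, dialect = dialect, runName = runName,
      sourcePath = normalizePath(csvPath))
}

#' Write a LabelChecker CSV
#'
#' Writes the run's unified columns followed by the seven label columns to
#' \code{out_dir/LabelChecker_<runName>.csv} (UTF-8, comma separated).
#' Numeric cells use the shortest representation that round-trips exactly,
#' so \code{readLabelCheckerCsv(writeLabelCheckerCsv(...))} is lossless.
#'
#' @param table a [ParticleTable-class].
#' @param labels data.frame from [labelColumns()], aligned 1:1 with the
#'   records.
#' @param outDir output directory (created if missing).
#' @return the path of the written file, invisibly.
#' @export
writeLabelCheckerCsv <- function(table, labels = NULL, outDir = ".") {
  stopifnot(is(table, "ParticleTable"))
  df <- particleData(table)
  if (is.null(labels)) labels <- labelColumns(nrow(df))
  .checkLabelColumns(labels, nrow(df))
  clash <- intersect(names(df), .labelColumnNames)
  df <- df[, setdiff(names(df), clash), drop = FALSE]
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  out <- file.path(outDir, paste0("LabelChecker_", runName(table), ".csv"))
  data.table::fwrite(cbind(df, labels), out, sep = ",", dec = ".",
                     quote = "auto", na = "", bom = FALSE)
  invisible(out)
}

#' Read a LabelChecker CSV
#'
#' Reads a file produced by [writeLabelCheckerCsv()] back into a
#' [ParticleTable-class] plus the seven-column label block. Empty label
#' cells map to \code{""} (text columns) or \code{NA} (numeric columns);
#' enum values are validated.
#'
#' @param path path to a \code{LabelChecker_*.csv} file.
#' @return list with elements \code{table} ([ParticleTable-class]) and
#'   \code{labels} (data.frame of the seven label columns).
#' @export
readLabelCheckerCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  missing <- setdiff(.labelColumnNames, names(df))
  if (length(missing) > 0L)
    stop("not a LabelChecker CSV: missing appended column(s) ",
         paste(missing, collapse = ", "))
  lab <- df[, .labelColumnNames, drop = FALSE]
  for (cc in c("Preprocessing", "PreprocessingTrue", "LabelPredicted",
               "LabelTrue")) {
    lab[[cc]] <- as.character(lab[[cc]])
    lab[[cc]][is.na(lab[[cc]])] <- ""
  }
  for (cc in c("ProbabilityScore", "Biovolume", "SurfaceArea"))
    lab[[cc]] <- as.numeric(lab[[cc]])
  .checkLabelColumns(lab, nrow(df))
  keep <- df[, setdiff(names(df), .labelColumnNames), drop = FALSE]
  tab <- new("ParticleTable", data = keep,
             dialect = vspDialects()$canonical,
             runName = sub("^LabelChecker_", "",
                           tools::file_path_sans_ext(basename(path))),
             sourcePath = normalizePath(path))
  list(table = tab, labels = lab)
}

#' Build a 9-letter taxon class code
#'
#' Class codes combine the first three letters of the taxonomic class, genus
#' and species, then an underscore and the GBIF taxon ID. Genus- or
#' class-level labels use \code{"000"} in the missing slots, and a missing
#' GBIF ID becomes \code{"0000000"}.
#'
#' @param className taxonomic class name (at least 3 letters).
#' @param genus,species optional genus / species epithet (each at least 3
#'   letters when given).
#' @param gbifId optional GBIF taxon ID (digits).
#' @return character(1) code, e.g. \code{"BacAstfor_3192686"}.
#' @examples
#' makeClassCode("Bacillariophyceae", "Asterionella", "formosa", "3192686")
#' makeClassCode("Chlorophyceae", "Pandorina", "morum")
#' @export
makeClassCode <- function(className, genus = "", species = "", gbifId = "") {
  take3 <- function(x, what) {
    if (is.null(x) || is.na(x) || !nzchar(x)) return("000")
    letters <- gsub("[^A-Za-z]", "", x)
    if (nchar(letters) < 3L)
      stop(what, " must contain at least 3 letters: '", x, "'")
    substr(letters, 1L, 3L)
  }
  if (is.null(className) || is.na(className) || !nzchar(className))
    stop("className is required")
  code <- paste0(take3(className, "className"), take3(genus, "genus"),
                 take3(species, "species"))
  id <- if (is.null(gbifId) || is.na(gbifId) || !nzchar(as.character(gbifId)))
    "0000000" else as.character(gbifId)
  if (!grepl("^[0-9]+$", id)) stop("gbifId must be digits: '", gbifId, "'")
  paste0(code, "_", id)
}

#' Small built-in example ParticleTable
#'
#' A deterministic 6-particle table with canonical columns, used in examples.
#' @return a [ParticleTable-class]
#' @export
exampleParticleTable <- function() {
  n <- 6L
  df <- data.frame(
    Id = 1:n, SourceImage = c(1L, 1L, 2L, 3L, 3L, 4L),
    CaptureX = c(120, 640, 150, 700, 300, 410),
    CaptureY = c(200, 350, 220, 100, 480, 260),
    CollageFile = "example_000001.tif",
    ImageX = c(0, 60, 120, 180, 240, 300), ImageY = 0,
    ImageW = c(40, 52, 38, 45, 60, 33), ImageH = c(41, 50, 40, 44, 58, 35),
    CalibrationFactor = 0.595,
    EdgeGradient = c(40.2, 51.0, 38.7, 45.5, 60.1, 33.9),
    AbdArea = c(510, 820, 470, 633, 1105, 340),
    AbdDiameter = c(25.5, 32.3, 24.5, 28.4, 37.5, 20.8),
    AvgBlue = c(120, 131, 118, 125, 140, 117),
    AvgGreen = c(122, 133, 119, 127, 141, 119),
    AvgRed = c(119, 130, 116, 124, 138, 115),
    Intensity = c(120.3, 131.2, 117.7, 125.3, 139.8, 117.0),
    Length = c(30.1, 38.0, 28.8, 33.5, 44.2, 24.4),
    Width = c(21.5, 27.2, 20.7, 24.0, 31.6, 17.5),
    Perimeter = c(88.2, 111.4, 84.6, 98.1, 129.5, 71.9),
    Roughness = c(1.08, 1.12, 1.05, 1.09, 1.15, 1.04),
    SigmaIntensity = c(12.1, 14.0, 11.5, 12.9, 15.8, 10.9),
    Transparency = c(0.31, 0.27, 0.33, 0.29, 0.24, 0.35),
    stringsAsFactors = FALSE)
  new("ParticleTable", data = df, dialect = vspDialects()$canonical,
      runName = "example", sourcePath = "")
}
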