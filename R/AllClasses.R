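#' @import methods
#' @importFrom stats cov sd rnorm runif setNames quantile
#' @importFrom utils read.csv head tail
#' @importFrom grDevices chull contourLines
NULL

#' VisualSpreadsheet CSV dialect
#'
#' Describes one VisualSpreadsheet (VSP) export schema: a version identifier
#' and a mapping from that version's column headers (aliases) to the
#' package-canonical CamelCase names. The \code{canonical} dialect maps every
#' canonical name to itself.
#'
#' @slot versionId character(1), one of \code{"v1_8"}, \code{"v2_2"},
#'   \code{"v2_4"}, \code{"v4_15"}, \code{"v4_19"}, \code{"v6_0"},
#'   \code{"canonical"}.
#' @slot columnMap named character vector; names are alias headers as they
#'   appear in the CSV, values are canonical headers.
#'
#' @seealso [detectDialect()], [vspDialects()]
#' @export
setClass("VspDialect",
  representation(versionId = "character", columnMap = "character"))

setValidity("VspDialect", function(object) {
  msg <- character()
  if (length(object@versionId) != 1L || is.na(object@versionId))
    msg <- c(msg, "versionId must be a single string")
  cm <- object@columnMap
  if (length(cm) > 0L) {
    if (is.null(names(cm)) || any(!nzchar(names(cm))))
      msg <- c(msg, "columnMap must be a named character vector")
    if (anyDuplicated(cm))
      msg <- c(msg, "columnMap canonical values must be unique")
    if (anyDuplicated(names(cm)))
      msg <- c(msg, "columnMap alias names must be unique")
  }
  if (identical(object@versionId, "canonical") &&
      !identical(unname(cm), names(cm)))
    msg <- c(msg, "canonical dialect must map every name to itself")
  if (length(msg)) msg else TRUE
})

#' Per-run table of particle records
#'
#' One FlowCam run: an ordered table with one row per imaged particle,
#' columns unified to canonical names, plus provenance (source path, run
#' name) and the dialect the file was read as. Row order is preserved from
#' the input file; unknown columns are retained verbatim.
#'
#' @slot data data.frame of particle properties (canonical names where
#'   recognised).
#' @slot dialect the [VspDialect-class] the source file was identified as.
#' @slot runName character(1), the sample run name (source file stem).
#' @slot sourcePath character(1), path the table was read from ("" if built
#'   in memory).
#'
#' @seealso [readRun()], [particleData()], [writeLabelCheckerCsv()]
#' @export
setClass("ParticleTable",
  representation(data = "data.frame", dialect = "VspDialect",
                 runName = "character", sourcePath = "character"))

setValidity("ParticleTable", function(object) {
  msg <- character()
  if (length(object@runName) != 1L)
    msg <- c(msg, "runName must be a single string")
  d <- object@data
  if ("Id" %in% names(d) && anyDuplicated(d$Id))
    msg <- c(msg, "record Ids must be unique")
  if ("CalibrationFactor" %in% names(d) &&
      any(!is.na(d$CalibrationFactor) & d$CalibrationFactor <= 0))
    msg <- c(msg, "CalibrationFactor must be > 0")
  if (length(msg)) msg else TRUE
})

#' Binary particle silhouette
#'
#' A 2-D logical foreground mask of a single particle together with the
#' pixel size (the VSP calibration constant, micrometres per pixel).
#'
#' @slot pixels logical matrix; TRUE = particle foreground.
#' @slot pixelSize numeric(1), micrometres per pixel (> 0). Use 1 to work in
#'   pixel units.
#'
#' @seealso [binarize()], [distanceMap()], [shapeStats()], [computeBiovolume()]
#' @export
setClass("BinaryMask",
  representation(pixels = "matrix", pixelSize = "numeric"))

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (!is.logical(object@pixels))
    msg <- c(msg, "pixels must be a logical matrix")
  if (any(dim(object@pixels) < 1L))
    msg <- c(msg, "mask must have positive dimensions")
  if (length(object@pixelSize) != 1L || is.na(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a BinaryMask
#'
#' @param pixels logical (or coercible 0/1) matrix, TRUE = foreground.
#' @param pixelSize micrometres per pixel; defaults to 1 (pixel units).
#' @return a [BinaryMask-class]
#' @examples
#' m <- binaryMask(rasterDisk(10))
#' maskArea(m)
#' @export
binaryMask <- function(pixels, pixelSize = 1) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  storage.mode(pixels) <- "logical"
  pixels[is.na(pixels)] <- FALSE
  new("BinaryMask", pixels = pixels, pixelSize = pixelSize)
}

setMethod("show", "VspDialect", function(object) {
  cat("VspDialect ", object@versionId, " (", length(object@columnMap),
      " mapped columns)\n", sep = "")
})

setMethod("show", "ParticleTable", function(object) {
  cat("ParticleTable '", object@runName, "': ", nrow(object@data),
      " particles, ", ncol(object@data), " properties [dialect ",
      object@dialect@versionId, "]\n", sep = "")
  if (nrow(object@data) > 0L) {
    shown <- head(names(object@data), 8L)
    cat("  columns: ", paste(shown, collapse = ", "),
        if (ncol(object@data) > 8L) ", ..." else "", "\n", sep = "")
  }
})

setMethod("show", "BinaryMask", function(object) {
  cat("BinaryMask ", nrow(object@pixels), "x", ncol(object@pixels),
      " px (", sum(object@pixels), " foreground), ",
      object@pixelSize, " um/px\n", sep = "")
})
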