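# VSP dialect registry and header detection.
#
# The per-version header spellings are not standardised anywhere public, so
# the registry ships as an editable CSV (inst/extdata/vsp_dialects.csv,
# columns dialect/alias/canonical). Users with a different VSP build can
# append rows rather than patch code.

.canonicalColumns <- c(
  "Id", "SourceImage", "CaptureX", "CaptureY", "CollageFile",
  "ImageX", "ImageY", "ImageW", "ImageH", "CalibrationFactor",
  "EdgeGradient", "AbdArea", "AbdDiameter", "AvgBlue", "AvgGreen", "AvgRed",
  "Intensity", "Length", "Width", "Perimeter", "Roughness",
  "SigmaIntensity", "Transparency")

# the particle-property vector compared by the duplicate detector
.duplicateFeatures <- c(
  "EdgeGradient", "AbdArea", "AbdDiameter", "AvgBlue", "AvgGreen", "AvgRed",
  "Intensity", "Length", "Width", "Perimeter", "Roughness",
  "SigmaIntensity", "Transparency")

#' Canonical column names
#'
#' Canonical (unified) particle-property column names used across the
#' package. \code{canonicalColumns()} returns all recognised names;
#' \code{duplicateFeatureNames()} the 13 particle properties whose vector is
#' compared by cosine similarity during duplicate detection (edge gradient,
#' area-based area and diameter, average blue/green/red, intensity, length,
#' width, perimeter, roughness, sigma intensity, transparency).
#'
#' @return character vector of column names
#' @examples
#' duplicateFeatureNames()
#' @export
canonicalColumns <- function() .canonicalColumns

#' @rdname canonicalColumns
#' @export
duplicateFeatureNames <- function() .duplicateFeatures

.dialectRegistry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "vsp_dialects.csv",
                          package = "flowcamtools", mustWork = TRUE)
      cache <<- utils::read.csv(path, stringsAsFactors = FALSE,
                                check.names = FALSE)
    }
    cache
  }
})

#' Known VSP dialects
#'
#' Returns the list of [VspDialect-class] objects built from the shipped
#' mapping table, keyed by version id. The \code{canonical} dialect (identity
#' mapping over [canonicalColumns()]) is always first.
#'
#' @return named list of [VspDialect-class]
#' @examples
#' names(vspDialects())
#' @export
vspDialects <- function() {
  reg <- .dialectRegistry()
  ids <- unique(reg$dialect)
  out <- list(canonical = new("VspDialect", versionId = "canonical",
    columnMap = setNames(.canonicalColumns, .canonicalColumns)))
  for (id in ids) {
    sub <- reg[reg$dialect == id, , drop = FALSE]
    out[[id]] <- new("VspDialect", versionId = id,
                     columnMap = setNames(sub$canonical, sub$alias))
  }
  out
}

#' Detect the VSP dialect of a CSV header
#'
#' Scores every known dialect by the Jaccard overlap between the header and
#' the dialect's alias set, and returns the best-scoring dialect. Columns not
#' covered by the winning dialect are retained verbatim downstream; they are
#' reported through a warning and the \code{"unknownColumns"} attribute of
#' the result.
#'
#' @param header character vector of column names, in file order.
#' @return the winning [VspDialect-class], with attribute
#'   \code{unknownColumns}.
#' @examples
#' detectDialect(canonicalColumns())
#' @export
detectDialect <- function(header) {
  if (length(header) == 0L || all(!nzchar(header)))
    stop("empty header: cannot detect a VSP dialect")
  dialects <- vspDialects()
  scores <- vapply(dialects, function(d) {
    aliases <- names(d@columnMap)
    length(intersect(header, aliases)) / length(union(header, aliases))
  }, numeric(1))
  if (all(scores == 0))
    stop("unknown dialect: no known VSP schema matches columns [",
         paste(header, collapse = ", "), "]")
  best <- dialects[[which.max(scores)]]
  unknown <- setdiff(header, names(best@columnMap))
  if (length(unknown) > 0L)
    warning("columns not in the '", best@versionId,
            "' dialect map are kept verbatim: ",
            paste(unknown, collapse = ", "))
  attr(best, "unknownColumns") <- unknown
  best
}

#' Unify a header to canonical names
#'
#' Renames every alias known to \code{dialect} to its canonical name;
#' unknown columns pass through unchanged. Idempotent for any dialect that
#' includes the identity rows (the canonical dialect trivially so).
#'
#' @param header character vector of column names.
#' @param dialect a [VspDialect-class]; detected from the header if missing.
#' @return character vector of the same length, canonical where recognised.
#' @examples
#' unifyHeader(c("ABD Area", "Length", "Foo"), vspDialects()$v1_8)
#' @export
unifyHeader <- function(header, dialect = NULL) {
  if (is.null(dialect))
    dialect <- suppressWarnings(detectDialect(header))
  cm <- dialect@columnMap
  hit <- header %in% names(cm)
  header[hit] <- unname(cm[header[hit]])
  header
}
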