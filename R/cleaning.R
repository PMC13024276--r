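# Duplicate detection and size thresholding.
#
# A later particle is a duplicate of an earlier one when all proximity gates
# hold and at least one similarity gate holds:
#   (1) captured within `frameWindow` source images of each other (<=, i.e.
#       inclusive), AND
#   (2) source-frame x-coordinates less than `maxXOffset` pixels apart
#       (strict <), AND
#   (3) bounding-box intersection over union >= minIou, OR
#   (4) cosine similarity of the 13 particle properties >= minCosine.
# Linked records form chains; the earliest record of each chain (by source
# image, then id) is kept, all later members are flagged "duplicate".

#' Duplicate-detection configuration
#'
#' Defaults follow the four published criteria: candidates within five
#' source images, source x-positions less than 100 px apart, and either a
#' bounding-box IoU of at least 30\% or a particle-property cosine
#' similarity of at least 99.9\%.
#'
#' @param frameWindow maximum source-image index difference (inclusive).
#' @param maxXOffset maximum |CaptureX| difference in px (exclusive).
#' @param minIou minimum bounding-box intersection over union (inclusive).
#' @param minCosine minimum feature cosine similarity (inclusive).
#' @param featureSet canonical names of the compared particle properties.
#' @param useIou,useCosine disable one similarity gate (at least one must
#'   stay enabled).
#' @return list of class \code{"DuplicateConfig"}
#' @export
duplicateConfig <- function(frameWindow = 5L, maxXOffset = 100,
                            minIou = 0.30, minCosine = 0.999,
                            featureSet = duplicateFeatureNames(),
                            useIou = TRUE, useCosine = TRUE) {
  stopifnot(frameWindow >= 1L, minIou > 0, minIou <= 1,
            minCosine > 0, minCosine <= 1, maxXOffset > 0,
            useIou || useCosine)
  structure(list(frameWindow = as.integer(frameWindow),
                 maxXOffset = maxXOffset, minIou = minIou,
                 minCosine = minCosine, featureSet = featureSet,
                 useIou = useIou, useCosine = useCosine),
            class = "DuplicateConfig")
}

#' Size-threshold configuration
#'
#' @param parameter canonical column name of the size parameter (e.g.
#'   \code{"Length"}, \code{"AbdDiameter"}), in micrometres.
#' @param lower,upper thresholds in micrometres; \code{-Inf}/\code{Inf}
#'   disable a side.
#' @return list of class \code{"SizeThresholdConfig"}
#' @export
sizeThresholdConfig <- function(parameter, lower = -Inf, upper = Inf) {
  stopifnot(is.character(parameter), length(parameter) == 1L,
            lower <= upper)
  structure(list(parameter = parameter, lower = lower, upper = upper),
            class = "SizeThresholdConfig")
}

#' Intersection over union of two axis-aligned boxes
#'
#' Boxes are \code{c(x, y, w, h)} with positive width and height.
#'
#' @param boxA,boxB numeric(4) boxes.
#' @return fraction in [0, 1].
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 10, 10))  # 50/150
#' @export
iou <- function(boxA, boxB) {
  if (boxA[3L] <= 0 || boxA[4L] <= 0 || boxB[3L] <= 0 || boxB[4L] <= 0)
    stop("degenerate box: width and height must be > 0")
  ix <- min(boxA[1L] + boxA[3L], boxB[1L] + boxB[3L]) -
        max(boxA[1L], boxB[1L])
  iy <- min(boxA[2L] + boxA[4L], boxB[2L] + boxB[4L]) -
        max(boxA[2L], boxB[2L])
  inter <- max(0, ix) * max(0, iy)
  inter / (boxA[3L] * boxA[4L] + boxB[3L] * boxB[4L] - inter)
}

#' Cosine similarity of two feature vectors
#'
#' Returns \eqn{u \cdot v / (\|u\|\|v\|)}. A zero vector has no direction;
#' the pair is treated as not similar (returns \code{-Inf} with a warning)
#' rather than erroring.
#'
#' @param u,v numeric vectors of equal length.
#' @return value in [-1, 1] (or \code{-Inf} for a zero vector).
#' @export
cosineSimilarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warning("zero feature vector: cosine undefined, treated as not similar")
    return(-Inf)
  }
  sum(u * v) / (nu * nv)
}

.requireColumns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop(what, " requires missing column(s): ",
         paste(missing, collapse = ", "))
}

#' Flag duplicate particle records
#'
#' Applies the four duplicate criteria (see [duplicateConfig()]) to every
#' candidate pair within the source-image window, links matching pairs into
#' chains, keeps the earliest record of each chain and flags all later
#' members \code{"duplicate"}. The result is independent of input row
#' permutation (records are compared in source-image, then id order).
#'
#' @param table a [ParticleTable-class] (or data.frame with canonical
#'   columns).
#' @param cfg a [duplicateConfig()].
#' @return character vector of per-record flags, \code{""} or
#'   \code{"duplicate"}, in input row order.
#' @export
flagDuplicates <- function(table, cfg = duplicateConfig()) {
  df <- if (is(table, "ParticleTable")) particleData(table) else table
  .requireColumns(df, c("Id", "SourceImage", "CaptureX", "CaptureY",
                        "ImageW", "ImageH"), "flagDuplicates")
  n <- nrow(df)
  flags <- character(n)
  if (n < 2L) return(flags)

  feats <- intersect(cfg$featureSet, names(df))
  haveFeats <- length(feats) > 0L && cfg$useCosine
  if (cfg$useCosine && length(feats) < length(cfg$featureSet))
    warning("missing duplicate feature column(s): ",
            paste(setdiff(cfg$featureSet, names(df)), collapse = ", "),
            if (haveFeats) "; cosine computed on the available subset" else
              "; pairs evaluated on the IoU gate only")

  ord <- order(df$SourceImage, df$Id)
  src <- df$SourceImage[ord]; cx <- df$CaptureX[ord]; cy <- df$CaptureY[ord]
  bw <- df$ImageW[ord]; bh <- df$ImageH[ord]
  fm <- if (haveFeats) as.matrix(df[ord, feats, drop = FALSE]) else NULL
  if (haveFeats) {
    norms <- sqrt(rowSums(fm^2))
    if (any(norms == 0))
      warning("zero feature vector: cosine undefined, treated as not similar")
  }

  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    while (j <= n && src[j] - src[i] <= cfg$frameWindow) {
      if (abs(cx[j] - cx[i]) < cfg$maxXOffset) {
        hit <- FALSE
        if (cfg$useIou) {
          ov <- iou(c(cx[i], cy[i], bw[i], bh[i]),
                    c(cx[j], cy[j], bw[j], bh[j]))
          hit <- ov >= cfg$minIou
        }
        if (!hit && haveFeats && norms[i] > 0 && norms[j] > 0) {
          cs <- sum(fm[i, ] * fm[j, ]) / (norms[i] * norms[j])
          hit <- cs >= cfg$minCosine
        }
        if (hit) {
          ri <- findRoot(i); rj <- findRoot(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
      j <- j + 1L
    }
  }

  roots <- vapply(seq_len(n), findRoot, integer(1))
  dupSorted <- roots != seq_len(n)  # chain root (earliest member) is kept
  flags[ord[dupSorted]] <- "duplicate"
  flags
}

#' Flag particles outside a size range
#'
#' Values strictly below \code{lower} are flagged \code{"small"}, strictly
#' above \code{upper} \code{"large"}; values inside the range (inclusive)
#' get no flag.
#'
#' @param table a [ParticleTable-class] or data.frame.
#' @param cfg a [sizeThresholdConfig()].
#' @return character vector of per-record flags (\code{""}, \code{"small"}
#'   or \code{"large"}).
#' @export
applySizeThreshold <- function(table, cfg) {
  stopifnot(inherits(cfg, "SizeThresholdConfig"))
  df <- if (is(table, "ParticleTable")) particleData(table) else table
  if (!cfg$parameter %in% names(df))
    stop("unknown size parameter '", cfg$parameter, "'")
  v <- df[[cfg$parameter]]
  if (!is.numeric(v)) stop("size parameter '", cfg$parameter,
                           "' is not numeric")
  flags <- character(nrow(df))
  flags[!is.na(v) & v < cfg$lower] <- "small"
  flags[!is.na(v) & v > cfg$upper] <- "large"
  flags
}

#' Combine preprocessing flags
#'
#' Merges duplicate and size flags into the single Preprocessing column;
#' the duplicate flag takes precedence over size flags.
#'
#' @param dupFlags,sizeFlags character vectors from [flagDuplicates()] and
#'   [applySizeThreshold()] (either may be NULL when that component is
#'   disabled).
#' @return character vector of combined flags.
#' @export
combineFlags <- function(dupFlags = NULL, sizeFlags = NULL) {
  n <- max(length(dupFlags), length(sizeFlags))
  out <- character(n)
  if (!is.null(sizeFlags)) out <- sizeFlags
  if (!is.null(dupFlags)) out[dupFlags == "duplicate"] <- "duplicate"
  out
}
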