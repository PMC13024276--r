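# Vignette extraction, binarization, distance maps and shape statistics.
#
# Conventions: image matrices are indexed [x, y] as in EBImage; bounding
# boxes use 0-based pixel offsets (VSP convention) with positive width and
# height. All measurements are in pixel units unless a BinaryMask carries a
# pixelSize.

#' Extract a particle vignette from a collage image
#'
#' Copies the bounding box \code{(imageX, imageY, imageW, imageH)} (0-based
#' offsets, as recorded in the VSP property CSV) out of a collage mosaic.
#' The collage itself is never modified.
#'
#' @param collage numeric matrix (grayscale) or EBImage \code{Image}.
#' @param imageX,imageY 0-based top-left offset of the vignette.
#' @param imageW,imageH vignette width and height in pixels (> 0).
#' @return numeric matrix of dimension \code{imageW x imageH}.
#' @export
extractVignette <- function(collage, imageX, imageY, imageW, imageH) {
  px <- if (is(collage, "Image")) EBImage::imageData(collage) else collage
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # first channel of RGB
  if (imageW <= 0 || imageH <= 0)
    stop("zero-size box: imageW and imageH must be > 0")
  if (imageX < 0 || imageY < 0 ||
      imageX + imageW > nrow(px) || imageY + imageH > ncol(px))
    stop("bounding box (", imageX, ",", imageY, ",", imageW, ",", imageH,
         ") exceeds collage bounds ", nrow(px), "x", ncol(px))
  px[(imageX + 1L):(imageX + imageW), (imageY + 1L):(imageY + imageH),
     drop = FALSE]
}

#' Binarize a particle vignette
#'
#' Global (Otsu) thresholding followed by hole filling and selection of the
#' largest connected component, yielding a single solid silhouette as the
#' biovolume estimators assume. With \code{polarity = "auto"} the side of the
#' threshold with the smaller pixel count is taken as foreground (particles
#' occupy a minority of a vignette); \code{"dark"}/\code{"light"} force the
#' below-/above-threshold side.
#'
#' A constant-intensity vignette yields an empty mask whose \code{"empty"}
#' attribute is TRUE rather than an error.
#'
#' \code{polarity = "border"} picks the side that is under-represented on
#' the one-pixel image border as foreground. This is the robust choice for
#' snug particle crops, where the particle can occupy the majority of the
#' pixels and the smaller-count heuristic would invert; the run-level
#' biovolume driver uses it.
#'
#' @param vignette numeric matrix (any intensity range) or EBImage Image.
#' @param polarity "auto", "dark", "light" or "border".
#' @param pixelSize um/px recorded on the returned mask.
#' @return a [BinaryMask-class]; attribute \code{empty} flags degenerate
#'   input.
#' @export
binarize <- function(vignette, polarity = c("auto", "dark", "light",
                                            "border"),
                     pixelSize = 1) {
  polarity <- match.arg(polarity)
  px <- if (is(vignette, "Image")) EBImage::imageData(vignette) else vignette
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  if (length(px) == 0L) stop("empty vignette")
  rng <- range(px, finite = TRUE)
  if (diff(rng) == 0) {
    m <- binaryMask(matrix(FALSE, nrow(px), ncol(px)), pixelSize)
    attr(m, "empty") <- TRUE
    return(m)
  }
  norm <- (px - rng[1L]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  dark <- norm < thr
  fg <- switch(polarity,
    dark = dark, light = !dark,
    auto = if (sum(dark) <= sum(!dark)) dark else !dark,
    border = {
      edge <- c(dark[1L, ], dark[nrow(dark), ], dark[, 1L], dark[, ncol(dark)])
      if (mean(edge) > 0.5) !dark else dark
    })
  fg <- .solidify(fg)
  m <- binaryMask(fg, pixelSize)
  attr(m, "empty") <- !any(fg)
  m
}

# fill holes, then keep the largest connected component
.solidify <- function(fg) {
  if (!any(fg)) return(fg)
  img <- EBImage::fillHull(EBImage::Image(fg * 1))
  lab <- EBImage::bwlabel(img)
  labs <- EBImage::imageData(lab)
  if (max(labs) > 1) {
    counts <- tabulate(labs[labs > 0])
    labs <- labs == which.max(counts)
  }
  matrix(labs > 0, nrow(fg), ncol(fg))
}

#' Euclidean distance map of a mask
#'
#' Each foreground pixel receives the Euclidean distance (in pixels) to the
#' nearest background pixel; background pixels hold 0. The mask is padded by
#' a one-pixel background ring before the transform so border-touching
#' particles get finite distances.
#'
#' @param mask a [BinaryMask-class] or logical matrix.
#' @return numeric matrix of the same dimension as the mask.
#' @seealso [biovolumeDm()]
#' @export
distanceMap <- function(mask) {
  px <- if (is(mask, "BinaryMask")) maskPixels(mask) else mask
  if (!any(px)) return(matrix(0, nrow(px), ncol(px)))
  pad <- matrix(0, nrow(px) + 2L, ncol(px) + 2L)
  pad[2:(nrow(px) + 1L), 2:(ncol(px) + 1L)] <- px * 1
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(pad)))
  d[2:(nrow(px) + 1L), 2:(ncol(px) + 1L), drop = FALSE]
}

#' Shape statistics of a binary silhouette
#'
#' Computes, in pixel units: foreground area; convex-hull area (hull taken
#' over the pixel corner points, so it is never smaller than the pixel
#' area); contour perimeter (marching-squares iso-contour at 0.5);
#' eccentricity \eqn{\sqrt{1 - \lambda_2/\lambda_1}} from the eigenvalues of
#' the foreground coordinate covariance (with the 1/12 unit-square pixel
#' term, keeping eccentricity < 1 even for one-pixel-wide lines); major-axis
#' length of the same-second-moment ellipse (\eqn{4\sqrt{\lambda_1}}); and
#' the equivalent circular diameter \eqn{2\sqrt{area/\pi}}.
#'
#' @param mask a [BinaryMask-class] or logical matrix with at least one
#'   foreground pixel.
#' @return list with elements \code{areaPx}, \code{convexAreaPx},
#'   \code{perimeterPx}, \code{eccentricity}, \code{majorAxisPx},
#'   \code{minorAxisPx}, \code{ecdPx}, \code{orientation} (radians).
#' @export
shapeStats <- function(mask) {
  px <- if (is(mask, "BinaryMask")) maskPixels(mask) else mask
  fg <- which(px, arr.ind = TRUE)
  if (nrow(fg) == 0L) stop("empty mask: no foreground pixels")
  area <- nrow(fg)

  # covariance ellipse; + I/12 accounts for the unit-square pixel footprint
  cv <- if (area > 1L) cov(fg) * (area - 1) / area else matrix(0, 2, 2)
  cv <- cv + diag(2) / 12
  ev <- eigen(cv, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  ecc <- sqrt(max(0, 1 - lam[2L] / lam[1L]))
  orient <- atan2(ev$vectors[2L, 1L], ev$vectors[1L, 1L])

  # convex hull over pixel corners
  corners <- rbind(fg + matrix(c(-0.5, -0.5), area, 2, byrow = TRUE),
                   fg + matrix(c( 0.5, -0.5), area, 2, byrow = TRUE),
                   fg + matrix(c(-0.5,  0.5), area, 2, byrow = TRUE),
                   fg + matrix(c( 0.5,  0.5), area, 2, byrow = TRUE))
  h <- grDevices::chull(corners)
  hx <- corners[h, 1L]; hy <- corners[h, 2L]
  hullArea <- abs(sum(hx * c(hy[-1L], hy[1L]) - c(hx[-1L], hx[1L]) * hy)) / 2

  list(areaPx = area, convexAreaPx = max(hullArea, area),
       perimeterPx = .contourPerimeter(px),
       eccentricity = ecc,
       majorAxisPx = 4 * sqrt(lam[1L]), minorAxisPx = 4 * sqrt(lam[2L]),
       ecdPx = 2 * sqrt(area / pi), orientation = orient)
}

# marching-squares contour length at level 0.5 on the padded mask
.contourPerimeter <- function(px) {
  pad <- matrix(0, nrow(px) + 2L, ncol(px) + 2L)
  pad[2:(nrow(px) + 1L), 2:(ncol(px) + 1L)] <- px * 1
  cl <- grDevices::contourLines(x = seq_len(nrow(pad)), y = seq_len(ncol(pad)),
                                z = pad, levels = 0.5)
  sum(vapply(cl, function(seg)
    sum(sqrt(diff(seg$x)^2 + diff(seg$y)^2)), numeric(1)))
}

#' Rotate a mask and re-rasterize
#'
#' Rotates a binary mask by \code{degrees} (bilinear interpolation) and
#' re-binarizes with a mass-preserving threshold: the N strongest pixels are
#' kept, where N is the rotated gray mass. A fixed 0.5 threshold locks onto
#' the pixel lattice at angles near 45 degrees and can inflate the area by
#' several percent; preserving mass keeps the silhouette area stable under
#' rotation.
#'
#' @param mask a [BinaryMask-class] or logical matrix.
#' @param degrees rotation angle, counter-clockwise.
#' @return logical matrix (expanded to fit the rotated silhouette).
#' @export
rotateMask <- function(mask, degrees) {
  px <- if (is(mask, "BinaryMask")) maskPixels(mask) else mask
  g <- EBImage::imageData(EBImage::rotate(EBImage::Image(px * 1.0), degrees,
                                          bg.col = 0))
  n <- round(sum(g))
  if (n <= 0L) return(matrix(FALSE, nrow(g), ncol(g)))
  thr <- sort(as.vector(g), decreasing = TRUE)[n]
  out <- g >= thr
  matrix(out, nrow(g), ncol(g))
}
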