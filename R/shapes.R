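# Parametric silhouette rasterizers.
#
# Shared by the synthetic-run generator and by the analytic test shapes
# (disk = sphere, rectangle = cylinder). A pixel is foreground iff its
# center lies inside the continuum shape; with this convention the
# rasterized area of a disk matches pi*R^2 to O(R^(2/3)) (Gauss circle) and
# both biovolume estimators converge to the closed-form solids.

#' Rasterize simple silhouettes
#'
#' \code{rasterDisk} draws a disk of radius \code{r} px; \code{rasterRect} an
#' axis-aligned rectangle of \code{len x wid} px (a cylinder silhouette);
#' \code{rasterStar} a regular \code{points}-pointed star with outer radius
#' \code{r} and inner radius \code{r * innerFrac}; \code{rasterFilament} a
#' dilated random walk (requires the RNG state, so seed the caller).
#'
#' @param r radius (outer radius for stars) in pixels.
#' @param len,wid rectangle length and width in pixels.
#' @param points number of star points.
#' @param innerFrac inner/outer radius ratio of the star.
#' @param steps,thickness random-walk length and dilation radius of the
#'   filament.
#' @param pad background margin around the shape, in pixels.
#' @return logical matrix, TRUE = foreground.
#' @examples
#' sum(rasterDisk(20)) / (pi * 20^2)  # ~1
#' @export
rasterDisk <- function(r, pad = 2L) {
  n <- 2L * ceiling(r) + 1L + 2L * pad
  c0 <- (n + 1) / 2
  x <- matrix(seq_len(n), n, n)
  y <- t(x)
  (x - c0)^2 + (y - c0)^2 <= r^2
}

#' @rdname rasterDisk
#' @export
rasterRect <- function(len, wid, pad = 2L) {
  m <- matrix(FALSE, round(len) + 2L * pad, round(wid) + 2L * pad)
  m[(pad + 1L):(pad + round(len)), (pad + 1L):(pad + round(wid))] <- TRUE
  m
}

#' @rdname rasterDisk
#' @export
rasterStar <- function(r, points = 5L, innerFrac = 0.08, pad = 2L) {
  n <- 2L * ceiling(r) + 1L + 2L * pad
  c0 <- (n + 1) / 2
  x <- matrix(seq_len(n), n, n) - c0
  y <- t(matrix(seq_len(n), n, n)) - c0
  th <- atan2(y, x)
  rad <- sqrt(x^2 + y^2)
  # star boundary radius as a function of angle (piecewise linear between
  # outer tips and inner notches)
  sector <- (th %% (2 * pi)) * points / (2 * pi)
  frac <- abs(sector - floor(sector + 0.5))  # 0 at tip, 0.5 at notch
  bound <- r * (1 - (1 - innerFrac) * (2 * frac))
  rad <= bound
}

#' @rdname rasterDisk
#' @export
rasterFilament <- function(steps = 60L, thickness = 2L, pad = 2L) {
  ang <- cumsum(rnorm(steps, 0, 0.25))
  xs <- cumsum(cos(ang)); ys <- cumsum(sin(ang))
  xs <- round(xs - min(xs)) + thickness + pad + 1L
  ys <- round(ys - min(ys)) + thickness + pad + 1L
  m <- matrix(FALSE, max(xs) + thickness + pad, max(ys) + thickness + pad)
  m[cbind(xs, ys)] <- TRUE
  k <- EBImage::makeBrush(2L * thickness + 1L, shape = "disc")
  d <- EBImage::imageData(EBImage::dilate(EBImage::Image(m * 1), k)) > 0.5
  matrix(d, nrow(m), ncol(m))
}

# crop a mask to its foreground bounding box plus a margin
.cropMask <- function(px, pad = 2L) {
  fg <- which(px, arr.ind = TRUE)
  if (nrow(fg) == 0L) return(px)
  r1 <- max(1L, min(fg[, 1L]) - pad); r2 <- min(nrow(px), max(fg[, 1L]) + pad)
  c1 <- max(1L, min(fg[, 2L]) - pad); c2 <- min(ncol(px), max(fg[, 2L]) + pad)
  px[r1:r2, c1:c2, drop = FALSE]
}
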