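#' Tassel area
#'
#' Sum of foreground pixels in the binary tassel mask; a proxy for tassel
#' biomass.
#'
#' @param mask Logical matrix.
#' @return Pixel count.
#' @export
mask_area <- function(mask) {
  stopifnot(is.logical(mask))
  if (!any(mask)) stop("empty mask has no area")
  sum(mask)
}

# Shoelace area of a polygon given as a two-column (x, y) matrix.
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Compactness (solidity)
#'
#' Tassel area divided by the area of the convex hull of the foreground
#' pixel centres: how densely the tassel's biomass fills its outline.
#' Near 1 for convex blobs, small for sparse, spreading tassels.
#'
#' @param mask Logical matrix with at least three non-collinear foreground
#'   pixels.
#' @return Dimensionless value in (0, ~1] (pixelation can push convex
#'   shapes marginally above 1).
#' @export
compactness <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 3) stop("mask is degenerate: fewer than 3 foreground pixels")
  xy <- cbind(pts[, 2], pts[, 1])
  hull <- grDevices::chull(xy)
  if (length(hull) < 3) stop("mask is degenerate: foreground is collinear")
  a <- polygon_area(xy[hull, , drop = FALSE])
  if (a <= 0) stop("mask is degenerate: foreground is collinear")
  nrow(pts) / a
}

#' Box-counting fractal dimension
#'
#' Occupied-box counts N(s) over power-of-two box sizes s = 2, 4, 8, ...,
#' floor(min(H, W)/4), on a grid anchored at the mask's bounding-box
#' origin; the fractal dimension is the slope of the unweighted
#' least-squares fit of log N(s) against log(1/s). Around 1 for
#' curve-like shapes, approaching 2 for filled regions; a complexity
#' measure that grows as branches are added.
#'
#' @param mask Logical matrix.
#' @return Slope of the log-log fit.
#' @export
fractal_dimension <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (!nrow(pts)) stop("empty mask")
  smax <- floor(min(dim(mask)) / 4)
  sizes <- 2^seq_len(floor(log2(max(smax, 1))))
  if (length(sizes) < 3) stop("image too small for box counting (need >= 3 box sizes)")
  ri <- pts[, 1] - min(pts[, 1])
  ci <- pts[, 2] - min(pts[, 2])
  n_boxes <- vapply(sizes, function(s) {
    length(unique((ri %/% s) * (max(ci) %/% s + 2) + (ci %/% s)))
  }, numeric(1))
  unname(coef(stats::lm(log(n_boxes) ~ log(1 / sizes)))[2])
}

#' Skeleton length
#'
#' Sum of the pixels in the skeleton produced during the tassel-length
#' computation; an indicator of overall tassel size.
#'
#' @param skel Logical skeleton matrix.
#' @return Pixel count (0, with a warning, for an empty skeleton).
#' @export
skeleton_length <- function(skel) {
  stopifnot(is.logical(skel))
  n <- sum(skel)
  if (n == 0) warning("empty skeleton")
  n
}

#' Perimeter length
#'
#' Count of foreground pixels lying on the outline of the tassel: a
#' foreground pixel belongs to the outline unless all eight of its
#' neighbours are also foreground. Pixels beyond the image frame count as
#' background.
#'
#' @param mask Logical matrix.
#' @return Pixel count.
#' @export
perimeter <- function(mask) {
  stopifnot(is.logical(mask))
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  interior <- matrix(TRUE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    interior <- interior & pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  }
  sum(mask & !interior)
}
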