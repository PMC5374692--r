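# Midpoint-circle pixel offsets of radius r, ordered by angle.
circle_offsets <- function(radius) {
  r <- round(radius)
  stopifnot(r >= 1)
  x <- 0L; y <- r; d <- 1L - r
  xs <- integer(0); ys <- integer(0)
  while (x <= y) {
    xs <- c(xs, x); ys <- c(ys, y)
    if (d < 0L) {
      d <- d + 2L * x + 3L
    } else {
      d <- d + 2L * (x - y) + 5L
      y <- y - 1L
    }
    x <- x + 1L
  }
  dr <- c(ys, xs, -xs, -ys, -ys, -xs, xs, ys)
  dc <- c(xs, ys, ys, xs, -xs, -ys, -ys, -xs)
  pts <- unique(cbind(dr, dc))
  pts[order(atan2(pts[, 1], pts[, 2])), , drop = FALSE]
}

#' Count intersections of the mask with a circle
#'
#' The circle of the given radius is rasterized (midpoint algorithm), its
#' pixels are traversed in angular order, and maximal runs of foreground
#' pixels are counted; the first and last run are merged when both touch
#' the angular wrap-around point. Single-pixel gaps are closed first: a
#' one-pixel notch in a noisy, binarized limb edge is below the
#' rasterization noise floor, whereas true gaps between limbs span many
#' circle pixels at these radii. Circle pixels falling outside the image
#' count as background.
#'
#' @param mask Logical matrix.
#' @param center Length-2 (row, col) centre, inside the image.
#' @param radius Radius in pixels.
#' @return Number of foreground runs crossed by the circle.
#' @export
circle_intersections <- function(mask, center, radius) {
  stopifnot(center[1] >= 1, center[1] <= nrow(mask),
            center[2] >= 1, center[2] <= ncol(mask))
  off <- circle_offsets(radius)
  r <- center[1] + off[, 1]
  c <- center[2] + off[, 2]
  inside <- r >= 1 & r <= nrow(mask) & c >= 1 & c <= ncol(mask)
  fg <- logical(nrow(off))
  fg[inside] <- mask[cbind(r[inside], c[inside])]
  if (!any(fg)) return(0L)
  # close single-pixel gaps (circular)
  n <- length(fg)
  fg <- fg | (fg[c(n, 1:(n - 1))] & fg[c(2:n, 1)])
  runs <- rle(fg)
  k <- sum(runs$values)
  if (length(runs$values) > 1L && runs$values[1] && runs$values[length(runs$values)])
    k <- k - 1L
  as.integer(k)
}

#' Branch number by concentric-circle counting
#'
#' Circles centred on the lowest branch point with radii `r0`, `r0 + dr`,
#' ... are intersected with the binary tassel; radii are extended while
#' each circle still intersects the object at least once, and the greatest
#' intersection count over all circles is the branch number. Because the
#' circles also cross the stem below and the spike above the lowest branch,
#' the count includes those two crossings; no correction is subtracted,
#' matching the published behaviour of the method.
#'
#' @param mask Logical matrix (unsmoothed, QC-passed).
#' @param center Lowest branch point (row, col).
#' @param params A [tassel_params()] set (uses `circle_r0`, `circle_dr`).
#' @return Integer count; 0 (with a warning) if the first circle misses the
#'   object entirely.
#' @export
branch_number <- function(mask, center, params = tassel_params()) {
  H <- nrow(mask); W <- ncol(mask)
  rmax <- sqrt(max((c(1, H) - center[1])^2) + max((c(1, W) - center[2])^2))
  radius <- params$circle_r0
  best <- 0L
  best_radius <- NA_real_
  repeat {
    if (radius > rmax) break
    k <- circle_intersections(mask, center, radius)
    if (k == 0L) {
      if (radius == params$circle_r0)
        warning("no intersections at initial radius; branch number is 0")
      break
    }
    if (k > best) {
      best <- k
      best_radius <- radius
    }
    radius <- radius + params$circle_dr
  }
  structure(best, best_radius = best_radius)
}
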