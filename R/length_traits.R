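#' Windowed single-row sums along the main path
#'
#' For each main-path pixel (r, c), the number of foreground pixels of the
#' unsmoothed binary mask in image row r within a window of `window`
#' columns centred on c (clipped to the image). The resulting width profile
#' is narrow along the stem and wide in the branching zone, which is what
#' the lowest-branch detector exploits.
#'
#' @param mask Logical matrix (the unsmoothed, QC-passed mask).
#' @param path A `main_path` from [extract_main_path()], or an m x 2 matrix
#'   of row/col pixel coordinates ordered base to tip.
#' @param window Odd window width in pixels.
#' @return Numeric vector, one value per path pixel.
#' @export
windowed_row_sums <- function(mask, path, window = 301) {
  px <- if (inherits(path, "main_path")) path$pixels else path
  stopifnot(is.logical(mask), window %% 2 == 1)
  half <- (window - 1) / 2
  cs <- t(apply(mask * 1L, 1, cumsum))
  r <- px[, 1]; c <- px[, 2]
  lo <- pmax(c - half, 1)
  hi <- pmin(c + half, ncol(mask))
  out <- cs[cbind(r, hi)]
  has_lo <- lo > 1
  out[has_lo] <- out[has_lo] - cs[cbind(r[has_lo], lo[has_lo] - 1)]
  as.numeric(out)
}

# 1-D Gaussian smoothing with a truncated kernel, renormalized at the edges.
gaussian_smooth_1d <- function(x, width = 41, sigma = 5) {
  h <- (width - 1) / 2
  k <- stats::dnorm(-h:h, sd = sigma)
  n <- length(x)
  num <- stats::convolve(c(rep(0, h), x, rep(0, h)), k, type = "filter")
  den <- stats::convolve(c(rep(0, h), rep(1, n), rep(0, h)), k, type = "filter")
  num / den
}

#' Locate the lowest branch along the main path
#'
#' The width profile is smoothed by a 1-D Gaussian, its first derivative
#' with respect to path position is taken by central differences, and the
#' profile is scanned from the base toward the tip: the first index at
#' which the derivative exceeds `deriv_threshold` marks the entry into the
#' branching zone, i.e. the lowest branch. Scanning base-to-tip with a
#' positive-slope threshold is the only orientation for which the first
#' crossing is the lowest branch.
#'
#' @param profile Width profile from [windowed_row_sums()].
#' @param params A [tassel_params()] set.
#' @param positions Path positions (cumulative arc length) of the profile
#'   values; defaults to unit spacing.
#' @return The path index (into `profile`) of the lowest branch.
#' @export
locate_lowest_branch <- function(profile, params = tassel_params(),
                                 positions = seq_along(profile) - 1) {
  stopifnot(length(profile) >= params$profile_kernel_width)
  sm <- gaussian_smooth_1d(profile, params$profile_kernel_width,
                           params$profile_kernel_sigma)
  n <- length(sm)
  d <- numeric(n)
  d[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) /
    (positions[3:n] - positions[1:(n - 2)])
  d[1] <- (sm[2] - sm[1]) / (positions[2] - positions[1])
  d[n] <- (sm[n] - sm[n - 1]) / (positions[n] - positions[n - 1])
  idx <- which(d > params$deriv_threshold)
  if (!length(idx)) stop("no branch detected")
  idx[1]
}

# Net heading change (degrees) of a path, measured on a decimated copy so
# pixel jitter cancels: local wobble contributes equal and opposite turns,
# genuine curvature accumulates.
path_net_turn <- function(pixels, s, chunk = 40) {
  if (max(s) < 3 * chunk) return(0)
  grid <- seq(0, max(s), by = chunk)
  r <- stats::approx(s, pixels[, 1], grid)$y
  c <- stats::approx(s, pixels[, 2], grid)$y
  h <- atan2(diff(c), -diff(r))
  dh <- diff(h)
  abs(sum(atan2(sin(dh), cos(dh)))) * 180 / pi
}

#' Fit cubic smoothing splines to the main path
#'
#' Row and column coordinates are fitted as cubic smoothing splines of the
#' cumulative chordal arc-length parameter. The default degrees of freedom
#' grow with path length and with the path's net heading change (see
#' [tassel_params()]): enough to follow genuine curvature of the spike
#' while suppressing pixel-level stair-stepping and the local skeleton
#' wobble introduced near branch junctions, which has no net turn. Fewer
#' than four points fall back to a straight segment.
#'
#' @param pixels m x 2 matrix of row/col path pixels (lowest branch to tip).
#' @param params A [tassel_params()] set.
#' @return An object of class `main_spline`.
#' @export
fit_main_spline <- function(pixels, params = tassel_params()) {
  pixels <- as.matrix(pixels)
  m <- nrow(pixels)
  step <- sqrt(rowSums((pixels[-1, , drop = FALSE] -
                        pixels[-m, , drop = FALSE])^2))
  s <- c(0, cumsum(step))
  if (m < 4) {
    return(structure(list(linear = TRUE, s_range = range(s),
                          pixels = pixels, s = s),
                     class = "main_spline"))
  }
  df <- max(params$spline_min_df, params$spline_df_per_px * max(s),
            4 + path_net_turn(pixels, s) / 15)
  df <- min(df, m - 1)
  fr <- stats::smooth.spline(s, pixels[, 1], df = df)
  fc <- stats::smooth.spline(s, pixels[, 2], df = df)
  structure(list(linear = FALSE, fr = fr, fc = fc, s_range = range(s),
                 n_px = m),
            class = "main_spline")
}

#' Evaluate a fitted main-path spline
#'
#' @param spline A `main_spline`.
#' @param s Arc-length parameter values.
#' @return Matrix with columns row, col.
#' @export
predict_spline <- function(spline, s) {
  if (spline$linear) {
    r <- stats::approx(spline$s, spline$pixels[, 1], xout = s, rule = 2)$y
    c <- stats::approx(spline$s, spline$pixels[, 2], xout = s, rule = 2)$y
    return(cbind(row = r, col = c))
  }
  cbind(row = stats::predict(spline$fr, s)$y,
        col = stats::predict(spline$fc, s)$y)
}

#' Tassel length as the line integral of the main-path spline
#'
#' Arc length of the fitted spline by dense parameter sampling (at least
#' ten samples per path pixel) and summed Euclidean increments.
#'
#' @param spline A `main_spline` from [fit_main_spline()].
#' @param oversample Samples per path pixel.
#' @return Length in pixels.
#' @export
tassel_length <- function(spline, oversample = 10) {
  n <- if (spline$linear) nrow(spline$pixels) else spline$n_px
  grid <- seq(spline$s_range[1], spline$s_range[2],
              length.out = max(2, oversample * n))
  pts <- predict_spline(spline, grid)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Tortuosity of the main axis
#'
#' Euclidean distance between the lowest branch and the spike tip divided
#' by the tassel length: 1 for a perfectly straight spike, smaller for
#' curved ones. In the pipeline the two anchor points are the spline's
#' evaluated endpoints, which guarantees chord <= arc and hence a value in
#' (0, 1].
#'
#' @param lowest_branch_px,tip_px Length-2 vectors (row, col).
#' @param tassel_length_px Tassel length in pixels.
#' @return Dimensionless value in (0, 1].
#' @export
tortuosity <- function(lowest_branch_px, tip_px, tassel_length_px) {
  if (tassel_length_px <= 0) stop("tassel length must be positive")
  sqrt(sum((lowest_branch_px - tip_px)^2)) / tassel_length_px
}

#' Convert pixels to millimetres
#'
#' @param value_px Value in pixels (or px^2 when `power = 2`).
#' @param scale_mm_per_px Scale factor in mm per pixel.
#' @param power 1 for lengths, 2 for areas.
#' @return Value in mm (or mm^2).
#' @export
px_to_mm <- function(value_px, scale_mm_per_px, power = 1) {
  if (is.na(scale_mm_per_px)) return(NA_real_)
  if (scale_mm_per_px <= 0) stop("scale must be positive")
  value_px * scale_mm_per_px^power
}
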