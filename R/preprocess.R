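#' Background subtraction
#'
#' Per-pixel absolute difference between the sample and background images.
#' The absolute value makes the operation symmetric in its arguments and
#' robust to the tassel being darker or lighter than the booth background.
#'
#' @param pair An [image_pair()].
#' @return A nonnegative numeric matrix; near zero over the background,
#'   large over the tassel.
#' @export
subtract_background <- function(pair) {
  stopifnot(inherits(pair, "image_pair"))
  abs(pair$sample - pair$background)
}

#' Otsu threshold of an 8-bit histogram
#'
#' Exhaustive between-class-variance maximization over the 256-bin
#' histogram. Ties are broken by the lower threshold. A degenerate
#' histogram (all mass in one bin) has no valid split and returns `NA`.
#'
#' @param counts Integer vector of length 256: counts of intensities
#'   0..255.
#' @return The chosen threshold t (pixels with intensity > t are
#'   foreground), or `NA` if the histogram is degenerate.
#' @export
otsu_threshold <- function(counts) {
  stopifnot(length(counts) == 256L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  p <- counts / n
  lev <- 0:255
  w0 <- cumsum(p)[1:255]              # class {0..t}, t = 0..254
  m0 <- cumsum(p * lev)[1:255]
  mt <- sum(p * lev)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  if (!any(valid)) return(NA_real_)
  mu0 <- m0 / w0
  mu1 <- (mt - m0) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[!valid] <- -Inf
  (0:254)[which.max(bcv)]
}

new_tassel_mask <- function(mask, threshold_used, qc_status, source_id) {
  structure(list(mask = mask, threshold_used = threshold_used,
                 qc_status = qc_status, source_id = source_id),
            class = "tassel_mask")
}

#' @export
print.tassel_mask <- function(x, ...) {
  cat(sprintf("<tassel_mask> %s: %s, threshold %s, %d foreground px\n",
              x$source_id, x$qc_status, format(x$threshold_used),
              sum(x$mask)))
  invisible(x)
}

#' Binarize a background-difference image
#'
#' Thresholds the difference image at the automatically chosen Otsu level.
#' If the chosen threshold falls below `min_threshold` the image is assumed
#' to contain no tassel (or too little contrast for a faithful threshold)
#' and is rejected.
#'
#' @param diff Nonnegative difference image from [subtract_background()].
#' @param min_threshold Minimum acceptable automatic threshold.
#' @param source_id Identifier recorded in the result.
#' @return A `tassel_mask` with `qc_status` either `"PASS"` (pending the
#'   later component and border checks) or `"REJECT_LOW_THRESHOLD"`.
#' @export
binarize <- function(diff, min_threshold = 10, source_id = "sample") {
  stopifnot(all(diff >= 0))
  d8 <- round(pmin(diff, 255))
  counts <- tabulate(as.integer(d8) + 1L, nbins = 256L)
  th <- otsu_threshold(counts)
  if (is.na(th) || th < min_threshold) {
    return(new_tassel_mask(matrix(FALSE, nrow(diff), ncol(diff)),
                           th, "REJECT_LOW_THRESHOLD", source_id))
  }
  new_tassel_mask(d8 > th, th, "PASS", source_id)
}

#' Retain only the largest connected component
#'
#' Foreground components are 8-connected; all but the largest (by pixel
#' count) are removed, which discards small debris, reflections and dirt
#' that survive background subtraction. Ties are broken in favour of the
#' component whose topmost-leftmost pixel is lexicographically smallest in
#' (row, column).
#'
#' @param mask Logical matrix.
#' @return Logical matrix with at most one foreground component.
#' @export
keep_largest_component <- function(mask) {
  stopifnot(is.logical(mask))
  if (!any(mask)) return(mask)
  lab <- .label_components8_cpp(mask)
  sizes <- tabulate(lab[lab > 0L])
  if (length(sizes) == 1L) return(mask)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # lexicographic (row, col) key of each tied component's first pixel
    key <- vapply(best, function(l) {
      px <- which(lab == l, arr.ind = TRUE)
      min((px[, 1] - 1) * ncol(mask) + (px[, 2] - 1))
    }, numeric(1))
    best <- best[which.min(key)]
  }
  lab == best
}

#' Border-contact check
#'
#' A mask whose foreground touches any image border indicates a tassel
#' extending outside the frame; such images cannot be measured.
#'
#' @param mask Logical matrix (single foreground component).
#' @return `"REJECT_BORDER_CONTACT"` or `"PASS"`.
#' @export
check_border_contact <- function(mask) {
  touches <- any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
  if (touches) "REJECT_BORDER_CONTACT" else "PASS"
}

#' Full pre-processing of an image pair
#'
#' Background subtraction, Otsu binarization with the low-threshold gate,
#' largest-component filtering, and the border-contact gate, in that order.
#'
#' @param pair An [image_pair()].
#' @param params A [tassel_params()] set.
#' @return A `tassel_mask`; `qc_status` is `"PASS"` only if the mask has
#'   exactly one foreground component clear of the border.
#' @export
preprocess_pair <- function(pair, params = tassel_params()) {
  diff <- subtract_background(pair)
  tm <- binarize(diff, params$min_threshold, pair$sample_id)
  if (tm$qc_status != "PASS") return(tm)
  m <- keep_largest_component(tm$mask)
  if (!any(m)) {
    tm$mask <- m
    tm$qc_status <- "REJECT_EMPTY"
    return(tm)
  }
  tm$mask <- m
  tm$qc_status <- check_border_contact(m)
  tm
}
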