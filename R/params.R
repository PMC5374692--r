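#' Analysis parameter set
#'
#' Collects every tunable parameter of the measurement pipeline with its
#' default. All defaults follow the published tassel-imaging protocol where
#' that protocol states a value; the remainder are documented package
#' choices. Every result row carries a hash of the parameter set used
#' to produce it, so sweeps over parameter values remain distinguishable in
#' merged result tables.
#'
#' @param min_threshold Minimum acceptable automatic threshold on the 8-bit
#'   background-difference image. An image whose chosen threshold falls below
#'   this value is rejected as having no tassel or too little contrast.
#' @param smooth_kernel_size Side length (odd, pixels) of the isometric 2-D
#'   Gaussian kernel used to smooth the binary mask before skeletonization.
#' @param smooth_kernel_sigma Standard deviation (pixels) of that kernel.
#'   With the default 31-pixel support and sigma 55 the truncated kernel is
#'   nearly uniform.
#' @param rethreshold_level Level in (0,1) at which the smoothed mask is
#'   re-thresholded to a binary mask.
#' @param spur_min_dist Endpoints of the skeleton closer than this path
#'   distance (pixels) to a branch point are excluded from spike-tip
#'   candidacy; protrusions such as spikelets otherwise masquerade as
#'   branches.
#' @param profile_window Width (odd, pixels) of the window, centred on the
#'   main path, over which single-row sums of the unsmoothed mask are taken
#'   to build the width profile used for lowest-branch detection.
#' @param profile_kernel_width,profile_kernel_sigma Width and standard
#'   deviation (pixels) of the 1-D Gaussian used to smooth the width profile.
#' @param deriv_threshold Threshold on the first derivative of the smoothed
#'   width profile with respect to path position; the first base-to-tip
#'   crossing marks the lowest branch.
#' @param spline_df_per_px Degrees of freedom per pixel of path length for
#'   the cubic smoothing splines fitted to the main path coordinates; a
#'   further term proportional to the path's net heading change is added
#'   automatically so strongly curved paths get the flexibility they need.
#' @param spline_min_df Lower bound on spline degrees of freedom.
#' @param circle_r0 Radius (pixels) of the first circle centred on the
#'   lowest branch point for branch counting.
#' @param circle_dr Radius increment (pixels) between successive circles.
#' @param scale_mm_per_px Scale factor converting pixels to millimetres
#'   (from the tassel-holder base); `NA` leaves mm-valued traits `NA`.
#'
#' @return An object of class `tassel_params` (a named list).
#' @examples
#' p <- tassel_params(scale_mm_per_px = 0.2)
#' p$circle_r0
#' @export
tassel_params <- function(min_threshold = 10,
                          smooth_kernel_size = 31,
                          smooth_kernel_sigma = 55,
                          rethreshold_level = 0.5,
                          spur_min_dist = 75,
                          profile_window = 301,
                          profile_kernel_width = 41,
                          profile_kernel_sigma = 5,
                          deriv_threshold = 0.2,
                          spline_df_per_px = 0.01,
                          spline_min_df = 5,
                          circle_r0 = 100,
                          circle_dr = 50,
                          scale_mm_per_px = NA_real_) {
  p <- list(min_threshold = min_threshold,
            smooth_kernel_size = as.integer(smooth_kernel_size),
            smooth_kernel_sigma = smooth_kernel_sigma,
            rethreshold_level = rethreshold_level,
            spur_min_dist = spur_min_dist,
            profile_window = as.integer(profile_window),
            profile_kernel_width = as.integer(profile_kernel_width),
            profile_kernel_sigma = profile_kernel_sigma,
            deriv_threshold = deriv_threshold,
            spline_df_per_px = spline_df_per_px,
            spline_min_df = spline_min_df,
            circle_r0 = circle_r0,
            circle_dr = circle_dr,
            scale_mm_per_px = scale_mm_per_px)
  stopifnot(p$smooth_kernel_size %% 2L == 1L, p$smooth_kernel_size >= 3L,
            p$smooth_kernel_sigma > 0,
            p$rethreshold_level > 0, p$rethreshold_level < 1,
            p$profile_window %% 2L == 1L,
            p$deriv_threshold > 0,
            p$circle_r0 > 0, p$circle_dr > 0,
            is.na(p$scale_mm_per_px) || p$scale_mm_per_px > 0)
  class(p) <- "tassel_params"
  p
}

#' Read parameters from a key=value config file
#'
#' Lines of the form `name = value`; blank lines and `#` comments ignored.
#' Unknown keys are an error. Values are parsed as numerics.
#'
#' @param path Path to the config file.
#' @param ... Overrides applied after the file is read (highest precedence).
#' @return A `tassel_params` object.
#' @export
read_params <- function(path, ...) {
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  kv <- strsplit(ln, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(ln[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[[`, "", 2L)))
  args <- stats::setNames(as.list(vals), keys)
  args <- utils::modifyList(args, list(...))
  known <- names(formals(tassel_params))
  unknown <- setdiff(names(args), known)
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  do.call(tassel_params, args)
}

#' Short stable hash of a parameter set
#'
#' FNV-1a over the canonical `key=value` serialization; recorded in every
#' result row so that outputs of different parameter sweeps can be told
#' apart.
#'
#' @param params A `tassel_params` object.
#' @return An 8-character hexadecimal string.
#' @export
params_hash <- function(params) {
  stopifnot(inherits(params, "tassel_params"))
  s <- paste(names(params), vapply(params, format, "", digits = 15),
             sep = "=", collapse = ";")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor on 16-bit halves: h can exceed .Machine$integer.max
    h <- bitwXor(h %% 65536, b %% 65536) +
      bitwXor(h %/% 65536, b %/% 65536) * 65536
    # 32-bit FNV prime (2^24 + 403) multiply, split to stay exact in doubles
    lo <- (h %% 65536) * 403
    hi <- ((h %/% 65536) * 403) %% 65536
    h <- (lo + hi * 65536 + (h %% 256) * 16777216) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' @export
print.tassel_params <- function(x, ...) {
  cat("<tassel_params>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
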