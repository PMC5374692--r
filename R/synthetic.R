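# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Parametric description of a synthetic tassel image pair
#'
#' Describes a booth-style image pair: a bright, mildly noisy background
#' with an illumination gradient, and a dark tassel composited onto it. The
#' tassel's main axis is an arc-length-parameterized circular arc entering
#' from the bottom centre: a bare stem of `stem_length`, a branching zone
#' of `branch_zone_length` carrying `n_branches` straight branches
#' (alternating sides, lower branches longer and more horizontal, the
#' lowest attached exactly at the top of the stem), and an unbranched
#' spike of `spike_length`. Every morphological quantity the pipeline
#' measures is known exactly from this description.
#'
#' @param image_size c(rows, cols) of the images.
#' @param stem_length,branch_zone_length,spike_length Arc lengths (px) of
#'   the three segments of the main axis.
#' @param n_branches Number of primary branches (0 = bare spike).
#' @param branch_lengths Lengths (px) of the branches; default tapers from
#'   about 420 at the bottom to about 300 at the top of the zone, each
#'   nudged by up to 25 px so that the rounded branch tip ends midway
#'   between two branch-counting radii (see [branch_number()]).
#' @param branch_angles Signed angles (degrees from vertical; sign = side);
#'   default alternates sides with magnitudes from 65 (lowest) to 30.
#' @param branch_width,stem_width,spike_width Limb widths in pixels.
#' @param curvature Signed reciprocal radius (1/px) of the main axis; 0 is
#'   straight.
#' @param background_level,tassel_level 8-bit intensities of booth
#'   background and tassel.
#' @param illumination_gradient Peak-to-peak intensity of the planar
#'   illumination gradient across the frame.
#' @param noise_sd Gaussian intensity noise, independent per image.
#' @param n_debris Small bright-floor debris blobs added to the sample
#'   image only (they survive background subtraction and exercise the
#'   largest-component filter).
#' @param n_spikelets Small protrusions stamped along the spike to
#'   exercise skeleton spur pruning.
#' @param bottom_margin Rows between the stem base and the bottom border
#'   (0 makes the tassel touch the border, triggering the QC gate).
#' @param seed RNG seed; the generated pair is a pure function of the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_size = c(1500, 1000),
                           stem_length = 424,
                           branch_zone_length = 220,
                           spike_length = 450,
                           n_branches = 6,
                           branch_lengths = NULL,
                           branch_angles = NULL,
                           branch_width = 18,
                           stem_width = 24,
                           spike_width = 20,
                           curvature = 0,
                           background_level = 215,
                           tassel_level = 40,
                           illumination_gradient = 12,
                           noise_sd = 2,
                           n_debris = 3,
                           n_spikelets = 8,
                           bottom_margin = 40,
                           seed = 1) {
  k <- n_branches
  if (is.null(branch_angles))
    branch_angles <- if (k > 0)
      rep(c(-1, 1), length.out = k) * seq(65, 30, length.out = k)
    else numeric(0)
  if (is.null(branch_lengths)) {
    branch_lengths <- if (k > 0) seq(420, 300, length.out = k) else numeric(0)
    # Nudge each default length so the branch's rounded tip ends midway
    # between two counting radii (50-px grid): a tip cap lying almost
    # exactly on a circle is clipped tangentially by rasterization, which
    # would make the circle-count ground truth ambiguous.
    if (k > 0) {
      d <- if (k > 1) (seq_len(k) - 1) / (k - 1) * branch_zone_length else 0
      a <- abs(branch_angles) * pi / 180
      for (it in 1:3) {
        reach <- sqrt((d + branch_lengths * cos(a))^2 +
                      (branch_lengths * sin(a))^2) + branch_width / 2
        delta <- (reach - 20) %% 50
        adj <- delta - ifelse(delta > 25, 50, 0)
        dr_dl <- (d * cos(a) + branch_lengths) /
          sqrt((d + branch_lengths * cos(a))^2 + (branch_lengths * sin(a))^2)
        branch_lengths <- branch_lengths - adj / dr_dl
      }
    }
  }
  stopifnot(stem_length > 0, branch_zone_length > 0, spike_length > 0,
            k == length(branch_lengths), k == length(branch_angles),
            all(branch_lengths > 0), branch_width > 0, stem_width > 0,
            spike_width > 0, noise_sd >= 0, bottom_margin >= 0)
  spec <- list(image_size = image_size, stem_length = stem_length,
               branch_zone_length = branch_zone_length,
               spike_length = spike_length, n_branches = k,
               branch_lengths = branch_lengths,
               branch_angles = branch_angles,
               branch_width = branch_width, stem_width = stem_width,
               spike_width = spike_width, curvature = curvature,
               background_level = background_level,
               tassel_level = tassel_level,
               illumination_gradient = illumination_gradient,
               noise_sd = noise_sd, n_debris = n_debris,
               n_spikelets = n_spikelets, bottom_margin = bottom_margin,
               seed = seed)
  class(spec) <- "synthetic_spec"
  spec
}

# Points on the main axis at arc lengths s (0 = stem base). The heading
# turns linearly with s (circular arc of curvature c); closed forms keep
# the parameterization exactly arc-length.
axis_points <- function(spec, s) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  r0 <- H - spec$bottom_margin
  c0 <- floor(W / 2) + 1
  cc <- spec$curvature
  if (abs(cc) < 1e-12) {
    cbind(row = r0 - s, col = rep(c0, length(s)))
  } else {
    cbind(row = r0 - sin(cc * s) / cc, col = c0 + (1 - cos(cc * s)) / cc)
  }
}

# Tangent headings (radians from vertical) at arc lengths s.
axis_heading <- function(spec, s) spec$curvature * s

# Arc positions where branches attach (lowest exactly at the stem top).
branch_positions <- function(spec) {
  k <- spec$n_branches
  if (k == 0) return(numeric(0))
  if (k == 1) return(spec$stem_length)
  spec$stem_length + (seq_len(k) - 1) / (k - 1) * spec$branch_zone_length
}

# Rasterize a polyline sampled at 0.5-px steps as a stroked band of width
# w (discs of radius w/2 stamped at every sample; clipped to the frame).
stamp_limb <- function(canvas, pts, w) {
  canvas | .stamp_discs_cpp(nrow(canvas), ncol(canvas),
                            pts[, 1], pts[, 2], w / 2)
}

render_tassel_mask <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  mask <- matrix(FALSE, H, W)
  L_total <- spec$stem_length + spec$branch_zone_length + spec$spike_length
  s_stem <- seq(0, spec$stem_length, by = 0.5)
  s_up <- seq(spec$stem_length, L_total, by = 0.5)
  mask <- stamp_limb(mask, axis_points(spec, s_stem), spec$stem_width)
  mask <- stamp_limb(mask, axis_points(spec, s_up), spec$spike_width)
  bp <- branch_positions(spec)
  for (j in seq_len(spec$n_branches)) {
    a <- spec$branch_angles[j] * pi / 180
    dir <- c(-cos(abs(a)), sign(a) * sin(abs(a)))
    A <- axis_points(spec, bp[j])[1, ]
    t <- seq(0, spec$branch_lengths[j], by = 0.5)
    pts <- cbind(A[1] + t * dir[1], A[2] + t * dir[2])
    end <- pts[nrow(pts), ]
    if (end[1] < 3 || end[1] > H - 2 || end[2] < 3 || end[2] > W - 2)
      stop(sprintf("branch %d exits the frame (ends at %.0f,%.0f)",
                   j, end[1], end[2]))
    mask <- stamp_limb(mask, pts, spec$branch_width)
  }
  if (spec$n_spikelets > 0) {
    s_sp <- runif(spec$n_spikelets, spec$stem_length + 20, L_total - 10)
    side <- sample(c(-1, 1), spec$n_spikelets, replace = TRUE)
    phi <- axis_heading(spec, s_sp)
    ctr <- axis_points(spec, s_sp)
    ctr[, 1] <- ctr[, 1] + side * sin(phi) * spec$spike_width / 2
    ctr[, 2] <- ctr[, 2] + side * cos(phi) * spec$spike_width / 2
    mask <- stamp_limb(mask, ctr, 9)
  }
  mask
}

#' Generate a synthetic image pair with ground truth
#'
#' Renders the tassel described by `spec` onto a booth-style background
#' (gradient + noise), with an independent-noise empty background image,
#' soft anti-aliased tassel edges, and optional debris blobs in the sample
#' image only. The returned ground truth is computed from the spec's
#' geometry (analytically for lengths and chords, by construction for the
#' rendered mask), never from the images.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_tassel`: `pair` (an [image_pair()]),
#'   `truth` (one-row data.frame of exact morphology), `mask` (the rendered
#'   tassel mask before compositing).
#' @export
generate_tassel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    H <- spec$image_size[1]; W <- spec$image_size[2]
    rows <- matrix(seq_len(H) / H, H, W)
    cols <- matrix(rep(seq_len(W) / W, each = H), H, W)
    field <- spec$background_level +
      spec$illumination_gradient * (0.7 * (cols - 0.5) + 0.3 * (rows - 0.5))
    background <- field + rnorm(H * W, sd = spec$noise_sd)
    tassel <- render_tassel_mask(spec)

    debris <- matrix(FALSE, H, W)
    if (spec$n_debris > 0) {
      px <- which(tassel, arr.ind = TRUE)
      bb <- c(range(px[, 1]), range(px[, 2]))
      for (i in seq_len(spec$n_debris)) {
        for (try in 1:20) {
          rr <- runif(1, 20, H - 20); cc <- runif(1, 20, W - 20)
          clear <- rr < bb[1] - 60 || rr > bb[2] + 60 ||
            cc < bb[3] - 60 || cc > bb[4] + 60
          if (clear) {
            debris <- stamp_limb(debris, cbind(rr, cc),
                                 round(runif(1, 6, 16)))
            break
          }
        }
      }
    }

    at <- pmin(pmax(gaussian_convolve2d(tassel * 1, 5, 1), 0), 1)
    ad <- pmin(pmax(gaussian_convolve2d(debris * 1, 5, 1), 0), 1)
    sample_img <- field * (1 - at) + spec$tassel_level * at
    sample_img <- sample_img * (1 - ad) + 90 * ad
    sample_img <- sample_img + rnorm(H * W, sd = spec$noise_sd)

    background <- round(pmin(pmax(background, 0), 255))
    sample_img <- round(pmin(pmax(sample_img, 0), 255))

    L_total <- spec$stem_length + spec$branch_zone_length + spec$spike_length
    true_len <- spec$branch_zone_length + spec$spike_length
    lb <- axis_points(spec, spec$stem_length)[1, ]
    tip <- axis_points(spec, L_total)[1, ]
    chord <- sqrt(sum((lb - tip)^2))
    border <- any(tassel[1, ]) || any(tassel[H, ]) ||
      any(tassel[, 1]) || any(tassel[, W])
    contrast <- abs(spec$background_level - spec$tassel_level)
    expected_qc <- if (border) "REJECT_BORDER_CONTACT"
      else if (contrast < 20) "REJECT_LOW_THRESHOLD" else "PASS"
    id <- sprintf("synth%06d", spec$seed %% 1000000)
    truth <- data.frame(
      sample_id = id,
      seed = spec$seed,
      n_branches = spec$n_branches,
      curvature = spec$curvature,
      true_length_px = if (spec$n_branches > 0) true_len else NA_real_,
      true_chord_px = if (spec$n_branches > 0) chord else NA_real_,
      true_tortuosity = if (spec$n_branches > 0) chord / true_len else NA_real_,
      true_lowest_branch_row = round(lb[1]),
      true_lowest_branch_col = round(lb[2]),
      true_area_px = sum(tassel),
      expected_circle_count = if (spec$n_branches > 0)
        spec$n_branches + 2L else 2L,
      expected_qc = expected_qc,
      stringsAsFactors = FALSE)
    structure(list(pair = image_pair(background, sample_img, id),
                   truth = truth, mask = tassel, spec = spec),
              class = "synthetic_tassel")
  })
}

#' Deterministic specification list for a validation suite
#'
#' Cycles branch counts 0-12, curvatures (straight and gently curved both
#' ways), and noise levels; optionally appends one frame-clipped pair and
#' one low-contrast pair so that both QC rejection paths are exercised.
#'
#' @param n Number of pairs.
#' @param seed Master seed; each spec gets a distinct derived seed.
#' @param qc_failures Include the two QC-failure pairs (as the last two).
#' @return List of [synthetic_spec()] objects.
#' @export
suite_specs <- function(n = 20, seed = 1, qc_failures = TRUE) {
  curvatures <- c(0, 1 / 3500, 0, -1 / 3500, 0, 1 / 5000)
  lapply(seq_len(n), function(i) {
    s <- (seed %% 20000) * 100000 + i
    if (qc_failures && i == n - 1 && n >= 2)
      return(synthetic_spec(n_branches = 4, bottom_margin = 0, seed = s))
    if (qc_failures && i == n && n >= 2)
      return(synthetic_spec(n_branches = 4, tassel_level = 207,
                            background_level = 215, n_debris = 0, seed = s))
    k <- (i - 1) %% 13
    synthetic_spec(n_branches = k,
                   curvature = curvatures[(i - 1) %% length(curvatures) + 1],
                   noise_sd = if (i %% 7 == 0) 4 else 2,
                   seed = s)
  })
}

#' Write a reproducible fixture suite to disk
#'
#' Generates `n` image pairs (PNG) named `<id>_background.png` /
#' `<id>_sample.png` plus a `ground_truth.csv` manifest whose columns align
#' with the pipeline's result table for join-based testing.
#'
#' @param dir Output directory (created if needed).
#' @param n Number of pairs.
#' @param seed Master seed.
#' @param qc_failures Include QC-failure pairs (see [suite_specs()]).
#' @return The manifest data.frame, invisibly.
#' @export
make_fixture_suite <- function(dir, n = 20, seed = 1, qc_failures = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- suite_specs(n, seed, qc_failures)
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    st <- generate_tassel(specs[[i]])
    id <- st$truth$sample_id
    write_gray_png(st$pair$background, file.path(dir, paste0(id, "_background.png")))
    write_gray_png(st$pair$sample, file.path(dir, paste0(id, "_sample.png")))
    rows[[i]] <- st$truth
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
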