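empty_record <- function() {
  data.frame(sample_id = character(0), qc_status = character(0),
             qc_detail = character(0), threshold_used = numeric(0),
             tassel_length_px = numeric(0), tassel_length_mm = numeric(0),
             branch_number_image = numeric(0), area_px = numeric(0),
             area_mm2 = numeric(0), tortuosity = numeric(0),
             compactness = numeric(0), fractal_dimension = numeric(0),
             skeleton_length_px = numeric(0), skeleton_length_mm = numeric(0),
             perimeter_px = numeric(0), perimeter_mm = numeric(0),
             lowest_branch_row = numeric(0), lowest_branch_col = numeric(0),
             param_hash = character(0), stringsAsFactors = FALSE)
}

#' Measure one image pair
#'
#' Runs the full measurement chain on a single pair: pre-processing and QC
#' gates, mask smoothing, skeletonization, base detection, geodesic main
#' path, lowest-branch detection, spline-based tassel length and
#' tortuosity, circle-based branch number, and the size/shape traits.
#' Failures at any stage yield a row with the corresponding rejection code
#' instead of aborting.
#'
#' @param pair An [image_pair()].
#' @param params A [tassel_params()] set.
#' @param detail Also return the intermediate objects (mask, skeleton,
#'   path, spline, winning circle radius) for QC overlays.
#' @return A one-row data.frame (the trait record); with `detail = TRUE`,
#'   a list `(record, internals)`.
#' @export
analyze_pair <- function(pair, params = tassel_params(), detail = FALSE) {
  rec <- empty_record()[1, ]
  rec$sample_id <- pair$sample_id
  rec$param_hash <- params_hash(params)
  rec$qc_detail <- ""
  internals <- NULL
  scale <- params$scale_mm_per_px

  tm <- preprocess_pair(pair, params)
  rec$qc_status <- tm$qc_status
  rec$threshold_used <- if (is.na(tm$threshold_used)) NA_real_ else tm$threshold_used

  if (tm$qc_status == "PASS") {
    res <- tryCatch({
      sm <- smooth_mask(tm$mask, params)
      if (!any(sm)) stop("smoothing erased all foreground")
      skel <- skeletonize(sm)
      sg <- skeleton_graph(skel)
      base <- find_base(sg)
      dists <- geodesic_distances(sg, base)
      cands <- prune_spurs(sg, params$spur_min_dist)
      mp <- extract_main_path(sg, base, dists, cands)
      prof <- windowed_row_sums(tm$mask, mp, params$profile_window)
      lbi <- locate_lowest_branch(prof, params, positions = mp$s)
      sub <- mp$pixels[lbi:nrow(mp$pixels), , drop = FALSE]
      spl <- fit_main_spline(sub, params)
      len <- tassel_length(spl)
      ends <- predict_spline(spl, spl$s_range)
      lb_px <- mp$pixels[lbi, ]
      warn <- character(0)
      bn <- withCallingHandlers(
        branch_number(tm$mask, lb_px, params),
        warning = function(w) {
          warn <<- c(warn, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      list(len = len, tort = tortuosity(ends[1, ], ends[2, ], len),
           lb_px = lb_px, bn = bn, skel = skel, sm = sm, mp = mp,
           spl = spl, warn = warn)
    }, error = function(e) e)

    if (inherits(res, "error")) {
      msg <- conditionMessage(res)
      rec$qc_status <- if (grepl("no branch detected", msg))
        "REJECT_NO_BRANCH"
      else if (grepl("no candidate spike tip", msg)) "REJECT_NO_TIP"
      else if (grepl("erased all foreground", msg)) "REJECT_EMPTY"
      else "ERROR"
      rec$qc_detail <- msg
    } else {
      rec$tassel_length_px <- res$len
      rec$tassel_length_mm <- px_to_mm(res$len, scale)
      rec$branch_number_image <- as.integer(res$bn)
      rec$tortuosity <- res$tort
      rec$area_px <- mask_area(tm$mask)
      rec$area_mm2 <- px_to_mm(rec$area_px, scale, power = 2)
      rec$compactness <- compactness(tm$mask)
      rec$fractal_dimension <- fractal_dimension(tm$mask)
      rec$skeleton_length_px <- skeleton_length(res$skel)
      rec$skeleton_length_mm <- px_to_mm(rec$skeleton_length_px, scale)
      rec$perimeter_px <- perimeter(tm$mask)
      rec$perimeter_mm <- px_to_mm(rec$perimeter_px, scale)
      rec$lowest_branch_row <- res$lb_px[1]
      rec$lowest_branch_col <- res$lb_px[2]
      if (length(res$warn)) rec$qc_detail <- paste(res$warn, collapse = "; ")
      internals <- res
      internals$mask <- tm$mask
    }
  }
  rownames(rec) <- NULL
  if (detail) list(record = rec, internals = internals) else rec
}

# QC overlay: mask in gray, main path red, fitted spline green, winning
# branch-count circle yellow.
write_overlay <- function(internals, path) {
  m <- internals$mask
  H <- nrow(m); W <- ncol(m)
  r <- g <- b <- m * 0.55
  put <- function(px, ch) {
    px <- round(px)
    ok <- px[, 1] >= 1 & px[, 1] <= H & px[, 2] >= 1 & px[, 2] <= W
    px <- px[ok, , drop = FALSE]
    if (ch %in% c("r", "y")) r[cbind(px[, 1], px[, 2])] <<- 1
    if (ch %in% c("g", "y")) g[cbind(px[, 1], px[, 2])] <<- 1
    if (ch == "r") g[cbind(px[, 1], px[, 2])] <<- 0.1
  }
  put(internals$mp$pixels, "r")
  grid <- seq(internals$spl$s_range[1], internals$spl$s_range[2],
              length.out = 2000)
  put(predict_spline(internals$spl, grid), "g")
  br <- attr(internals$bn, "best_radius")
  if (!is.na(br)) {
    circ <- circle_offsets(br)
    put(cbind(circ[, 1] + internals$lb_px[1],
              circ[, 2] + internals$lb_px[2]), "y")
  }
  img <- EBImage::rgbImage(EBImage::Image(t(r)), EBImage::Image(t(g)),
                           EBImage::Image(t(b)))
  EBImage::writeImage(img, path, type = "png")
  invisible(path)
}

#' Run the measurement pipeline over a batch of image pairs
#'
#' Discovers pairs (directory naming convention or manifest CSV), measures
#' each, and writes `results.csv` (one row per pair, rejected pairs
#' retained with their reason code), a structured log, and optional
#' per-sample QC overlay PNGs. Output rows are sorted by `sample_id`, so
#' results are independent of discovery order; the whole run is
#' deterministic for fixed inputs and parameters.
#'
#' @param input Input directory or manifest CSV (see [discover_pairs()]).
#' @param output_dir Directory for `results.csv`, `batch_log.txt` and
#'   overlays; `NULL` skips writing.
#' @param params A [tassel_params()] set.
#' @param overlays Write QC overlay PNGs for PASS rows.
#' @return The results data.frame.
#' @export
run_batch <- function(input, output_dir = NULL, params = tassel_params(),
                      overlays = FALSE) {
  pairs <- discover_pairs(input)
  if (!is.null(output_dir))
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!nrow(pairs)) {
    warning("no image pairs found in ", input)
    out <- empty_record()
  } else {
    log_lines <- character(0)
    rows <- vector("list", nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch({
        pair <- read_image_pair(pairs$background_path[i],
                                pairs$sample_path[i], pairs$sample_id[i])
        analyze_pair(pair, params, detail = overlays)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        rec <- empty_record()[1, ]
        rec$sample_id <- pairs$sample_id[i]
        rec$qc_status <- "ERROR"
        rec$qc_detail <- conditionMessage(res)
        rec$param_hash <- params_hash(params)
        rownames(rec) <- NULL
      } else if (overlays) {
        rec <- res$record
        if (!is.null(res$internals) && !is.null(output_dir))
          write_overlay(res$internals,
                        file.path(output_dir,
                                  paste0(rec$sample_id, "_overlay.png")))
      } else {
        rec <- res
      }
      rows[[i]] <- rec
      log_lines <- c(log_lines,
                     sprintf("%s\tqc=%s\telapsed=%.2fs", rec$sample_id,
                             rec$qc_status,
                             proc.time()[["elapsed"]] - t0))
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$sample_id), ]
    rownames(out) <- NULL
    if (!is.null(output_dir))
      writeLines(log_lines, file.path(output_dir, "batch_log.txt"))
  }
  if (!is.null(output_dir)) {
    fm <- out
    num <- vapply(fm, is.numeric, logical(1))
    fm[num] <- lapply(fm[num], signif, digits = 6)
    utils::write.csv(fm, file.path(output_dir, "results.csv"),
                     row.names = FALSE, na = "NA")
  }
  out
}
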