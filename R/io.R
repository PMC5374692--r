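#' Construct an image pair
#'
#' The raw input unit of the pipeline: one photograph of the empty booth and
#' one with the tassel mounted, as 8-bit grayscale matrices (row 1 = top of
#' the image).
#'
#' @param background,sample Numeric matrices of identical dimensions with
#'   intensities in \[0, 255\].
#' @param sample_id Identifier carried through to the result row.
#' @return An object of class `image_pair`.
#' @export
image_pair <- function(background, sample, sample_id = "sample") {
  stopifnot(is.matrix(background), is.matrix(sample))
  if (!identical(dim(background), dim(sample)))
    stop(sprintf("background (%dx%d) and sample (%dx%d) dimensions differ",
                 nrow(background), ncol(background),
                 nrow(sample), ncol(sample)))
  rng <- range(background, sample)
  if (rng[1] < 0 || rng[2] > 255)
    stop("intensities must lie in [0, 255]")
  structure(list(sample_id = as.character(sample_id),
                 background = background, sample = sample,
                 height = nrow(background), width = ncol(background)),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair> %s: %d x %d px\n", x$sample_id, x$height, x$width))
  invisible(x)
}

# Convert an EBImage image to an 8-bit grayscale matrix (rows = image rows).
# RGB is collapsed with the standard luminance weights 0.299/0.587/0.114.
as_gray8 <- function(img) {
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3L) {
    nch <- dim(d)[3]
    g <- if (nch >= 3L)
      0.299 * d[, , 1] + 0.587 * d[, , 2] + 0.114 * d[, , 3]
    else d[, , 1]
  } else {
    g <- d
  }
  # EBImage stores x (columns) in dim 1; transpose to row-major convention
  m <- t(g) * 255
  round(pmin(pmax(m, 0), 255))
}

#' Read an image pair from disk
#'
#' Reads PNG/TIFF/JPEG images, converts RGB to 8-bit grayscale by fixed
#' luminance weights, and checks that the two images have equal dimensions.
#'
#' @param background_path,sample_path Paths to the background and sample
#'   images.
#' @param sample_id Identifier; defaults to the shared filename prefix.
#' @return An `image_pair`.
#' @export
read_image_pair <- function(background_path, sample_path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("_sample$", "",
                     tools::file_path_sans_ext(basename(sample_path)))
  bg <- as_gray8(EBImage::readImage(background_path))
  sm <- as_gray8(EBImage::readImage(sample_path))
  image_pair(bg, sm, sample_id)
}

#' Discover image pairs in a directory or manifest
#'
#' Either scans a directory for the `<id>_background.<ext>` /
#' `<id>_sample.<ext>` naming convention, or reads a manifest CSV with
#' columns `background_path`, `sample_path` and optional `sample_id`.
#'
#' @param input Directory or manifest CSV path.
#' @return A data.frame with columns `sample_id`, `background_path`,
#'   `sample_path`, sorted by `sample_id`.
#' @export
discover_pairs <- function(input) {
  if (dir.exists(input)) {
    ff <- list.files(input, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                     ignore.case = TRUE, full.names = TRUE)
    base <- tools::file_path_sans_ext(basename(ff))
    is_bg <- grepl("_background$", base)
    is_sm <- grepl("_sample$", base)
    ids_bg <- sub("_background$", "", base[is_bg])
    ids_sm <- sub("_sample$", "", base[is_sm])
    ids <- sort(intersect(ids_bg, ids_sm))
    orphan <- setdiff(union(ids_bg, ids_sm), ids)
    if (length(orphan))
      warning("unpaired image id(s) skipped: ", paste(orphan, collapse = ", "))
    data.frame(sample_id = ids,
               background_path = ff[is_bg][match(ids, ids_bg)],
               sample_path = ff[is_sm][match(ids, ids_sm)],
               stringsAsFactors = FALSE)
  } else if (file.exists(input)) {
    man <- utils::read.csv(input, stringsAsFactors = FALSE)
    if (!all(c("background_path", "sample_path") %in% names(man)))
      stop("manifest must have columns background_path, sample_path")
    if (is.null(man$sample_id))
      man$sample_id <- sub("_sample$", "",
                           tools::file_path_sans_ext(basename(man$sample_path)))
    man <- man[order(man$sample_id),
               c("sample_id", "background_path", "sample_path")]
    rownames(man) <- NULL
    man
  } else {
    stop("input not found: ", input)
  }
}

# Write an 8-bit grayscale matrix (or logical mask) as PNG.
write_gray_png <- function(m, path) {
  if (is.logical(m)) m <- m * 255
  EBImage::writeImage(EBImage::Image(t(m) / 255), path, type = "png")
  invisible(path)
}
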