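# Truncated, renormalized isometric 2-D Gaussian kernel.
gaussian_kernel2d <- function(size, sigma) {
  h <- (size - 1) / 2
  g <- stats::dnorm(-h:h, sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

# Convolution with the truncated isometric Gaussian, exploiting its
# separability (outer product of the normalized 1-D kernel with itself);
# edge values are replicated.
gaussian_convolve2d <- function(x, size, sigma) {
  h <- (size - 1) / 2
  g <- stats::dnorm(-h:h, sd = sigma)
  .sep_convolve_cpp(x, g / sum(g))
}

#' Smooth a binary mask by Gaussian convolution and re-thresholding
#'
#' Convolves the mask with a truncated, renormalized isometric 2-D Gaussian
#' and re-thresholds, producing a smooth contour so the subsequent thinning
#' yields a skeleton without spurious spurs. With the default 31-px support
#' and sigma 55 px the kernel is nearly uniform, so the operation acts like
#' a majority filter over a 31 x 31 neighbourhood: protrusions narrower than
#' about half the support are erased. Should smoothing split the mask, only
#' the largest fragment is kept so the skeleton stays connected.
#'
#' @param mask Logical matrix (single foreground component).
#' @param params A [tassel_params()] set.
#' @return Logical matrix; empty if smoothing erased all foreground.
#' @export
smooth_mask <- function(mask, params = tassel_params()) {
  stopifnot(is.logical(mask))
  sm <- gaussian_convolve2d(mask * 1, params$smooth_kernel_size,
                            params$smooth_kernel_sigma)
  out <- sm > params$rethreshold_level
  if (!any(out)) return(out)
  keep_largest_component(out)
}

#' Thin a binary mask to a one-pixel-wide skeleton
#'
#' Topology-preserving thinning (Zhang-Suen passes followed by sequential
#' removal of remaining simple pixels) producing a fully thin, 8-connected
#' skeleton of the mask.
#'
#' @param mask Logical matrix with a single foreground component.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.logical(mask))
  if (!any(mask)) stop("cannot skeletonize an empty mask")
  .thin_mask_cpp(mask)
}

#' Build a graph over skeleton pixels
#'
#' Vertices are skeleton pixels; edges join 8-adjacent pixels with Euclidean
#' step weights (1 axial, sqrt(2) diagonal). Endpoints are pixels with at
#' most one skeleton neighbour; junction pixels have three or more.
#' Junction pixels frequently occur in small 8-connected clusters, which are
#' labelled for reporting.
#'
#' @param skel Logical skeleton matrix.
#' @return An object of class `skeleton_graph` with elements `coords`
#'   (n x 2, row/col), `graph` (weighted igraph), `endpoints`, `junctions`
#'   (vertex indices), `junction_cluster` (cluster label per vertex, 0 for
#'   non-junction), and `dims`.
#' @export
skeleton_graph <- function(skel) {
  stopifnot(is.logical(skel), any(skel))
  coords <- which(skel, arr.ind = TRUE)
  dimnames(coords) <- NULL
  n <- nrow(coords)
  idx <- matrix(0L, nrow(skel), ncol(skel))
  idx[coords] <- seq_len(n)
  H <- nrow(skel); W <- ncol(skel)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    r2 <- coords[, 1] + d[1]; c2 <- coords[, 2] + d[2]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    ok[ok] <- skel[cbind(r2[ok], c2[ok])]
    if (any(ok)) {
      from <- c(from, idx[coords[ok, , drop = FALSE]])
      to <- c(to, idx[cbind(r2[ok], c2[ok])])
      w <- c(w, rep(if (all(d != 0L)) sqrt(2) else 1, sum(ok)))
    }
  }
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  igraph::E(g)$weight <- w
  if (igraph::count_components(g) != 1L)
    stop("skeleton is not a single connected component")
  deg <- igraph::degree(g)
  endpoints <- which(deg <= 1L)
  junctions <- which(deg >= 3L)
  jl <- integer(n)
  if (length(junctions)) {
    jm <- matrix(FALSE, H, W)
    jm[coords[junctions, , drop = FALSE]] <- TRUE
    lab <- .label_components8_cpp(jm)
    jl[junctions] <- lab[coords[junctions, , drop = FALSE]]
  }
  structure(list(coords = coords, graph = g, endpoints = endpoints,
                 junctions = junctions, junction_cluster = jl,
                 dims = c(H, W), skeleton = skel),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d px, %d endpoints, %d junction px (%d clusters)\n",
              nrow(x$coords), length(x$endpoints), length(x$junctions),
              length(unique(x$junction_cluster[x$junction_cluster > 0]))))
  invisible(x)
}

#' Identify the tassel base
#'
#' The skeleton endpoint closest (Euclidean) to the bottom-centre anchor of
#' the image, where the tassel holder enters the frame. Ties break to the
#' smaller column, then the smaller row.
#'
#' @param sg A [skeleton_graph()].
#' @return Vertex index of the base endpoint.
#' @export
find_base <- function(sg) {
  stopifnot(length(sg$endpoints) >= 1L)
  anchor <- c(sg$dims[1], floor(sg$dims[2] / 2) + 1)
  pc <- sg$coords[sg$endpoints, , drop = FALSE]
  d2 <- (pc[, 1] - anchor[1])^2 + (pc[, 2] - anchor[2])^2
  ord <- order(d2, pc[, 2], pc[, 1])
  sg$endpoints[ord[1]]
}

#' Geodesic distances from the base
#'
#' Shortest-path distance (Dijkstra, Euclidean step weights) from the base
#' to every skeleton pixel.
#'
#' @param sg A [skeleton_graph()].
#' @param base Vertex index of the base.
#' @return Numeric vector of length `nrow(sg$coords)`.
#' @export
geodesic_distances <- function(sg, base) {
  d <- igraph::distances(sg$graph, v = base, algorithm = "dijkstra")[1, ]
  if (any(!is.finite(d))) stop("skeleton graph is disconnected")
  d
}

#' Exclude short spurs from spike-tip candidacy
#'
#' Small protrusions from the tassel (spikelets, rough contours) produce
#' short skeleton branches; endpoints closer than `min_endpoint_dist` along
#' the skeleton to the nearest junction pixel are excluded from the
#' candidate-tip set. The skeleton itself is not modified. With no
#' junctions the rule is vacuous and all endpoints are retained.
#'
#' @param sg A [skeleton_graph()].
#' @param min_endpoint_dist Path-distance threshold in pixels.
#' @return Vertex indices of retained endpoints.
#' @export
prune_spurs <- function(sg, min_endpoint_dist = 75) {
  if (!length(sg$junctions)) return(sg$endpoints)
  dj <- igraph::distances(sg$graph, v = sg$endpoints, to = sg$junctions,
                          algorithm = "dijkstra")
  keep <- apply(dj, 1, min) >= min_endpoint_dist
  sg$endpoints[keep]
}

#' Extract the main path from base to spike tip
#'
#' The retained endpoint farthest (geodesically) from the base is taken as
#' the spike tip; the main path is the shortest path from base to tip with
#' its cumulative arc length. Distance ties break to the smaller row, then
#' the smaller column.
#'
#' @param sg A [skeleton_graph()].
#' @param base Base vertex index.
#' @param distances Output of [geodesic_distances()].
#' @param candidates Retained endpoints from [prune_spurs()]; the base is
#'   removed automatically.
#' @return An object of class `main_path`: `pixels` (m x 2 row/col), `s`
#'   (cumulative arc length, starting at 0), `base_px`, `tip_px`.
#' @export
extract_main_path <- function(sg, base, distances,
                              candidates = prune_spurs(sg)) {
  cand <- setdiff(candidates, base)
  if (!length(cand)) stop("no candidate spike tip")
  dv <- distances[cand]
  pc <- sg$coords[cand, , drop = FALSE]
  ord <- order(-dv, pc[, 1], pc[, 2])
  tip <- cand[ord[1]]
  vp <- igraph::shortest_paths(sg$graph, from = base, to = tip,
                               algorithm = "dijkstra",
                               output = "vpath")$vpath[[1]]
  px <- sg$coords[as.integer(vp), , drop = FALSE]
  step <- sqrt(rowSums((px[-1, , drop = FALSE] -
                        px[-nrow(px), , drop = FALSE])^2))
  structure(list(pixels = px, s = c(0, cumsum(step)),
                 base_px = px[1, ], tip_px = px[nrow(px), ]),
            class = "main_path")
}

#' @export
print.main_path <- function(x, ...) {
  cat(sprintf("<main_path> %d px, arc length %.1f px, base (%d,%d) -> tip (%d,%d)\n",
              nrow(x$pixels), max(x$s), x$base_px[1], x$base_px[2],
              x$tip_px[1], x$tip_px[2]))
  invisible(x)
}
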