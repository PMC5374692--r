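# Independent oracles used across tests. Each is a deliberately naive
# implementation kept separate from the package's code paths.

# Exhaustive between-class-variance search over all 256 candidate
# thresholds; ties kept at the lowest threshold.
otsu_oracle <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  best <- -Inf
  best_t <- NA_real_
  for (t in 0:254) {
    n0 <- sum(counts[1:(t + 1)])
    n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum((0:t) * counts[1:(t + 1)]) / n0
    mu1 <- sum(((t + 1):255) * counts[(t + 2):256]) / n1
    v <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (v > best + 1e-12) {
      best <- v
      best_t <- t
    }
  }
  best_t
}

# Breadth-first flood-fill labelling (8-connectivity).
flood_label <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  H <- nrow(mask); W <- ncol(mask)
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r < 1 || c < 1 || r > H || c > W) next
        if (mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Brute-force single-source shortest paths on a skeleton pixel set by
# repeated relaxation (Bellman-Ford style) over all 8-adjacent pairs.
ucs_distances <- function(skel, base_rc) {
  coords <- which(skel, arr.ind = TRUE)
  n <- nrow(coords)
  key <- paste(coords[, 1], coords[, 2])
  d <- rep(Inf, n)
  d[match(paste(base_rc[1], base_rc[2]), key)] <- 0
  adj <- list()
  for (i in seq_len(n)) {
    dr <- coords[, 1] - coords[i, 1]
    dc <- coords[, 2] - coords[i, 2]
    j <- which(abs(dr) <= 1 & abs(dc) <= 1)
    j <- j[j != i]
    adj[[i]] <- cbind(j, sqrt(dr[j]^2 + dc[j]^2))
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      if (!is.finite(d[i]) || !nrow(adj[[i]])) next
      for (row in seq_len(nrow(adj[[i]]))) {
        j <- adj[[i]][row, 1]
        w <- adj[[i]][row, 2]
        if (d[i] + w < d[j] - 1e-12) {
          d[j] <- d[i] + w
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  names(d) <- key
  d
}

# Random connected pixel set on a small grid: a branching random walk.
random_skeleton <- function(seed, size = 30, steps = 50) {
  set.seed(seed)
  m <- matrix(FALSE, size, size)
  pos <- c(size %/% 2, size %/% 2)
  m[pos[1], pos[2]] <- TRUE
  visited <- list(pos)
  for (i in seq_len(steps)) {
    if (runif(1) < 0.15) pos <- visited[[sample(length(visited), 1)]]
    step <- c(sample(-1:1, 1), sample(-1:1, 1))
    cand <- pmin(pmax(pos + step, 1), size)
    pos <- cand
    if (!m[pos[1], pos[2]]) {
      m[pos[1], pos[2]] <- TRUE
      visited[[length(visited) + 1]] <- pos
    }
  }
  m
}

# Angular-scan intersection count: samples the true circle at `step_deg`
# resolution and counts runs of foreground samples with wrap-around merge.
angular_count_oracle <- function(mask, center, radius, step_deg = 0.1) {
  th <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  r <- round(center[1] + radius * sin(th))
  c <- round(center[2] + radius * cos(th))
  ok <- r >= 1 & r <= nrow(mask) & c >= 1 & c <= ncol(mask)
  fg <- logical(length(th))
  fg[ok] <- mask[cbind(r[ok], c[ok])]
  if (!any(fg)) return(0L)
  runs <- rle(fg)
  k <- sum(runs$values)
  if (length(runs$values) > 1L && runs$values[1] &&
      runs$values[length(runs$values)]) k <- k - 1L
  as.integer(k)
}

# Jarvis-march convex hull returning hull vertices in order (x, y).
gift_wrap_hull <- function(xy) {
  xy <- unique(xy)
  n <- nrow(xy)
  start <- which.min(xy[, 1] + xy[, 2] * 1e-9)
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    q <- cand[1]
    for (r in cand[-1]) {
      cr <- (xy[q, 1] - xy[p, 1]) * (xy[r, 2] - xy[p, 2]) -
        (xy[q, 2] - xy[p, 2]) * (xy[r, 1] - xy[p, 1])
      d_q <- sum((xy[q, ] - xy[p, ])^2)
      d_r <- sum((xy[r, ] - xy[p, ])^2)
      if (cr < 0 || (cr == 0 && d_r > d_q)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) stop("hull did not close")
  }
  xy[hull, , drop = FALSE]
}

shoelace <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Binary Sierpinski gasket of side 2^depth (Pascal's triangle mod 2).
sierpinski_mask <- function(depth) {
  n <- 2^depth
  outer(0:(n - 1), 0:(n - 1), function(i, j) bitwAnd(i, j) == 0L)
}

disk_mask <- function(size, radius, center = c(size / 2, size / 2)) {
  outer(seq_len(size), seq_len(size), function(r, c)
    (r - center[1])^2 + (c - center[2])^2 <= radius^2)
}

# Vertical band (stem/spike style) helper.
band_mask <- function(H, W, rows, col_center, width) {
  m <- matrix(FALSE, H, W)
  half <- floor(width / 2)
  m[rows, (col_center - half):(col_center + half)] <- TRUE
  m
}

# Straight limb of given width from a centre point at `angle_deg` from
# vertical (positive = rightward), stamped onto an existing mask.
add_arm <- function(mask, from, angle_deg, len, width = 9) {
  a <- angle_deg * pi / 180
  t <- seq(0, len, by = 0.5)
  pts <- cbind(from[1] - t * cos(a), from[2] + t * sin(a))
  half <- width / 2
  H <- nrow(mask); W <- ncol(mask)
  for (i in seq_len(nrow(pts))) {
    rr <- max(1, floor(pts[i, 1] - half)):min(H, ceiling(pts[i, 1] + half))
    cc <- max(1, floor(pts[i, 2] - half)):min(W, ceiling(pts[i, 2] + half))
    sub <- outer(rr, cc, function(r, c)
      (r - pts[i, 1])^2 + (c - pts[i, 2])^2 <= half^2)
    mask[rr, cc] <- mask[rr, cc] | sub
  }
  mask
}
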