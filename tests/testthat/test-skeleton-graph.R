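test_that("mask smoothing preserves smooth shapes and removes hairs", {
  p <- tassel_params()

  d <- disk_mask(500, 200)
  sm <- smooth_mask(d, p)
  expect_lt(sum(sm != d) / length(d), 0.02)

  # thick bar with a 1-px hair: skeleton endpoint count drops from 3 to 2
  bar <- matrix(FALSE, 120, 300)
  bar[50:80, 30:270] <- TRUE
  hair <- bar
  hair[39:49, 150] <- TRUE
  n_endpoints <- function(m) length(skeleton_graph(skeletonize(m))$endpoints)
  expect_equal(n_endpoints(hair), 3)
  expect_equal(n_endpoints(smooth_mask(hair, p)), 2)

  all_true <- matrix(TRUE, 80, 90)
  expect_identical(smooth_mask(all_true, p), all_true)
})

test_that("skeletonization yields thin, topologically faithful skeletons", {
  bar <- matrix(FALSE, 40, 140)
  bar[18:22, 21:120] <- TRUE
  sk <- skeletonize(bar)
  sg <- skeleton_graph(sk)
  expect_equal(length(sg$endpoints), 2)
  expect_equal(length(sg$junctions), 0)
  # thinning erodes each rounded bar end by about half the bar width
  expect_gte(sum(sk), 100 - 5)
  expect_lte(sum(sk), 100)

  # Y-shape with three 4-px arms: 3 endpoints, one junction cluster
  y <- matrix(FALSE, 200, 200)
  y <- add_arm(y, c(100, 100), 180, 60, width = 4)  # down
  y <- add_arm(y, c(100, 100), -35, 60, width = 4)  # up-left
  y <- add_arm(y, c(100, 100), 35, 60, width = 4)   # up-right
  sgy <- skeleton_graph(skeletonize(y))
  expect_equal(length(sgy$endpoints), 3)
  expect_gte(length(sgy$junctions), 1)
  expect_equal(length(unique(sgy$junction_cluster[sgy$junction_cluster > 0])), 1)

  single <- matrix(FALSE, 5, 5)
  single[3, 3] <- TRUE
  expect_identical(skeletonize(single), single)
  expect_error(skeletonize(matrix(FALSE, 5, 5)), "empty")
})

test_that("skeleton is a subset of the smoothed mask foreground", {
  st <- generate_tassel(synthetic_spec(seed = 7))
  tm <- preprocess_pair(st$pair)
  sm <- smooth_mask(tm$mask)
  sk <- skeletonize(sm)
  expect_true(all(sm[sk]))
})

test_that("base detection picks the endpoint nearest the bottom-centre", {
  fake_sg <- function(coords, dims) {
    ep <- seq_len(nrow(coords))
    structure(list(coords = coords, endpoints = ep, dims = dims),
              class = "skeleton_graph")
  }
  expect_equal(find_base(fake_sg(cbind(400, 200), c(1000, 1000))), 1)

  sg2 <- fake_sg(rbind(c(900, 500), c(100, 500)), c(1000, 1000))
  expect_equal(unname(sg2$coords[find_base(sg2), ]), c(900, 500))

  set.seed(5)
  for (i in 1:10) {
    coords <- cbind(sample(1000, 10), sample(1000, 10))
    sg <- fake_sg(coords, c(1000, 1000))
    anchor <- c(1000, 501)
    d2 <- (coords[, 1] - anchor[1])^2 + (coords[, 2] - anchor[2])^2
    best <- order(d2, coords[, 2], coords[, 1])[1]
    expect_equal(find_base(sg), best)
  }
})

test_that("geodesic distances agree with hand sums and the brute-force oracle", {
  # straight path of n axial steps
  line <- matrix(FALSE, 10, 60)
  line[5, 10:50] <- TRUE
  sg <- skeleton_graph(line)
  base <- find_base(sg)
  d <- geodesic_distances(sg, base)
  expect_equal(max(d[sg$endpoints]), 40)

  # pixel-exact Y: arms of 50/60/70 axial steps from one junction
  y <- matrix(FALSE, 200, 200)
  y[100:150, 100] <- TRUE   # down arm, 50 steps
  y[40:100, 100] <- TRUE    # up arm, 60 steps
  y[100, 100:170] <- TRUE   # right arm, 70 steps
  sgy <- skeleton_graph(y)
  base <- sgy$endpoints[which(sgy$coords[sgy$endpoints, 1] == 150)]
  dy <- geodesic_distances(sgy, base)
  others <- setdiff(sgy$endpoints, base)
  # straight continuation: 50 + 60; the right arm cuts the junction corner
  # diagonally: 49 + sqrt(2) + 69
  expect_equal(sort(dy[others]), c(110, 49 + sqrt(2) + 69), tolerance = 1e-12)

  # random skeletons vs uniform-cost-search oracle (exact)
  for (seed in 1:20) {
    m <- random_skeleton(seed)
    sgr <- skeleton_graph(m)
    b <- 1L  # any source vertex exercises the same shortest-path machinery
    d_pkg <- geodesic_distances(sgr, b)
    d_orc <- ucs_distances(m, sgr$coords[b, ])
    key <- paste(sgr$coords[, 1], sgr$coords[, 2])
    expect_equal(unname(d_pkg), unname(d_orc[key]), tolerance = 1e-9)
  }
})

test_that("spur pruning excludes endpoints by path distance to a junction", {
  base_skel <- function(spur_len) {
    m <- matrix(FALSE, 120, 400)
    m[100, 50:350] <- TRUE
    m[(100 - spur_len):99, 150] <- TRUE
    m
  }
  for (spur_len in c(74, 76)) {
    sg <- skeleton_graph(base_skel(spur_len))
    kept <- prune_spurs(sg, 75)
    spur_tip <- sg$endpoints[which(sg$coords[sg$endpoints, 1] == 100 - spur_len)]
    if (spur_len < 75) expect_false(spur_tip %in% kept)
    else expect_true(spur_tip %in% kept)
  }
  # no junctions: the rule is vacuous
  line <- matrix(FALSE, 10, 60)
  line[5, 10:50] <- TRUE
  sg <- skeleton_graph(line)
  expect_setequal(prune_spurs(sg, 75), sg$endpoints)
})

test_that("main path extraction picks the farthest tip with stable ties", {
  vert <- matrix(FALSE, 100, 20)
  vert[10:90, 10] <- TRUE
  sg <- skeleton_graph(vert)
  base <- find_base(sg)
  d <- geodesic_distances(sg, base)
  mp <- extract_main_path(sg, base, d)
  expect_equal(nrow(mp$pixels), 81)
  expect_equal(diff(mp$s), rep(1, 80))
  expect_equal(unname(mp$tip_px), c(10, 10))

  # Y above base: arms 60 vs 70 -> tip is the end of the 70 arm
  y <- matrix(FALSE, 220, 220)
  y[100:180, 110] <- TRUE
  y[40:100, 110] <- TRUE                     # 60 up
  y[100, 110:180] <- TRUE                    # 70 right
  sgy <- skeleton_graph(y)
  base <- sgy$endpoints[which(sgy$coords[sgy$endpoints, 1] == 180)]
  dy <- geodesic_distances(sgy, base)
  mpy <- extract_main_path(sgy, base, dy, sgy$endpoints)
  expect_equal(unname(mpy$tip_px), c(100, 180))

  # equal-distance tips: deterministic tie-break, stable across calls
  t2 <- matrix(FALSE, 220, 220)
  t2[100:180, 110] <- TRUE
  t2[40:100, 110] <- TRUE
  t2[100, 110:170] <- TRUE                   # also 60
  sgt <- skeleton_graph(t2)
  base <- sgt$endpoints[which(sgt$coords[sgt$endpoints, 1] == 180)]
  dt <- geodesic_distances(sgt, base)
  tip1 <- extract_main_path(sgt, base, dt, sgt$endpoints)$tip_px
  tip2 <- extract_main_path(sgt, base, dt, sgt$endpoints)$tip_px
  expect_identical(tip1, tip2)
  expect_equal(unname(tip1), c(40, 110))  # smaller row wins the tie

  expect_error(extract_main_path(sg, base, d, candidates = base),
               "no candidate spike tip")
})

test_that("adding a longer arm never decreases the maximal geodesic distance", {
  for (extra in c(20, 40, 80)) {
    m <- matrix(FALSE, 300, 300)
    m[150:250, 150] <- TRUE
    m[50:150, 150] <- TRUE
    sg <- skeleton_graph(m)
    b <- sg$endpoints[which(sg$coords[sg$endpoints, 1] == 250)]
    d0 <- max(geodesic_distances(sg, b)[sg$endpoints])
    m2 <- m
    m2[150, 150:(150 + 60 + extra)] <- TRUE
    sg2 <- skeleton_graph(m2)
    b2 <- sg2$endpoints[which(sg2$coords[sg2$endpoints, 1] == 250)]
    d1 <- max(geodesic_distances(sg2, b2)[sg2$endpoints])
    expect_gte(d1, d0)
  }
})
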