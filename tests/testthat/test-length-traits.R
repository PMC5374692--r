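make_path <- function(rows, cols) cbind(rows, cols)

test_that("windowed row sums match the brute-force summation oracle", {
  # vertical bar of width 20 with the path down its centre
  m <- band_mask(400, 200, 50:350, 100, 20)
  path <- make_path(350:50, rep(100, 301))
  prof <- windowed_row_sums(m, path, 301)
  expect_equal(prof, rep(21, 301))  # width-20 band renders 21 columns

  # step construction: wide zone then narrow spike along the path
  m2 <- band_mask(700, 400, 1:700, 200, 20)
  m2[351:700, 120:280] <- TRUE      # wide zone below path position 350
  path2 <- make_path(700:1, rep(200, 700))
  prof2 <- windowed_row_sums(m2, path2, 301)
  expect_equal(unique(prof2[1:350]), 161)
  expect_equal(unique(prof2[351:700]), 21)

  # random mask + random path vs brute-force oracle
  set.seed(9)
  mr <- matrix(runif(60 * 80) < 0.3, 60, 80)
  pr <- make_path(sample(60, 40, replace = TRUE), sample(80, 40, replace = TRUE))
  prof_r <- windowed_row_sums(mr, pr, 31)
  oracle <- vapply(seq_len(40), function(i) {
    r <- pr[i, 1]; c <- pr[i, 2]
    sum(mr[r, max(1, c - 15):min(80, c + 15)])
  }, numeric(1))
  expect_identical(prof_r, oracle)
})

test_that("lowest-branch detection matches a direct filtering oracle", {
  p <- tassel_params()
  prof <- c(rep(15, 200), rep(90, 200))
  idx <- locate_lowest_branch(prof, p)

  # independent direct computation: smooth, differentiate, first crossing
  h <- 20
  k <- dnorm(-h:h, sd = 5); k <- k / sum(k)
  n <- length(prof)
  smth <- vapply(seq_len(n), function(i) {
    j <- max(1, i - h):min(n, i + h)
    w <- k[j - i + h + 1]
    sum(prof[j] * w) / sum(w)
  }, numeric(1))
  d <- c(smth[2] - smth[1], (smth[3:n] - smth[1:(n - 2)]) / 2,
         smth[n] - smth[n - 1])
  expect_equal(idx, which(d > 0.2)[1])
  expect_true(idx >= 188 && idx <= 200)

  expect_error(locate_lowest_branch(rep(40, 300), p), "no branch detected")
  ramp <- seq(10, by = 0.1, length.out = 300)
  expect_error(locate_lowest_branch(ramp, p), "no branch detected")
})

test_that("main-path splines reproduce lines and circles", {
  p <- tassel_params()

  # collinear points: spline reproduces the line
  s <- 0:200
  line <- cbind(500 - s, rep(100, 201))
  spl <- fit_main_spline(line, p)
  fitted <- predict_spline(spl, s)
  expect_lt(max(abs(fitted[, 1] - line[, 1])), 0.5)
  expect_lt(max(abs(fitted[, 2] - line[, 2])), 0.5)

  # noiseless quarter circle of radius 100: within 1 px everywhere
  th <- seq(0, pi / 2, length.out = 158)
  qc <- cbind(200 - 100 * sin(th), 200 + 100 * cos(th))
  splq <- fit_main_spline(qc, p)
  dense <- predict_spline(splq, seq(splq$s_range[1], splq$s_range[2],
                                    length.out = 2000))
  radial <- sqrt((dense[, 1] - 200)^2 + (dense[, 2] - 200)^2)
  expect_lt(max(abs(radial - 100)), 1)

  # stair-step jitter: spline residual to the true line beats the raw path
  set.seed(3)
  true_col <- 100 + 0.2 * s
  jit <- cbind(500 - s, round(true_col) + sample(c(-1, 0, 1), 201, TRUE))
  splj <- fit_main_spline(jit, p)
  fit_j <- predict_spline(splj, seq(splj$s_range[1], splj$s_range[2],
                                    length.out = 201))
  res_spline <- mean(abs(fit_j[, 2] - (100 + 0.2 * (500 - fit_j[, 1]))))
  res_raw <- mean(abs(jit[, 2] - true_col))
  expect_lt(res_spline, res_raw)

  # fewer than 4 points: straight-segment fallback
  seg <- fit_main_spline(rbind(c(10, 10), c(5, 10)), p)
  expect_equal(tassel_length(seg), 5, tolerance = 1e-6)
})

test_that("tassel length agrees with analytic arc lengths", {
  p <- tassel_params()
  vert <- cbind(400 - (0:300), rep(50, 301))
  expect_equal(tassel_length(fit_main_spline(vert, p)), 300, tolerance = 1 / 300)

  th <- seq(0, pi, length.out = 316)
  semi <- cbind(300 - 100 * sin(th), 300 + 100 * cos(th))
  expect_equal(tassel_length(fit_main_spline(semi, p)), pi * 100, tolerance = 2 / 314)

  diag <- cbind(200 - (0:100), 50 + (0:100))
  expect_equal(tassel_length(fit_main_spline(diag, p)), sqrt(2) * 100,
               tolerance = 1 / 141)
})

test_that("tortuosity is the chord/arc ratio, bounded by 1", {
  expect_equal(tortuosity(c(400, 50), c(100, 50), 300), 1)
  # semicircle: chord 2r over arc pi r
  p <- tassel_params()
  th <- seq(0, pi, length.out = 316)
  semi <- cbind(300 - 100 * sin(th), 300 + 100 * cos(th))
  spl <- fit_main_spline(semi, p)
  len <- tassel_length(spl)
  ends <- predict_spline(spl, spl$s_range)
  tt <- tortuosity(ends[1, ], ends[2, ], len)
  expect_equal(tt, 2 / pi, tolerance = 0.01 / 0.63)

  # arbitrary wiggly paths: chord between spline endpoints never exceeds arc
  set.seed(21)
  for (i in 1:5) {
    s <- 0:250
    path <- cbind(500 - s + rnorm(251, sd = 0.5),
                  100 + 20 * sin(s / 40) + rnorm(251, sd = 0.5))
    spl_i <- fit_main_spline(path, p)
    len_i <- tassel_length(spl_i)
    e <- predict_spline(spl_i, spl_i$s_range)
    expect_lte(tortuosity(e[1, ], e[2, ], len_i), 1)
  }
  expect_error(tortuosity(c(0, 0), c(1, 1), 0), "positive")
})

test_that("pixel-to-mm conversion uses the holder-derived scale", {
  expect_equal(px_to_mm(1000, 0.2), 200)
  expect_equal(px_to_mm(0, 0.2), 0)
  # holder base: 200 px spanning a known 40 mm
  scale <- 40 / 200
  expect_equal(scale, 0.2)
  expect_equal(px_to_mm(2000, scale), 400)
  expect_equal(px_to_mm(100, 0.5, power = 2), 25)
  expect_true(is.na(px_to_mm(100, NA_real_)))
  expect_error(px_to_mm(10, -1), "positive")
})
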