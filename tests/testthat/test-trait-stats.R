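sim_design <- function(n_geno, n_rep, s2g, s2e, seed, rep_effects = NULL) {
  set.seed(seed)
  if (is.null(rep_effects)) rep_effects <- seq(0, by = 1.5, length.out = n_rep)
  g_eff <- rnorm(n_geno, sd = sqrt(s2g))
  d <- expand.grid(genotype = sprintf("g%04d", seq_len(n_geno)),
                   rep = seq_len(n_rep), stringsAsFactors = FALSE)
  d$y <- 50 + g_eff[match(d$genotype, sprintf("g%04d", seq_len(n_geno)))] +
    rep_effects[d$rep] + rnorm(nrow(d), sd = sqrt(s2e))
  d
}

test_that("variance components recover simulation truth", {
  # no genotype signal: genotype variance collapses towards zero
  d0 <- sim_design(200, 2, s2g = 0, s2e = 2, seed = 1)
  vc0 <- fit_variance_components(d0, "y")
  expect_lt(vc0$sigma2_G, 0.15 * vc0$sigma2_e)

  # balanced 500 x 2 with known components
  d <- sim_design(500, 2, s2g = 3, s2e = 2, seed = 2)
  vc <- fit_variance_components(d, "y")
  expect_equal(vc$sigma2_G, 3, tolerance = 0.10)
  expect_equal(vc$sigma2_e, 2, tolerance = 0.10)
  expect_equal(vc$b, 2)
})

test_that("REML matches the ANOVA method-of-moments oracle on balanced data", {
  d <- sim_design(300, 2, s2g = 3, s2e = 2, seed = 5)
  vc <- fit_variance_components(d, "y")
  an <- anova(lm(y ~ factor(rep) + factor(genotype), data = d))
  ms_g <- an["factor(genotype)", "Mean Sq"]
  ms_e <- an["Residuals", "Mean Sq"]
  s2g_mom <- (ms_g - ms_e) / 2
  expect_equal(vc$sigma2_G, s2g_mom, tolerance = 0.01)
  expect_equal(vc$sigma2_e, ms_e, tolerance = 0.01)
})

test_that("repeatability follows the variance-ratio formula", {
  expect_equal(repeatability(3, 2, b = 2), 0.75)
  expect_equal(repeatability(0, 2, b = 2), 0)
  expect_equal(repeatability(3, 0, b = 2), 1)
  expect_error(repeatability(0, 0, b = 2), "zero")

  # monotone in genotype variance and in replication count
  r <- vapply(c(1, 2, 4, 8), function(s) repeatability(s, 2, b = 2), numeric(1))
  expect_true(all(diff(r) > 0))
  rb <- vapply(2:6, function(b) repeatability(3, 2, b = b), numeric(1))
  expect_true(all(diff(rb) > 0))
  expect_true(all(c(r, rb) >= 0 & c(r, rb) <= 1))
})

test_that("genotype means average available replications", {
  d <- data.frame(genotype = c("a", "a", "b", "b", "c"),
                  rep = c(1, 2, 1, 2, 1),
                  y = c(10, 20, 5, NA, 7))
  gm <- genotype_means(d, "y")
  expect_equal(gm$mean[gm$genotype == "a"], 15)
  expect_equal(gm$mean[gm$genotype == "b"], 5)   # missing rep dropped
  expect_equal(gm$mean[gm$genotype == "c"], 7)

  d_big <- sim_design(50, 3, 1, 1, seed = 8)
  gm_big <- genotype_means(d_big, "y")
  oracle <- tapply(d_big$y, d_big$genotype, mean)
  expect_equal(gm_big$mean, as.numeric(oracle[gm_big$genotype]))

  d$y[d$genotype == "c"] <- NA
  expect_warning(gm2 <- genotype_means(d, "y"), "dropped: c")
  expect_false("c" %in% gm2$genotype)
})

test_that("Pearson correlation behaves as defined", {
  x <- c(1, 4, 2, 8, 5, 7)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)

  set.seed(13)
  a <- rnorm(10000); b <- rnorm(10000)
  expect_lt(abs(pearson_r(a, b)), 0.05)

  # affine invariance
  expect_equal(pearson_r(x, c(3, 1, 4, 1, 5, 9)),
               pearson_r(10 + 2 * x, 5 - 0 * x + c(3, 1, 4, 1, 5, 9)))
  expect_error(pearson_r(x[1:2], x[1:2]), "3 complete pairs")
  expect_error(pearson_r(rep(1, 5), x[1:5]), "zero variance")
})

test_that("CV(RMSE) measures residual scatter of the calibration fit", {
  img <- c(100, 150, 200, 250, 300, 350)
  expect_lt(cv_rmse(img, img), 1e-10)
  expect_lt(cv_rmse(2 * img + 5, img), 1e-10)  # affine relation absorbed

  set.seed(17)
  image_v <- runif(2000, 100, 400)
  hand_v <- image_v + rnorm(2000, sd = 12)
  expect_equal(cv_rmse(hand_v, image_v), 12 / mean(hand_v), tolerance = 0.05)

  # invariance to affine recalibration of the image values
  expect_equal(cv_rmse(hand_v, image_v), cv_rmse(hand_v, 3 * image_v - 40),
               tolerance = 1e-10)
  expect_error(cv_rmse(c(-1, 0, 1), c(1, 2, 3)), "zero")
})

test_that("trait summary combines repeatability and hand comparisons", {
  d <- sim_design(80, 2, 3, 2, seed = 23)
  hand <- d
  hand$y <- d$y * 1.1 + rnorm(nrow(d), sd = 0.5)
  out <- trait_summary(d, "y", hand = hand)
  expect_equal(nrow(out), 1)
  expect_true(out$repeatability > 0.4 && out$repeatability < 1)
  expect_gt(out$r_vs_hand, 0.9)
  expect_lt(out$cv_rmse, 0.05)

  cm <- trait_correlations(cbind(d, y2 = d$y * 2 + 1), c("y", "y2"))
  expect_equal(cm["y", "y2"], 1)
})
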