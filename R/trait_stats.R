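#' Variance components for a replicated field design
#'
#' Fits the linear model y = u + G + B + e for one trait, with the genotype
#' effect G random and the field-replication effect B fixed, by restricted
#' maximum likelihood. Returns the genotype variance, the residual
#' variance, and the number of field replications used downstream in the
#' repeatability formula. Negative variance estimates cannot occur under
#' REML's boundary constraint (they are truncated at zero by the fitter).
#'
#' @param data Data frame with genotype, replication and trait columns.
#' @param trait Name of the trait column.
#' @param genotype,rep Names of the genotype and replication columns.
#' @param b Number of field replications; defaults to the number of
#'   distinct replication levels in the data.
#' @return An object of class `variance_components` with elements
#'   `sigma2_G`, `sigma2_e`, `b`, `mu`, `rep_effects`, `trait`, `n`.
#' @export
fit_variance_components <- function(data, trait, genotype = "genotype",
                                    rep = "rep", b = NULL) {
  stopifnot(all(c(trait, genotype, rep) %in% names(data)))
  d <- data.frame(y = data[[trait]],
                  G = factor(data[[genotype]]),
                  B = factor(data[[rep]]))
  d <- d[is.finite(d$y), ]
  if (!nrow(d)) stop("no non-missing values for trait '", trait, "'")
  if (nlevels(droplevels(d$G)) < 2) stop("need >= 2 genotypes")
  if (nlevels(droplevels(d$B)) < 2) stop("need >= 2 replications")
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ B + (1 | G), data = d, REML = TRUE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2g <- vc$vcov[vc$grp == "G"]
  s2e <- stats::sigma(fit)^2
  if (is.null(b)) b <- nlevels(droplevels(d$B))
  structure(list(sigma2_G = s2g, sigma2_e = s2e, b = b,
                 mu = mean(d$y), rep_effects = lme4::fixef(fit),
                 trait = trait, n = nrow(d)),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> %s: sigma2_G = %.4g, sigma2_e = %.4g, b = %d\n",
              x$trait, x$sigma2_G, x$sigma2_e, x$b))
  invisible(x)
}

#' Repeatability from variance components
#'
#' sigma_G^2 / (sigma_G^2 + sigma_e^2 / b): the proportion of variance
#' among genotype means attributable to genotype, given b field
#' replications.
#'
#' @param vc A `variance_components` object, or a genotype variance.
#' @param sigma2_e,b Residual variance and replication count when `vc` is
#'   given as a plain number.
#' @return Value in \[0, 1\].
#' @export
repeatability <- function(vc, sigma2_e = NULL, b = NULL) {
  if (inherits(vc, "variance_components")) {
    s2g <- vc$sigma2_G; s2e <- vc$sigma2_e; b <- vc$b
  } else {
    s2g <- vc; s2e <- sigma2_e
  }
  if (s2g + s2e == 0) stop("both variance components are zero")
  s2g / (s2g + s2e / b)
}

#' Genotype means across replications
#'
#' @param data Data frame with genotype and trait columns.
#' @param trait Trait column name.
#' @param genotype Genotype column name.
#' @return Data frame with columns `genotype` and `mean`; genotypes with no
#'   non-missing data are dropped with a warning.
#' @export
genotype_means <- function(data, trait, genotype = "genotype") {
  stopifnot(all(c(trait, genotype) %in% names(data)))
  y <- data[[trait]]
  g <- factor(data[[genotype]])
  ok <- is.finite(y)
  empty <- setdiff(levels(g), unique(as.character(g[ok])))
  if (length(empty))
    warning("genotype(s) with no data dropped: ", paste(empty, collapse = ", "))
  agg <- stats::aggregate(y[ok], list(genotype = as.character(g[ok])), mean)
  names(agg)[2] <- "mean"
  agg[order(agg$genotype), ]
}

#' Pearson correlation
#'
#' cov(x, y) / (sd(x) sd(y)) on complete pairs.
#'
#' @param x,y Numeric vectors of equal length, at least 3 complete pairs.
#' @return Correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Coefficient of variation of the root mean squared error
#'
#' Hand-measured values are regressed on image-based values; the RMSE of
#' the residuals (n - 2 degrees of freedom) divided by the mean of the
#' hand-measured values gives a scale-free accuracy measure that is
#' invariant to affine recalibration of the image measurements.
#'
#' @param hand,image Paired numeric vectors (typically genotype means).
#' @return Dimensionless CV(RMSE).
#' @export
cv_rmse <- function(hand, image) {
  ok <- is.finite(hand) & is.finite(image)
  hand <- hand[ok]; image <- image[ok]
  n <- length(hand)
  if (n < 3) stop("need at least 3 complete pairs")
  m <- mean(hand)
  if (m == 0) stop("mean of hand measurements is zero")
  fit <- stats::lm(hand ~ image)
  sqrt(sum(stats::residuals(fit)^2) / (n - 2)) / m
}

#' Trait summary statistics for a results table
#'
#' For each requested trait: repeatability from the replicated design and,
#' when a matching hand-measured column is supplied, the Pearson
#' correlation and CV(RMSE) of genotype means between the two sources.
#'
#' @param data Data frame with genotype, replication and image-trait
#'   columns.
#' @param traits Character vector of trait column names in `data`.
#' @param hand Optional data frame of hand measurements with the same
#'   genotype/rep columns; `hand_traits[i]` is compared against
#'   `traits[i]`.
#' @param hand_traits Column names in `hand` paired with `traits`.
#' @param genotype,rep Design column names.
#' @return Data frame with columns `trait`, `repeatability`, `r_vs_hand`,
#'   `cv_rmse`.
#' @export
trait_summary <- function(data, traits, hand = NULL, hand_traits = traits,
                          genotype = "genotype", rep = "rep") {
  rows <- lapply(seq_along(traits), function(i) {
    tr <- traits[i]
    rep_val <- tryCatch(repeatability(
      fit_variance_components(data, tr, genotype, rep)),
      error = function(e) NA_real_)
    r <- NA_real_; cvr <- NA_real_
    if (!is.null(hand) && hand_traits[i] %in% names(hand)) {
      gm_i <- genotype_means(data, tr, genotype)
      gm_h <- genotype_means(hand, hand_traits[i], genotype)
      j <- merge(gm_i, gm_h, by = "genotype", suffixes = c("_image", "_hand"))
      if (nrow(j) >= 3) {
        r <- pearson_r(j$mean_hand, j$mean_image)
        cvr <- cv_rmse(j$mean_hand, j$mean_image)
      }
    }
    data.frame(trait = tr, repeatability = rep_val, r_vs_hand = r,
               cv_rmse = cvr, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlation matrix of genotype means
#'
#' @param data Data frame with genotype and trait columns.
#' @param traits Trait column names.
#' @param genotype Genotype column name.
#' @return Correlation matrix of per-genotype trait means.
#' @export
trait_correlations <- function(data, traits, genotype = "genotype") {
  gms <- lapply(traits, function(tr) genotype_means(data, tr, genotype))
  ids <- Reduce(intersect, lapply(gms, `[[`, "genotype"))
  m <- vapply(gms, function(g) g$mean[match(ids, g$genotype)],
              numeric(length(ids)))
  colnames(m) <- traits
  stats::cor(m, use = "pairwise.complete.obs")
}
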