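# Multivariate tests on ilr coordinates: omnibus MANOVA, pairwise
# Hotelling's T-squared, interaction tests in a multivariate linear model,
# assumption checks, and Bonferroni multiplicity control.

# internal: Rao's F approximation for Wilks' Lambda.
# p responses, q hypothesis df, v error df.
wilks_to_f <- function(lambda, p, q, v) {
  tmp3 <- p^2 + q^2 - 5
  t <- if (tmp3 > 0) sqrt(((p * q)^2 - 4) / tmp3) else 1
  df1 <- p * q
  df2 <- (v - (p - q + 1) / 2) * t - (p * q - 2) / 2
  F <- (lambda^(-1 / t) - 1) * df2 / df1
  list(f_approx = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# internal: Pillai trace approximation (config alternative)
pillai_to_f <- function(eig, q, v) {
  p <- length(eig)
  V <- sum(eig / (1 + eig))
  s <- min(p, q)
  m <- 0.5 * (abs(p - q) - 1)
  n0 <- 0.5 * (v - p - 1)
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * n0 + s + 1)
  F <- (V / (s - V)) * (df2 / df1)
  list(statistic = V, f_approx = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

#' Omnibus MANOVA on ilr coordinates
#'
#' Tests equality of the group mean ilr vectors across k groups using
#' Wilks' Lambda (likelihood ratio of within to total cross-products) with
#' Rao's F approximation, or Pillai's trace. Because the ilr map is an
#' isometry, this is the compositionally coherent test of equality of
#' compositional centres.
#'
#' @param z Numeric matrix of ilr coordinates (n x 6).
#' @param groups Factor (or coercible) of group labels, length n.
#' @param statistic "wilks" (default) or "pillai".
#' @return List with `statistic_name`, `statistic`, `f_approx`, `df1`,
#'   `df2`, `p`.
#' @export
manova_ilr <- function(z, groups, statistic = c("wilks", "pillai")) {
  statistic <- match.arg(statistic)
  z <- as.matrix(z)
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  n <- nrow(z)
  p <- ncol(z)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) == 0)) stop("empty group", call. = FALSE)
  if (n <= p * k) stop("too few observations for ", p, " coordinates and ",
                       k, " groups", call. = FALSE)
  gbar <- rowsum(z, groups) / as.numeric(table(groups))
  centred <- z - gbar[groups, , drop = FALSE]
  E <- crossprod(centred)
  tot <- sweep(z, 2, colMeans(z))
  Tm <- crossprod(tot)
  H <- Tm - E
  if (abs(det(E)) < 1e-300) {
    stop("singular within-group cross-product matrix; check the ilr ",
         "coordinates for collinearity", call. = FALSE)
  }
  q <- k - 1
  v <- n - k
  if (statistic == "wilks") {
    lambda <- det(E) / det(E + H)
    fa <- wilks_to_f(lambda, p, q, v)
    c(list(statistic_name = "wilks", statistic = lambda), fa)
  } else {
    eig <- Re(eigen(solve(E, H), only.values = TRUE)$values)
    eig <- pmax(eig, 0)
    res <- pillai_to_f(eig, q, v)
    c(list(statistic_name = "pillai"), res)
  }
}

#' Two-sample Hotelling's T-squared test
#'
#' The multivariate generalisation of the pooled two-sample t-test, applied
#' to ilr coordinates of two exposure groups. Uses the pooled covariance;
#' the F transform is exact under multivariate normality.
#'
#' @param za,zb Matrices of ilr coordinates for the two groups (columns
#'   must agree).
#' @return List with `statistic_name = "hotelling_t2"`, `statistic` (T2),
#'   `f_approx`, `df1`, `df2`, `p`.
#' @export
hotelling_t2 <- function(za, zb) {
  za <- as.matrix(za)
  zb <- as.matrix(zb)
  if (ncol(za) != ncol(zb)) stop("coordinate mismatch", call. = FALSE)
  p <- ncol(za)
  na <- nrow(za)
  nb <- nrow(zb)
  n <- na + nb
  if (n <= p + 2) stop("too few observations to invert the pooled ",
                       "covariance", call. = FALSE)
  d <- colMeans(za) - colMeans(zb)
  Sp <- ((na - 1) * stats::cov(za) + (nb - 1) * stats::cov(zb)) / (n - 2)
  qr_sp <- qr(Sp)
  if (qr_sp$rank < p) stop("singular pooled covariance", call. = FALSE)
  t2 <- as.numeric((na * nb / n) * crossprod(d, solve(Sp, d)))
  df1 <- p
  df2 <- n - p - 1
  F <- t2 * df2 / (p * (n - 2))
  list(statistic_name = "hotelling_t2", statistic = t2, f_approx = F,
       df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# internal: Wilks test of a nested pair of multivariate linear models
wilks_nested <- function(fit_full, fit_reduced) {
  Ef <- crossprod(stats::residuals(fit_full))
  Er <- crossprod(stats::residuals(fit_reduced))
  H <- Er - Ef
  p <- ncol(Ef)
  q <- fit_full$rank - fit_reduced$rank
  v <- nrow(stats::residuals(fit_full)) - fit_full$rank
  lambda <- det(Ef) / det(Ef + H)
  fa <- wilks_to_f(lambda, p, q, v)
  c(list(statistic_name = "wilks", statistic = lambda), fa)
}

#' Test an exposure-by-modifier interaction on the ilr outcome
#'
#' Fits a multivariate linear model on all 6 ilr coordinates with the
#' exposure, the candidate effect modifier, any further covariates, and the
#' exposure x modifier interaction; returns the Wilks test of the
#' interaction block (full vs reduced model). A significant interaction at
#' the Bonferroni-adjusted critical level triggers stratified analysis.
#'
#' @param z Matrix of ilr coordinates (n x 6).
#' @param exposure Factor of foodwork categories.
#' @param modifier Factor for the candidate modifier (e.g. gender).
#' @param covariates Optional data.frame of additional covariates.
#' @return Wilks test result list (see [manova_ilr()]).
#' @export
test_interaction <- function(z, exposure, modifier, covariates = NULL) {
  z <- as.matrix(z)
  dat <- data.frame(.exposure = droplevels(as.factor(exposure)),
                    .modifier = droplevels(as.factor(modifier)))
  rhs_red <- ".exposure + .modifier"
  if (!is.null(covariates) && ncol(covariates) > 0) {
    dat <- cbind(dat, covariates)
    rhs_red <- paste(rhs_red, "+",
                     paste(names(covariates), collapse = " + "))
  }
  rhs_full <- paste(rhs_red, "+ .exposure:.modifier")
  full <- stats::lm(stats::as.formula(paste("z ~", rhs_full)), data = dat)
  red <- stats::lm(stats::as.formula(paste("z ~", rhs_red)), data = dat)
  X <- stats::model.matrix(full)
  if (full$rank < ncol(X)) {
    aliased <- colnames(X)[is.na(stats::coef(full)[, 1])]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  wilks_nested(full, red)
}

#' Assumption checks for the multivariate tests
#'
#' Advisory goodness-of-fit report: Mardia's multivariate skewness and
#' kurtosis tests of residual normality, and Box's M test of
#' between-group covariance homogeneity (chi-square approximation).
#' Quantitative substitutes for visual assumption checks; results never
#' abort the pipeline.
#'
#' @param resid Matrix of model residuals in ilr space (n x 6).
#' @param groups Factor of group labels for Box's M.
#' @return List with `mardia_skew_p`, `mardia_kurt_p`, `boxm_p` and the
#'   underlying statistics.
#' @export
gof_checks <- function(resid, groups) {
  resid <- as.matrix(resid)
  groups <- droplevels(as.factor(groups))
  n <- nrow(resid)
  p <- ncol(resid)
  xc <- sweep(resid, 2, colMeans(resid))
  S <- crossprod(xc) / n  # ML covariance for Mardia
  Sinv <- solve(S)
  G <- xc %*% Sinv %*% t(xc)
  b1 <- mean(G^3)
  skew_stat <- n * b1 / 6
  skew_df <- p * (p + 1) * (p + 2) / 6
  b2 <- mean(diag(G)^2)
  kurt_z <- (b2 - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
  ni <- as.numeric(table(groups))
  k <- nlevels(groups)
  boxm <- NA_real_
  boxm_p <- NA_real_
  if (k >= 2 && all(ni > p)) {
    Si <- lapply(levels(groups), function(g) {
      stats::cov(resid[groups == g, , drop = FALSE])
    })
    Sp <- Reduce(`+`, Map(function(S, m) (m - 1) * S, Si, ni)) / (n - k)
    M <- (n - k) * log(det(Sp)) -
      sum((ni - 1) * vapply(Si, function(S) log(det(S)), numeric(1)))
    c1 <- (sum(1 / (ni - 1)) - 1 / (n - k)) *
      (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (k - 1))
    boxm <- M * (1 - c1)
    boxm_df <- p * (p + 1) * (k - 1) / 2
    boxm_p <- stats::pchisq(boxm, boxm_df, lower.tail = FALSE)
  }
  list(mardia_skew = skew_stat,
       mardia_skew_p = stats::pchisq(skew_stat, skew_df,
                                     lower.tail = FALSE),
       mardia_kurt_z = kurt_z,
       mardia_kurt_p = 2 * stats::pnorm(-abs(kurt_z)),
       boxm = boxm,
       boxm_p = boxm_p)
}

#' Bonferroni-adjusted critical level
#'
#' Divides the family-wise alpha by the number of comparisons. With the
#' default alpha = 0.05 over 3 group comparisons this gives 0.0167,
#' reported as 0.017 and applied throughout the pipeline.
#'
#' @param family_alpha Family-wise type-I error rate (default 0.05).
#' @param comparisons Number of comparisons (default 3).
#' @return List with `family_alpha`, `comparisons`, `adjusted_alpha`.
#' @export
bonferroni <- function(family_alpha = 0.05, comparisons = 3) {
  if (family_alpha <= 0 || family_alpha >= 1 || comparisons < 1) {
    stop("invalid alpha or comparison count", call. = FALSE)
  }
  list(family_alpha = family_alpha,
       comparisons = comparisons,
       adjusted_alpha = family_alpha / comparisons)
}
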