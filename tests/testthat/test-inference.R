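# Multivariate tests: MANOVA, Hotelling's T2, interactions, assumption
# checks, Bonferroni.

test_that("manova_ilr matches the stats::manova oracle", {
  set.seed(71)
  z <- MASS::mvrnorm(90, rep(0, 6), diag(6))
  g <- factor(rep(1:3, each = 30))
  z[g == 2, 1] <- z[g == 2, 1] + 0.8
  res <- manova_ilr(z, g)
  orc <- summary(stats::manova(z ~ g), test = "Wilks")$stats
  expect_equal(res$statistic, orc["g", "Wilks"], tolerance = 1e-10)
  expect_equal(res$f_approx, orc["g", "approx F"], tolerance = 1e-8)
  expect_equal(res$p, orc["g", "Pr(>F)"], tolerance = 1e-8)

  pil <- manova_ilr(z, g, statistic = "pillai")
  orc_p <- summary(stats::manova(z ~ g), test = "Pillai")$stats
  expect_equal(pil$statistic, orc_p["g", "Pillai"], tolerance = 1e-10)
  expect_equal(pil$p, orc_p["g", "Pr(>F)"], tolerance = 1e-8)

  few <- c(1:6, 31:36)  # n = 12 <= p * k
  expect_error(manova_ilr(z[few, ], g[few]), "too few")
})

test_that("two-group Wilks relates to Hotelling's T2 by the exact identity", {
  set.seed(72)
  z <- MASS::mvrnorm(60, rep(0, 6), diag(6) + 0.2)
  g <- factor(rep(c("a", "b"), each = 30))
  z[g == "b", ] <- z[g == "b", ] + 0.3
  lam <- manova_ilr(z, g)$statistic
  t2 <- hotelling_t2(z[g == "a", ], z[g == "b", ])$statistic
  n <- nrow(z)
  expect_equal(lam, 1 / (1 + t2 / (n - 2)), tolerance = 1e-10)
})

test_that("hotelling reduces to the squared pooled t in one dimension", {
  set.seed(73)
  xa <- matrix(rnorm(25, 0, 1.3), ncol = 1)
  xb <- matrix(rnorm(35, 0.7, 1.3), ncol = 1)
  h <- hotelling_t2(xa, xb)
  tt <- stats::t.test(xa, xb, var.equal = TRUE)
  expect_equal(h$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(h$f_approx, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(h$p, tt$p.value, tolerance = 1e-10)

  # identical samples -> T2 = 0, p = 1
  same <- matrix(rnorm(40), 20, 2)
  h0 <- hotelling_t2(same, same)
  expect_equal(h0$statistic, 0, tolerance = 1e-12)
  expect_equal(h0$p, 1)
})

test_that("MANOVA decision matches univariate ANOVA in the degenerate case", {
  # all coordinates constant except one noisy coordinate: the multivariate
  # test must reduce to the one-way ANOVA on it
  set.seed(74)
  n <- 120
  g <- factor(rep(1:3, each = n / 3))
  y <- rnorm(n) + 0.5 * (g == 2)
  z <- cbind(y)
  res <- manova_ilr(z, g)
  a <- stats::anova(stats::lm(y ~ g))
  expect_equal(res$p, a[["Pr(>F)"]][1], tolerance = 1e-6)
})

test_that("tests are invariant to the choice of orthonormal ilr basis", {
  set.seed(75)
  X <- random_comps(90, seed = 75)
  g <- factor(rep(1:3, each = 30))
  b1 <- sbp_basis()
  b2 <- sbp_basis(rev(time_use_parts()))  # a different pivot order
  z1 <- log(X) %*% t(b1$V)
  z2 <- X[, rev(time_use_parts())]
  z2 <- log(z2) %*% t(b2$V)
  m1 <- manova_ilr(z1, g)
  m2 <- manova_ilr(z2, g)
  expect_equal(m1$statistic, m2$statistic, tolerance = 1e-8)
  h1 <- hotelling_t2(z1[g == 1, ], z1[g == 2, ])
  h2 <- hotelling_t2(z2[g == 1, ], z2[g == 2, ])
  expect_equal(h1$statistic, h2$statistic, tolerance = 1e-8)
})

test_that("interaction test: null calibration, power, label symmetry", {
  set.seed(76)
  # null: no interaction; rejection ~ nominal over quick replicates
  rej <- replicate(200, {
    z <- MASS::mvrnorm(120, rep(0, 3), diag(3))
    e <- factor(rep(c("none", "some", "more"), 40))
    m <- factor(rep(c("x", "y"), 60))
    test_interaction(z, e, m)$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.05)

  # gender-specific shift on the last coordinate is detected
  set.seed(77)
  n <- 1500
  e <- factor(rep(c("none", "some", "more"), each = n),
              levels = c("none", "some", "more"))
  m <- factor(rep(rep(c("men", "women"), each = n / 2), 3))
  z <- MASS::mvrnorm(3 * n, rep(0, 6), diag(6) * 0.25)
  z[e == "more" & m == "women", 6] <-
    z[e == "more" & m == "women", 6] + 0.15
  it <- test_interaction(z, e, m)
  expect_lt(it$p, 0.017)
  # relabeling modifier levels leaves p unchanged
  m2 <- factor(ifelse(m == "men", "B", "A"))
  expect_equal(test_interaction(z, e, m2)$p, it$p, tolerance = 1e-10)

  # oracle: anova.mlm on the nested pair
  set.seed(78)
  zs <- MASS::mvrnorm(90, rep(0, 4), diag(4))
  es <- factor(rep(1:3, 30))
  ms <- factor(rep(1:2, 45))
  full <- stats::lm(zs ~ es * ms)
  red <- stats::lm(zs ~ es + ms)
  orc <- stats::anova(full, red, test = "Wilks")
  mine <- test_interaction(zs, es, ms)
  expect_equal(mine$statistic, orc$Wilks[2], tolerance = 1e-8)
  expect_equal(mine$p, orc[["Pr(>F)"]][2], tolerance = 1e-8)
})

test_that("gof_checks flags heavy tails and calibrates on normal data", {
  set.seed(79)
  # multivariate normal residuals: Mardia p-values approximately uniform
  ps <- replicate(300, {
    r <- MASS::mvrnorm(150, rep(0, 3), diag(3))
    g <- factor(rep(1:3, 50))
    gof_checks(r, g)$mardia_skew_p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # t(3) residuals: kurtosis rejection far above 5%
  set.seed(80)
  rej <- replicate(100, {
    r <- matrix(stats::rt(150 * 3, df = 3), 150, 3)
    gof_checks(r, factor(rep(1:3, 50)))$mardia_kurt_p < 0.05
  })
  expect_gt(mean(rej), 0.5)

  # equal covariances: Box's M rejection near nominal
  set.seed(81)
  rejm <- replicate(300, {
    r <- MASS::mvrnorm(180, rep(0, 3), diag(3))
    gof_checks(r, factor(rep(1:3, each = 60)))$boxm_p < 0.05
  })
  expect_lt(abs(mean(rejm) - 0.05), 0.04)
})

test_that("bonferroni arithmetic", {
  b <- bonferroni(0.05, 3)
  expect_equal(round(b$adjusted_alpha, 3), 0.017)
  expect_equal(bonferroni(0.04, 1)$adjusted_alpha, 0.04)
  expect_equal(bonferroni(0.05, 5)$adjusted_alpha, 0.01)
  expect_error(bonferroni(1.2, 3))
})
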