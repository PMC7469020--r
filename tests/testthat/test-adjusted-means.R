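# Adjusted compositional means: model fitting, reference-grid averaging,
# back-transformation, stratification.

test_that("exposure-only fit reproduces raw group ilr means", {
  set.seed(91)
  X <- random_comps(90, seed = 91)
  g <- factor(rep(c("none", "some", "more"), each = 30),
              levels = c("none", "some", "more"))
  z <- ilr(X)
  models <- fit_ilr_models(z, g)
  zm <- adjusted_ilr_means(models)
  raw <- rowsum(z, g) / 30
  expect_equal(zm, raw[rownames(zm), ], tolerance = 1e-10)
  # permuting row order leaves coefficients unchanged
  perm <- sample(90)
  m2 <- fit_ilr_models(z[perm, ], g[perm])
  expect_equal(stats::coef(models$fit), stats::coef(m2$fit),
               tolerance = 1e-10)
})

test_that("known linear model coefficients are recovered", {
  set.seed(92)
  n <- 800
  g <- factor(sample(c("none", "some", "more"), n, TRUE),
              levels = c("none", "some", "more"))
  age <- rnorm(n, 45, 15)
  beta_some <- 0.3
  beta_age <- 0.01
  z <- matrix(rnorm(n * 2, sd = 0.5), n, 2)
  z[, 1] <- z[, 1] + beta_some * (g == "some") + beta_age * age
  models <- fit_ilr_models(z, g, data.frame(age = age))
  co <- stats::coef(models$fit)
  se_some <- summary(models$fit)[[1]]$coefficients[".exposuresome", 2]
  se_age <- summary(models$fit)[[1]]$coefficients["age", 2]
  expect_lt(abs(co[".exposuresome", 1] - beta_some), 3 * se_some)
  expect_lt(abs(co["age", 1] - beta_age), 3 * se_age)
})

test_that("balanced designs make adjustment a no-op", {
  set.seed(93)
  n <- 240
  g <- factor(rep(c("none", "some", "more"), each = n / 3),
              levels = c("none", "some", "more"))
  sex <- factor(rep(c("m", "w"), n / 2))  # balanced within category
  z <- matrix(rnorm(n * 6, sd = 0.3), n, 6)
  z[, 5] <- z[, 5] + 0.4 * (g == "more") + 0.2 * (sex == "w")
  models <- fit_ilr_models(z, g, data.frame(sex = sex))
  zm <- adjusted_ilr_means(models)
  raw <- rowsum(z, g) / (n / 3)
  expect_equal(zm, raw[rownames(zm), ], tolerance = 1e-8)
})

test_that("adjustment moves the contrast toward truth under confounding", {
  set.seed(94)
  n <- 5000
  age <- rnorm(n, 47, 18)
  # older participants do more foodwork AND age shifts z1
  p_more <- stats::plogis((age - 47) / 12)
  g <- factor(ifelse(stats::runif(n) < p_more, "more", "some"),
              levels = c("some", "more"))
  true_contrast <- 0.25
  z <- matrix(rnorm(n * 6, sd = 0.4), n, 6)
  z[, 1] <- z[, 1] + 0.015 * (age - 47) + true_contrast * (g == "more")
  raw_contrast <- mean(z[g == "more", 1]) - mean(z[g == "some", 1])
  models <- fit_ilr_models(z, g, data.frame(age = age))
  zm <- adjusted_ilr_means(models)
  adj_contrast <- zm["more", 1] - zm["some", 1]
  expect_lt(abs(adj_contrast - true_contrast),
            abs(raw_contrast - true_contrast))
  expect_lt(abs(adj_contrast - true_contrast), 0.05)
})

test_that("back-transformation closes, stays positive, and matches the geometric-mean route", {
  zm <- rbind(none = rep(0, 6), some = rnorm(6, sd = 3))
  res <- back_transform_means(zm)
  expect_equal(unname(res$minutes["none", ]), rep(1440 / 7, 7),
               tolerance = 1e-10)
  expect_true(all(res$minutes > 0))
  expect_equal(unname(rowSums(res$minutes)), c(1440, 1440),
               tolerance = 1e-9)

  # covariate-free balanced data: full chain equals closed geometric means
  X <- random_comps(60, seed = 95)
  g <- factor(rep(c("some", "more"), each = 30),
              levels = c("some", "more"))
  am <- adjusted_comp_means(X, g)
  expect_equal(am$minutes["some", ], comp_mean(X[g == "some", ]),
               tolerance = 1e-8)
  expect_equal(am$minutes["more", ], comp_mean(X[g == "more", ]),
               tolerance = 1e-8)
})

test_that("adjusted shares are scale coherent", {
  set.seed(96)
  X <- random_comps(120, seed = 96)
  g <- factor(rep(c("none", "some", "more"), 40))
  cov <- data.frame(sex = factor(sample(c("m", "w"), 120, TRUE)))
  a <- adjusted_comp_means(X, g, cov)
  b <- adjusted_comp_means(X * 3, g, cov)  # diaries rescaled
  expect_equal(a$minutes, b$minutes, tolerance = 1e-9)
})

test_that("stratified analysis recovers stratum-specific effects", {
  set.seed(97)
  n <- 3000
  basis <- sbp_basis()
  sex <- factor(rep(c("men", "women"), each = n / 2))
  g <- factor(sample(c("some", "more"), n, TRUE),
              levels = c("some", "more"))
  z <- matrix(rnorm(n * 6, sd = 0.25), n, 6)
  # effect on z5 only among women
  z[, 5] <- z[, 5] + 0.3 * (g == "more" & sex == "women")
  X <- ilr_inv(z, basis)
  cov <- data.frame(sex = sex,
                    age = rnorm(n, 45, 10))
  res <- stratified_adjusted_means(X, g, cov, "sex")
  expect_named(res, c("men", "women"))
  d_men <- ilr(res$men$minutes["more", ], basis)[5] -
    ilr(res$men$minutes["some", ], basis)[5]
  d_wom <- ilr(res$women$minutes["more", ], basis)[5] -
    ilr(res$women$minutes["some", ], basis)[5]
  expect_lt(abs(d_men), 0.05)
  expect_lt(abs(d_wom - 0.3), 0.05)
  expect_error(stratified_adjusted_means(X, g, cov, "nope"), "stratifier")
})

test_that("null stratification: strata agree and pooled lies between", {
  set.seed(98)
  n <- 2400
  basis <- sbp_basis()
  strat <- factor(rep(c("a", "b"), n / 2))
  g <- factor(rep(c("some", "more"), each = n / 2),
              levels = c("some", "more"))
  z <- MASS::mvrnorm(n, rep(0, 6), diag(6) * 0.09)
  z[g == "more", 5] <- z[g == "more", 5] + 0.2
  X <- ilr_inv(z, basis)
  cov <- data.frame(strat = strat)
  res <- stratified_adjusted_means(X, g, cov, "strat")
  pooled <- adjusted_comp_means(X, g)
  for (part in time_use_parts()) {
    a <- res$a$minutes["more", part]
    b <- res$b$minutes["more", part]
    expect_lt(abs(a - b) / pooled$minutes["more", part], 0.1)
    expect_gte(pooled$minutes["more", part], min(a, b) * 0.999)
    expect_lte(pooled$minutes["more", part], max(a, b) * 1.001)
  }
})
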