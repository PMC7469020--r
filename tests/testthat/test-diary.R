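# Diary validation, part mapping, foodwork exposure, and the descriptive
# statistics helpers.

test_that("validate_diary applies each exclusion flag", {
  tax <- default_taxonomy()
  d <- basic_diary()
  ok <- validate_diary(d$acts, d$travel, tax)
  expect_true(ok$include)
  expect_equal(ok$missing_minutes, 0)
  expect_gte(ok$episode_count, 7)

  # 100 missing minutes -> excluded (flag threshold is 90)
  miss <- d$acts
  miss[1:10] <- "missing"
  v <- validate_diary(miss, d$travel, tax)
  expect_equal(v$missing_minutes, 100)
  expect_false(v$include)
  # 90 missing minutes alone is still allowed by that flag, but the diary
  # is no longer a full 24 h of eligible codes
  miss9 <- d$acts
  miss9[1:9] <- "missing"
  expect_false(validate_diary(miss9, d$travel, tax)$include)

  # fewer than seven episodes: 6 blocks -> 6 episodes
  six <- c(rep("sleep_bed", 48), rep("pcare_wash", 12),
           rep("eat_meal", 12), rep("work_paid", 36),
           rep("screen_tv", 24), rep("pa_walk", 12))
  v6 <- validate_diary(six, rep("none", 144), tax)
  expect_equal(v6$episode_count, 6)
  expect_false(v6$include)
  # a travel-flag change alone starts a new episode
  trv <- rep("none", 144)
  trv[60] <- "travel_active"
  expect_equal(validate_diary(six, trv, tax)$episode_count, 7)

  # two or more basic activities missing
  nb <- c(rep("sleep_bed", 72), rep("work_paid", 72))
  v_nb <- validate_diary(nb, rep("none", 144), tax)
  expect_gte(v_nb$basic_activities_missing, 2)
  expect_false(v_nb$include)

  # zero sleep
  ns <- c(rep("pcare_wash", 24), rep("eat_meal", 24), rep("pa_walk", 24),
          rep("work_paid", 72))
  v_ns <- validate_diary(ns, rep("none", 144), tax)
  expect_true(v_ns$zero_sleep)
  expect_false(v_ns$include)

  expect_error(validate_diary(d$acts[1:100], d$travel[1:100]), "144")
  bad <- d$travel
  bad[3] <- "teleport"
  expect_error(validate_diary(d$acts, bad, tax), "slot 3")
})

test_that("select_one_diary is deterministic and uniform", {
  n <- 400
  diaries <- data.frame(participant_id = rep(seq_len(n), each = 2),
                        day = rep(1:2, n))
  s1 <- select_one_diary(diaries, seed = 9)
  s2 <- select_one_diary(diaries, seed = 9)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), n)
  expect_equal(unname(table(s1$participant_id)), rep(1L, n),
               ignore_attr = TRUE)
  # day-1 fraction ~ Binomial(400, .5); 4 sd band
  frac <- mean(s1$day == 1)
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / n))
  one <- data.frame(participant_id = 1, day = 7)
  expect_identical(select_one_diary(one, seed = 1)$day, 7)
})

test_that("map_to_parts allocates travel to the activity it enables", {
  tax <- default_taxonomy()
  allsleep <- map_to_parts(rep("sleep_bed", 144), rep("none", 144), tax)
  expect_equal(unname(allsleep),
               c(0, 1440, 0, 0, 0, 0, 0))

  # active travel inside an all-work diary -> physical activity
  acts <- rep("work_paid", 144)
  trv <- rep("none", 144)
  trv[10] <- "travel_active"
  m <- map_to_parts(acts, trv, tax)
  expect_equal(unname(m[c("physical_activity", "work")]), c(10, 1430))

  # passive travel inherits the next non-travel slot's part
  acts2 <- c(rep("sleep_bed", 50), "travel_bus", "work_paid",
             rep("sleep_bed", 92))
  trv2 <- rep("none", 144)
  trv2[51] <- "travel_passive"
  m2 <- map_to_parts(acts2, trv2, tax)
  expect_equal(unname(m2["work"]), 20)

  # trailing passive travel wraps past the diary end
  acts3 <- c(rep("sleep_bed", 143), "travel_bus")
  trv3 <- c(rep("none", 143), "travel_passive")
  m3 <- map_to_parts(acts3, trv3, tax)
  expect_equal(unname(m3["sleep"]), 1440)

  expect_error(map_to_parts(c(rep("sleep_bed", 143), "zzz"),
                            rep("none", 144), tax), "zzz")
})

test_that("slot conservation: parts + missing = 1440 over random diaries", {
  tax <- default_taxonomy()
  set.seed(21)
  codes <- c(tax$code, "missing")
  for (r in 1:20) {
    acts <- sample(codes, 144, replace = TRUE)
    trv <- sample(c("none", "travel_active", "travel_passive"), 144,
                  replace = TRUE, prob = c(0.9, 0.05, 0.05))
    m <- map_to_parts(acts, trv, tax)
    missing <- 10 * sum(acts == "missing" & trv == "none")
    expect_equal(sum(m) + missing, 1440)
    # foodwork is contained in the work part
    expect_lte(foodwork_minutes(acts, trv, tax), m["work"])
  }
})

test_that("foodwork minutes sum flagged slots", {
  tax <- default_taxonomy()
  d <- basic_diary()
  expect_equal(foodwork_minutes(d$acts, d$travel, tax), 30)
  acts <- rep("sleep_bed", 144)
  expect_equal(foodwork_minutes(acts, rep("none", 144), tax), 0)
  acts[1:3] <- "food_prep"
  acts[4] <- "food_dishes"
  expect_equal(foodwork_minutes(acts, rep("none", 144), tax), 40)
})

test_that("engager median and categorisation", {
  expect_equal(engager_median(c(0, 0, 30, 110)), 70)
  expect_error(engager_median(c(0, 0, 0)), "engaged")
  set.seed(31)
  x <- stats::rexp(20000, 1 / 70)
  expect_lt(abs(engager_median(x) - 70 * log(2)), 2)

  cat <- categorize_foodwork(c(0, 69, 70, 200), threshold = 70)
  # 70 with threshold 70 belongs to 'more' (the boundary is inclusive)
  expect_equal(as.character(cat), c("none", "some", "more", "more"))
  # partition: every observation in exactly one category
  expect_false(anyNA(cat))
})

test_that("pearson_chi2 matches hand computation and is permutation invariant", {
  t0 <- matrix(c(10, 20, 30, 40), 2, byrow = TRUE)
  r <- pearson_chi2(t0)
  # expected counts 12,18,28,42 -> 1/3 + 2/9 + 1/7 + 2/21
  expect_equal(r$statistic, 1 / 3 + 2 / 9 + 1 / 7 + 2 / 21,
               tolerance = 1e-12)
  expect_equal(r$df, 1)

  expect_equal(pearson_chi2(matrix(10, 2, 2))$statistic, 0)

  set.seed(41)
  tab <- matrix(rpois(12, 40) + 1, 3, 4)
  a <- pearson_chi2(tab)
  b <- pearson_chi2(tab[sample(3), sample(4)])
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  # oracle: stats::chisq.test without continuity correction
  cq <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(a$statistic, unname(cq$statistic), tolerance = 1e-10)
  expect_equal(a$p, cq$p.value, tolerance = 1e-10)

  expect_error(pearson_chi2(matrix(c(0, 0, 1, 2), 2)), "margin")
})

test_that("anova_f_summary agrees with raw-data ANOVA on matched moments", {
  expect_equal(anova_f_summary(c(10, 10), c(5, 5), c(1, 2))$F, 0)
  set.seed(51)
  g <- list(rnorm(13, 2), rnorm(21, 2.5), rnorm(17, 1.6))
  n <- lengths(g)
  m <- vapply(g, mean, 0)
  s <- vapply(g, sd, 0)
  res <- anova_f_summary(n, m, s)
  raw <- stats::oneway.test(y ~ grp, data = data.frame(
    y = unlist(g), grp = factor(rep(seq_along(g), n))),
    var.equal = TRUE)
  expect_equal(res$F, unname(raw$statistic), tolerance = 1e-8)
  expect_equal(res$p, raw$p.value, tolerance = 1e-8)
  expect_error(anova_f_summary(c(5, 1), c(1, 2), c(1, 1)), "n >= 2")
})
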