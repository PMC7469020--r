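# Shared fixtures: random compositions, tiny diaries, and a two-group
# logistic-normal sampler used across test files.

random_comps <- function(n, seed = 1, lmin = log(5), lmax = log(600)) {
  set.seed(seed)
  m <- matrix(exp(stats::runif(n * 7, lmin, lmax)), n, 7,
              dimnames = list(NULL, time_use_parts()))
  closure(m)
}

# a clean diary: blocks covering all seven parts, no travel
basic_diary <- function() {
  acts <- c(rep("sleep_bed", 48),        # 480 min
            rep("pcare_wash", 6),        # 60
            rep("eat_meal", 9),          # 90
            rep("work_paid", 42),        # 420
            rep("food_prep", 3),         # 30
            rep("pa_walk", 6),           # 60
            rep("screen_tv", 18),        # 180
            rep("social_visit", 12))     # 120
  list(acts = acts, travel = rep("none", 144))
}

# draw two exposure groups from the logistic-normal model, no covariates
two_group_sample <- function(n_per_group, mu_a, mu_b, sigma,
                             levels = c("some", "more")) {
  basis <- sbp_basis()
  z <- rbind(MASS::mvrnorm(n_per_group, ilr(closure(mu_a), basis), sigma),
             MASS::mvrnorm(n_per_group, ilr(closure(mu_b), basis), sigma))
  list(comps = ilr_inv(z, basis),
       z = z,
       exposure = factor(rep(levels, each = n_per_group), levels = levels))
}
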