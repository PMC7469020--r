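# Synthetic survey generator: covariates, logistic-normal compositions with
# known ground truth, rounded-zero injection, and full 144-slot diaries.
# Stands in for the restricted survey microdata so every pipeline stage can
# be validated against a known truth.

#' Default simulation configuration
#'
#' The stated world of the generator. Category compositional means follow
#' the qualitative ordering of the motivating findings (work largest and
#' sleep smallest in the 'more' foodwork category; personal care and
#' socialising lower with more foodwork); they are plausible round numbers,
#' not estimates from any survey. Residual ilr dispersion is 0.25 per
#' coordinate (exchangeable correlation 0.10): roughly +/-28% relative
#' spread per log-ratio after demographics are accounted for, with the
#' covariate effects below supplying the rest of the realistic marginal
#' variability. Covariate effects are sum-to-zero coded across levels (age
#' centred at its population mean), so the covariate-adjusted equal-grid
#' mean of each category equals that category's generating mean --
#' which is what makes recovery tests well-posed. Covariate marginals
#' mirror a UK adult diary sample (47% men, 60% economically active,
#' mean age 47.9, sd 18.3, truncated at 16).
#'
#' @param n_per_category Named vector of participants per foodwork
#'   category (default 1500 each).
#' @param seed Optional integer seed stored in the config.
#' @return List of class `sim_config` with elements `n_per_category`,
#'   `mu_minutes` (3 x 7 true category means, rows summing to 1440),
#'   `sigma_ilr` (6 x 6 positive-definite residual covariance),
#'   `effects` (per-covariate ilr effect matrices, rows summing to zero),
#'   `age_slope` (per-year ilr effect on centred age), `marginals`,
#'   `zeros` (rounding behaviour) and `foodwork` (minute ranges per
#'   category).
#' @export
sim_config <- function(n_per_category = c(none = 1500, some = 1500,
                                          more = 1500),
                       seed = NULL) {
  parts <- time_use_parts()
  mu <- rbind(
    none = c(50, 530, 75, 48, 215, 310, 212),
    some = c(52, 520, 80, 50, 200, 345, 193),
    more = c(45, 505, 78, 52, 190, 400, 170))
  colnames(mu) <- parts
  stopifnot(all(rowSums(mu) == day_total()))
  sigma <- matrix(0.10 * 0.25^2, 6, 6)
  diag(sigma) <- 0.25^2
  # ilr coordinate order: z1 sleep:pc, z2 eating, z3 physical activity,
  # z4 screen, z5 work, z6 socialising
  eff <- list(
    gender = rbind(men = c(0, 0, 0.02, 0.05, -0.10, 0),
                   women = c(0, 0, -0.02, -0.05, 0.10, 0)),
    economic_activity = rbind(active = c(-0.03, 0, -0.05, -0.10, 0.30, 0),
                              inactive = c(0.03, 0, 0.05, 0.10, -0.30, 0)),
    occupational_grade = rbind(professional_managerial =
                                 c(0, 0, 0.02, -0.02, 0.04, 0),
                               intermediate = c(0, 0, 0.01, 0, 0.01, 0),
                               routine_semiroutine =
                                 c(0, 0, -0.01, 0, -0.01, 0),
                               not_applicable = c(0, 0, -0.02, 0.02,
                                                  -0.04, 0)),
    education = rbind(still_in_education = c(0, 0, 0, 0.05, -0.15, 0.05),
                      age_16_or_under = c(0, 0, 0, 0, 0.05, -0.02),
                      over_16 = c(0, 0, 0, -0.05, 0.10, -0.03)),
    children_under_16 = rbind(yes = c(0, -0.02, 0, -0.03, 0.10, -0.05),
                              no = c(0.00, 0.02, 0, 0.03, -0.10, 0.05)),
    day_type = rbind(weekday = c(-0.05, 0, 0, -0.05, 0.25, -0.05),
                     weekend = c(0.05, 0, 0, 0.05, -0.25, 0.05)))
  eff <- lapply(eff, function(m) sweep(m, 2, colMeans(m)))  # exact sum-0
  structure(list(
    n_per_category = n_per_category,
    mu_minutes = mu,
    sigma_ilr = sigma,
    effects = eff,
    age_slope = c(0.002, 0, -0.002, 0, 0.001, 0),
    age_center = 47.9,
    marginals = list(
      gender = c(men = 0.473, women = 0.527),
      economic_activity = c(active = 0.605, inactive = 0.395),
      occupational_grade = c(professional_managerial = 0.342,
                             intermediate = 0.278,
                             routine_semiroutine = 0.266,
                             not_applicable = 0.114),
      education = c(still_in_education = 0.160, age_16_or_under = 0.394,
                    over_16 = 0.446),
      children_under_16 = c(yes = 0.331, no = 0.669),
      day_type = c(weekday = 0.504, weekend = 0.496),
      age = c(mean = 47.9, sd = 18.3, min = 16, max = 95)),
    zeros = list(prob = stats::setNames(rep(1, 7), parts),
                 shrink_prob = stats::setNames(rep(0, 7), parts),
                 detection_limit = 10),
    foodwork = list(some_range = c(10, 60), more_range = c(70, 240)),
    seed = seed),
    class = "sim_config")
}

#' Simulate a participant covariate table
#'
#' Independent draws from the configured marginal distributions (age is a
#' truncated normal; all other covariates categorical).
#'
#' @param n Number of participants.
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @return data.frame with age, gender, economic_activity,
#'   occupational_grade, education, children_under_16 and day_type.
#' @export
simulate_covariates <- function(n, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- config$marginals
  draw_cat <- function(p) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("invalid probability vector", call. = FALSE)
    }
    factor(sample(names(p), n, replace = TRUE, prob = p),
           levels = names(p))
  }
  age <- stats::rnorm(n, m$age["mean"], m$age["sd"])
  age <- pmin(pmax(age, m$age["min"]), m$age["max"])
  data.frame(age = round(age, 1),
             gender = draw_cat(m$gender),
             economic_activity = draw_cat(m$economic_activity),
             occupational_grade = draw_cat(m$occupational_grade),
             education = draw_cat(m$education),
             children_under_16 = draw_cat(m$children_under_16),
             day_type = draw_cat(m$day_type))
}

#' Simulate compositions from the logistic-normal model
#'
#' Per participant, draws ilr coordinates from a multivariate normal with
#' mean `ilr(category mean) + covariate effects + age_slope * (age -
#' age_center)` and the configured residual covariance, then maps back to
#' the simplex closed to 1440 min. Optionally snaps to the 10-minute diary
#' grid by largest-remainder rounding (sum preserved exactly).
#'
#' @param config A `sim_config`.
#' @param covariates Covariate table from [simulate_covariates()] (one row
#'   per participant, ordered by category blocks); NULL for no covariate
#'   effects.
#' @param grid_snap Snap outputs to multiples of 10 min (default FALSE).
#' @param seed Integer seed.
#' @return List with `comps` (n x 7 matrix), `exposure` (factor), and
#'   `truth` (generating means, effect list, covariance).
#' @export
simulate_compositions <- function(config = sim_config(),
                                  covariates = NULL,
                                  grid_snap = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  ev <- eigen(config$sigma_ilr, symmetric = TRUE, only.values = TRUE)$values
  # zero covariance is a legitimate degenerate world (every draw at its
  # category mean); only genuinely negative eigenvalues are rejected
  if (any(ev < -1e-8 * max(abs(ev), 1))) {
    stop("sigma_ilr must be positive (semi-)definite", call. = FALSE)
  }
  basis <- sbp_basis()
  n_cat <- config$n_per_category
  exposure <- factor(rep(names(n_cat), n_cat),
                     levels = c("none", "some", "more"))
  n <- length(exposure)
  mu_ilr <- ilr(closure(config$mu_minutes), basis)
  shift <- mu_ilr[as.character(exposure), , drop = FALSE]
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == n)
    for (nm in names(config$effects)) {
      E <- config$effects[[nm]]
      shift <- shift + E[as.character(covariates[[nm]]), , drop = FALSE]
    }
    shift <- shift +
      outer(covariates$age - config$age_center, config$age_slope)
  }
  z <- shift + MASS::mvrnorm(n, mu = rep(0, 6), Sigma = config$sigma_ilr)
  comps <- ilr_inv(z, basis, day_total())
  if (grid_snap) comps <- snap_to_grid(comps)
  list(comps = comps, exposure = exposure,
       truth = list(mu_minutes = config$mu_minutes, mu_ilr = mu_ilr,
                    effects = config$effects,
                    age_slope = config$age_slope,
                    sigma_ilr = config$sigma_ilr))
}

#' Snap compositions to the 10-minute diary grid
#'
#' Largest-remainder rounding to multiples of 10 min preserving the row
#' sum at 1440 exactly. Parts below 5 min can round to zero -- the same
#' rounding mechanism that produces rounded zeros in real diaries.
#'
#' @param comps Matrix of compositions closed to 1440.
#' @return Matrix of multiples of 10, rows summing to 1440.
#' @export
snap_to_grid <- function(comps) {
  m <- as_comp_matrix(comps)
  t(apply(m, 1, function(x) {
    slots <- x / 10
    fl <- floor(slots)
    need <- 144L - as.integer(sum(fl))
    if (need > 0) {
      up <- order(slots - fl, decreasing = TRUE)[seq_len(need)]
      fl[up] <- fl[up] + 1
    }
    10 * fl
  }))
}

#' Inject rounded zeros with retained ground truth
#'
#' Emulates the detection-limit mechanism: cells below the limit are
#' recorded as zero with probability `prob[part]` (default 1: a 10-minute
#' diary grid cannot record shorter activities). Optionally, cells at or
#' above the limit are first shrunk to a uniform draw on (0, limit) with
#' probability `shrink_prob[part]` and then zeroed -- a stress mode for
#' imputation tests. The true sub-limit values are returned for recovery
#' checks; rows are re-closed to 1440 after zeroing.
#'
#' @param comps Strictly positive composition matrix closed to 1440.
#' @param config A `sim_config` (its `zeros` block is used).
#' @param seed Integer seed.
#' @return List with `comps` (zeros introduced), `truth_mask` (logical
#'   matrix) and `truth_values` (matrix, NA where not zeroed).
#' @export
inject_rounded_zeros <- function(comps, config = sim_config(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- as_comp_matrix(comps)
  if (any(m <= 0)) stop("inputs must be strictly positive", call. = FALSE)
  zc <- config$zeros
  dl <- zc$detection_limit
  prob <- zc$prob[colnames(m) %||% time_use_parts()]
  shrink <- zc$shrink_prob[colnames(m) %||% time_use_parts()]
  n <- nrow(m)
  truth <- matrix(NA_real_, n, ncol(m), dimnames = dimnames(m))
  out <- m
  for (j in seq_len(ncol(m))) {
    sub <- m[, j] < dl
    hit <- sub & (stats::runif(n) < prob[j])
    if (shrink[j] > 0) {
      sh <- !sub & (stats::runif(n) < shrink[j])
      out[sh, j] <- stats::runif(sum(sh), 0, dl)
      hit <- hit | sh
    }
    truth[hit, j] <- out[hit, j]
    out[hit, j] <- 0
  }
  keep <- rowSums(out) > 0
  if (!all(keep)) stop("a row lost all its parts", call. = FALSE)
  pos <- out > 0
  out <- out * (day_total() / rowSums(out))
  out[!pos] <- 0
  list(comps = out, truth_mask = !is.na(truth), truth_values = truth)
}

#' Expand a grid composition into a 144-slot diary
#'
#' Inverse of [map_to_parts()] for end-to-end tests: writes contiguous
#' blocks of slots per part (in randomised order), with the requested
#' foodwork minutes carved out of the work block using the taxonomy's
#' foodwork codes. All travel flags are `none`, so the diary maps back to
#' exactly the input composition.
#'
#' @param comp Named 7-vector of minutes, multiples of 10, summing to 1440.
#' @param foodwork Foodwork minutes (multiple of 10, at most the work
#'   part).
#' @param taxonomy Activity taxonomy.
#' @param seed Integer seed for the block order.
#' @return List with `acts` and `travel` (length-144 character vectors).
#' @export
expand_to_diary <- function(comp, foodwork = 0,
                            taxonomy = default_taxonomy(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  parts <- time_use_parts()
  comp <- comp[parts]
  if (any(comp %% 10 != 0) || sum(comp) != day_total()) {
    stop("composition must be multiples of 10 min summing to 1440",
         call. = FALSE)
  }
  if (foodwork %% 10 != 0 || foodwork > comp["work"]) {
    stop("foodwork must be a multiple of 10 within the work part",
         call. = FALSE)
  }
  code_for <- function(part, fw = FALSE) {
    cand <- taxonomy$code[taxonomy$part == part &
                            taxonomy$is_foodwork == fw]
    if (length(cand) == 0) stop("taxonomy lacks codes for part ", part,
                                call. = FALSE)
    cand
  }
  acts <- character(0)
  for (p in sample(parts[comp > 0])) {
    k <- comp[p] / 10
    if (p == "work") {
      kf <- foodwork / 10
      fw_codes <- rep_len(code_for("work", TRUE), max(kf, 1))[seq_len(kf)]
      acts <- c(acts, fw_codes, rep(code_for(p)[1], k - kf))
    } else {
      acts <- c(acts, rep(code_for(p)[1], k))
    }
  }
  list(acts = acts, travel = rep("none", 144))
}

#' Simulate a complete analysis-ready sample
#'
#' One call producing everything the pipeline consumes: covariates,
#' compositions with rounded zeros (ground truth retained), foodwork
#' minutes consistent with the category labels, and the generating truth.
#'
#' @param config A `sim_config`.
#' @param seed Master integer seed.
#' @param grid_snap Snap compositions to the 10-min grid.
#' @return List with `covariates`, `comps` (with zeros), `comps_true`,
#'   `zero_truth`, `exposure`, `foodwork_minutes`, `truth`.
#' @export
simulate_sample <- function(config = sim_config(), seed = 1L,
                            grid_snap = FALSE) {
  set.seed(as.integer(seed))
  n <- sum(config$n_per_category)
  covs <- simulate_covariates(n, config)
  sim <- simulate_compositions(config, covs, grid_snap = grid_snap)
  zr <- inject_rounded_zeros(sim$comps, config)
  fw <- numeric(n)
  some <- sim$exposure == "some"
  more <- sim$exposure == "more"
  r_some <- config$foodwork$some_range
  r_more <- config$foodwork$more_range
  fw[some] <- 10 * sample(seq(r_some[1] / 10, r_some[2] / 10),
                          sum(some), replace = TRUE)
  fw[more] <- 10 * sample(seq(r_more[1] / 10, r_more[2] / 10),
                          sum(more), replace = TRUE)
  # foodwork sits inside the work part; cap at the realised work minutes
  fw <- pmin(fw, 10 * floor(sim$comps[, "work"] / 10))
  fw[some & fw == 0] <- 10
  list(covariates = covs, comps = zr$comps, comps_true = sim$comps,
       zero_truth = zr, exposure = sim$exposure, foodwork_minutes = fw,
       truth = sim$truth)
}
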