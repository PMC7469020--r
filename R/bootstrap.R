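# Per-part log-ratio differences between foodwork categories with
# nonparametric bootstrap percentile confidence intervals.
#
# The resampling loop avoids lm() overhead: with the multiplicative zero
# fill (row-wise deterministic) the imputed ilr matrix can be computed
# once and row-subset per resample, and with the additive OLS design the
# adjusted category means are linear functionals g_lv' beta of the
# coefficients, where g_lv is the reference-grid average design row for
# category lv. This is algebraically identical to the
# impute -> ilr -> fit -> adjust -> back-transform chain run per resample
# (asserted against adjusted_comp_means() in the test suite); the
# data-augmentation imputation method falls back to the full chain.

#' Bootstrap CIs for per-part log-ratio differences
#'
#' Point estimate: the per-part log-ratio difference
#' `ln(adjusted minutes in pair[1] / adjusted minutes in pair[2])`
#' between two foodwork categories' covariate-adjusted compositional
#' means. Uncertainty: nonparametric case resampling with replacement,
#' stratified within exposure category (preserving group sizes), re-running
#' impute -> ilr -> fit -> adjust -> back-transform on every resample;
#' percentile interval at `level`. The default level 1 - 0.017 = 0.983
#' ties the zero-crossing decision to the Bonferroni-adjusted critical
#' level: an interval that crosses zero indicates no between-group
#' difference for that part.
#'
#' @param comps Matrix of raw compositions (zeros allowed; imputed
#'   internally per resample).
#' @param exposure Factor of foodwork categories.
#' @param covariates Optional covariate data.frame (complete cases
#'   required).
#' @param pair Character vector of two category levels, numerator first
#'   (e.g. `c("more", "some")`).
#' @param B Number of bootstrap resamples (default 1999; at least 999 for
#'   a stable percentile interval).
#' @param level Confidence level (default 0.983).
#' @param seed Integer seed for reproducibility.
#' @param basis Pivot ilr basis.
#' @param grid Reference-grid policy: "equal" weights covariate levels
#'   equally, "proportional" weights them by their resample frequencies.
#' @param impute_method Zero-replacement method used on each resample
#'   ("multiplicative", the fast default, or "data_augmentation").
#' @param detection_limit,delta_fraction Passed to [impute_zeros()].
#' @return data.frame with one row per part: `pair`, `part`, `estimate`,
#'   `ci_low`, `ci_high`, `significant`, `B`, `level`, `seed`.
#' @export
logratio_diff_ci <- function(comps, exposure, covariates = NULL,
                             pair = c("more", "some"),
                             B = 1999, level = 0.983, seed = 1L,
                             basis = sbp_basis(),
                             grid = c("equal", "proportional"),
                             impute_method = "multiplicative",
                             detection_limit = 10,
                             delta_fraction = 0.65) {
  grid <- match.arg(grid)
  if (B < 999) stop("B must be at least 999", call. = FALSE)
  comps <- as_comp_matrix(comps)
  exposure <- droplevels(as.factor(exposure))
  if (!all(pair %in% levels(exposure))) {
    stop("pair levels not present in exposure", call. = FALSE)
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (any(!stats::complete.cases(covariates))) {
      stop("bootstrap requires complete covariates", call. = FALSE)
    }
  }
  n <- nrow(comps)
  fast <- impute_method == "multiplicative"

  if (fast) {
    Z <- ilr(impute_zeros(comps, method = "multiplicative",
                          detection_limit = detection_limit,
                          delta_fraction = delta_fraction), basis)
    dat <- data.frame(.exposure = exposure)
    if (!is.null(covariates)) {
      for (nm in names(covariates)) {
        if (!is.numeric(covariates[[nm]])) {
          covariates[[nm]] <- droplevels(as.factor(covariates[[nm]]))
        }
      }
      dat <- cbind(dat, covariates)
    }
    X <- stats::model.matrix(
      stats::as.formula(paste("~", paste(names(dat), collapse = " + "))),
      dat)
    asgn <- attr(X, "assign")
    labs <- c("(Intercept)",
              attr(stats::terms(
                stats::as.formula(paste("~", paste(names(dat),
                                                   collapse = " + ")))),
                "term.labels"))
    # column template for the reference-grid average design row:
    # exposure dummies set per category; categorical covariate dummies at
    # 1/L (equal grid) or their resample mean (proportional); continuous
    # covariates at their resample mean; intercept 1.
    col_kind <- character(ncol(X))   # "intercept"/"exposure"/"mean"/"fixed"
    col_fixed <- numeric(ncol(X))
    for (j in seq_len(ncol(X))) {
      lab <- labs[asgn[j] + 1]
      if (lab == "(Intercept)") {
        col_kind[j] <- "fixed"; col_fixed[j] <- 1
      } else if (lab == ".exposure") {
        col_kind[j] <- "exposure"
      } else if (is.numeric(dat[[lab]])) {
        col_kind[j] <- "mean"
      } else if (grid == "equal") {
        col_kind[j] <- "fixed"
        col_fixed[j] <- 1 / nlevels(dat[[lab]])
      } else {
        col_kind[j] <- "mean"
      }
    }
    expo_cols <- which(col_kind == "exposure")
    expo_template <- function(lv) {
      # design-row entries of the exposure dummies for category lv
      nd <- dat[1, , drop = FALSE]
      nd$.exposure <- factor(lv, levels = levels(exposure))
      row <- stats::model.matrix(stats::delete.response(stats::terms(
        stats::as.formula(paste("~", paste(names(dat),
                                           collapse = " + "))))),
        nd, xlev = lapply(Filter(is.factor, dat), levels))
      row[1, expo_cols]
    }
    expo_rows <- lapply(stats::setNames(pair, pair), expo_template)

    adj_diff <- function(idx) {
      Xb <- X[idx, , drop = FALSE]
      qrx <- qr(Xb)
      if (qrx$rank < ncol(Xb)) return(NULL)
      beta <- qr.coef(qrx, Z[idx, , drop = FALSE])
      g <- col_fixed
      mcols <- which(col_kind == "mean")
      if (length(mcols) > 0) g[mcols] <- colMeans(Xb[, mcols, drop = FALSE])
      zm <- vapply(pair, function(lv) {
        gi <- g
        gi[expo_cols] <- expo_rows[[lv]]
        as.numeric(gi %*% beta)
      }, numeric(ncol(Z)))
      ma <- ilr_inv(zm[, 1], basis)
      mb <- ilr_inv(zm[, 2], basis)
      logratio_diff(ma, mb)
    }
  } else {
    adj_diff <- function(idx) {
      ci <- impute_zeros(comps[idx, , drop = FALSE],
                         method = impute_method,
                         detection_limit = detection_limit,
                         delta_fraction = delta_fraction,
                         seed = sample.int(.Machine$integer.max, 1))
      am <- tryCatch(
        adjusted_comp_means(ci, droplevels(exposure[idx]),
                            if (is.null(covariates)) NULL else
                              droplevels(covariates[idx, , drop = FALSE]),
                            basis, grid),
        error = function(e) NULL)
      if (is.null(am)) return(NULL)
      logratio_diff(am$minutes[pair[1], ], am$minutes[pair[2], ])
    }
  }

  est <- adj_diff(seq_len(n))
  if (is.null(est)) stop("rank-deficient design on the full data",
                         call. = FALSE)
  set.seed(as.integer(seed))
  strata <- split(seq_len(n), exposure)
  boot <- matrix(NA_real_, B, length(est))
  dropped <- 0L
  for (b in seq_len(B)) {
    idx <- unlist(lapply(strata, function(i) {
      i[sample.int(length(i), length(i), replace = TRUE)]
    }), use.names = FALSE)
    res <- adj_diff(idx)
    if (is.null(res)) {
      dropped <- dropped + 1L
      next
    }
    boot[b, ] <- res
  }
  if (dropped > 0) {
    message("logratio_diff_ci: ", dropped, " resample(s) dropped")
    if (dropped > 0.01 * B) {
      stop(dropped, " of ", B, " resamples failed (> 1%)", call. = FALSE)
    }
  }
  ok <- stats::complete.cases(boot)
  alpha <- 1 - level
  qs <- apply(boot[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE,
              type = 7)
  data.frame(pair = paste(pair, collapse = "_vs_"),
             part = names(est),
             estimate = as.numeric(est),
             ci_low = qs[1, ],
             ci_high = qs[2, ],
             significant = qs[1, ] > 0 | qs[2, ] < 0,
             B = B, level = level, seed = as.integer(seed),
             row.names = NULL)
}

#' Per-part significance markers for report tables
#'
#' Attaches the figure-style marker to significant parts: `"^"` for the
#' more-vs-some comparison and `"*"` for the some-vs-none comparison;
#' empty string where the interval crosses zero.
#'
#' @param results data.frame from [logratio_diff_ci()].
#' @return The input with a `marker` column added.
#' @export
significance_flags <- function(results) {
  marker <- ifelse(!results$significant, "",
                   ifelse(grepl("^more", results$pair), "^", "*"))
  results$marker <- marker
  results
}
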