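#' Tabulate the pattern of zeros in a composition matrix
#'
#' @param x Non-negative matrix of raw compositions (rows = diaries,
#'   columns = parts).
#' @return List with `part_counts` (zeros per part), `row_mask` (logical
#'   matrix, TRUE where zero) and `rows_with_zeros`.
#' @export
zero_pattern <- function(x) {
  m <- as_comp_matrix(x)
  if (any(m < 0)) stop("negative entries are not compositions", call. = FALSE)
  mask <- m == 0
  list(part_counts = colSums(mask),
       row_mask = mask,
       rows_with_zeros = sum(rowSums(mask) > 0))
}

#' Replace rounded zeros below the detection limit
#'
#' A recorded zero in a diary composition is treated as a rounded zero: a
#' true value below the 10-minute detection limit of the diary grid. Two
#' replacement methods are provided.
#'
#' `"multiplicative"` (deterministic default): each zero cell becomes
#' `delta_fraction * detection_limit` (6.5 min by default) and the
#' remaining parts of that row are shrunk multiplicatively so the row still
#' sums to `total` — time is drawn from the other parts and the ratios
#' among originally positive parts are unchanged.
#'
#' `"data_augmentation"`: a Markov-chain sampler in log space. Zero cells
#' are initialised at `delta_fraction * detection_limit`; each sweep fits a
#' multivariate normal to the log-minute matrix, then redraws every zero
#' cell from its univariate conditional normal given the observed cells of
#' its row, truncated above at `log(detection_limit)`; the post-burn-in
#' draws are averaged (geometrically) and rows re-closed. This estimates
#' sub-limit values from the correlation structure of the data while
#' keeping them below the limit.
#'
#' @param x Matrix of compositions with zeros; every row must have at least
#'   two positive parts, and rows are assumed closed to `total`.
#' @param method "multiplicative" or "data_augmentation".
#' @param detection_limit Minutes below which a true value is rounded to
#'   zero (default 10, the diary slot length).
#' @param delta_fraction Fraction of the detection limit used for the
#'   multiplicative fill and sampler initialisation (default 0.65).
#' @param iterations,burn_in Sweeps for the augmentation sampler.
#' @param seed Integer seed (augmentation method only).
#' @param total Row total in minutes (default 1440).
#' @return Strictly positive matrix, rows summing to `total`, imputed
#'   entries strictly below `detection_limit`.
#' @export
impute_zeros <- function(x,
                         method = c("multiplicative", "data_augmentation"),
                         detection_limit = 10,
                         delta_fraction = 0.65,
                         iterations = 60,
                         burn_in = 20,
                         seed = NULL,
                         total = day_total()) {
  method <- match.arg(method)
  m <- as_comp_matrix(x)
  if (any(m < 0)) stop("negative entries", call. = FALSE)
  if (detection_limit <= 0) stop("detection_limit must be > 0", call. = FALSE)
  if (delta_fraction <= 0 || delta_fraction >= 1) {
    stop("delta_fraction must be in (0, 1)", call. = FALSE)
  }
  all_zero <- rowSums(m > 0) == 0
  if (any(all_zero)) {
    stop("row(s) entirely zero: ", which(all_zero)[1], call. = FALSE)
  }
  mask <- m == 0
  if (!any(mask)) {
    return(closure(m, total))
  }
  out <- switch(method,
    multiplicative = impute_multiplicative(m, mask, detection_limit,
                                           delta_fraction, total),
    data_augmentation = impute_lrda(m, mask, detection_limit,
                                    delta_fraction, iterations, burn_in,
                                    seed, total))
  # contract: never emit an imputed value at or above the limit
  cap <- detection_limit * (1 - 1e-9)
  out[mask] <- pmin(out[mask], cap)
  out
}

impute_multiplicative <- function(m, mask, dl, delta, total) {
  fill <- delta * dl
  out <- m
  for (i in which(rowSums(mask) > 0)) {
    z <- mask[i, ]
    k <- sum(z)
    pos_sum <- sum(m[i, !z])
    out[i, z] <- fill
    out[i, !z] <- m[i, !z] * (total - k * fill) / pos_sum
  }
  out
}

impute_lrda <- function(m, mask, dl, delta, iterations, burn_in, seed,
                        total) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(m)
  D <- ncol(m)
  cur <- m
  cur[mask] <- delta * dl
  rows <- which(rowSums(mask) > 0)
  log_dl <- log(dl)
  acc <- matrix(0, n, D)
  kept <- 0L
  for (it in seq_len(iterations)) {
    Y <- log(cur)
    mu <- colMeans(Y)
    S <- stats::cov(Y)
    # ridge keeps the conditional solve stable when n is small
    S <- S + diag(1e-8 * mean(diag(S)), D)
    for (i in rows) {
      z <- which(mask[i, ])
      o <- which(!mask[i, ])
      Soo_inv <- solve(S[o, o, drop = FALSE])
      for (j in z) {
        cm <- mu[j] + S[j, o, drop = FALSE] %*% Soo_inv %*%
          (Y[i, o] - mu[o])
        cv <- S[j, j] - S[j, o, drop = FALSE] %*% Soo_inv %*%
          S[o, j, drop = FALSE]
        csd <- sqrt(max(as.numeric(cv), 1e-12))
        # draw from N(cm, csd^2) truncated above at log(dl)
        u <- stats::runif(1, 0, stats::pnorm(log_dl, cm, csd))
        draw <- stats::qnorm(max(u, 1e-12), cm, csd)
        cur[i, j] <- exp(min(draw, log_dl - 1e-9))
      }
    }
    if (it > burn_in) {
      acc <- acc + log(cur)
      kept <- kept + 1L
    }
  }
  est <- exp(acc / kept)
  out <- m
  for (i in rows) {
    z <- mask[i, ]
    imp <- pmin(est[i, z], dl * (1 - 1e-9))
    out[i, z] <- imp
    out[i, !z] <- m[i, !z] * (total - sum(imp)) / sum(m[i, !z])
  }
  out
}
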