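#' Close a vector of positive parts to a fixed total
#'
#' Rescales strictly positive raw part totals so they sum to `total`
#' (1440 min by default), the canonical representative of the composition.
#' Rows of a matrix are closed independently.
#'
#' @param x Numeric vector of 7 strictly positive parts, or a matrix with
#'   7 columns (one composition per row).
#' @param total Positive sum to close to (default 1440 minutes).
#' @return Object of the same shape as `x`, each (row) summing to `total`.
#' @export
#' @examples
#' closure(c(personal_care = 1, sleep = 8, eating = 1, physical_activity = 1,
#'           screen_time = 2, work = 8, social_hobbies = 3) * 60)
closure <- function(x, total = day_total()) {
  if (total <= 0) stop("total must be positive", call. = FALSE)
  m <- as_comp_matrix(x)
  if (any(!is.finite(m))) stop("non-finite part values", call. = FALSE)
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    nm <- colnames(m)
    lab <- if (is.null(nm)) paste0("part ", bad[1, 2]) else nm[bad[1, 2]]
    stop("non-positive value in part '", lab,
         "' (row ", bad[1, 1], "); run zero replacement first", call. = FALSE)
  }
  out <- m * (total / rowSums(m))
  if (!is.matrix(x)) out <- stats::setNames(drop(out), colnames(m))
  out
}

#' Sequential-binary-partition (pivot) ilr basis
#'
#' Builds the 6x7 orthonormal contrast matrix of pivot coordinates for the
#' fixed part order. Coordinate k contrasts part k+1 (positive sign) against
#' the geometric mean of parts 1..k:
#' z_k = sqrt(k/(k+1)) * ln( x_{k+1} / gm(x_1..x_k) ).
#' With the canonical order, z1 is the sleep : personal-care log-ratio, z2
#' contrasts eating against the geometric mean of sleep and personal care,
#' and so on up to z6 (socialising & hobbies against all other parts).
#'
#' @param parts Character vector of 7 distinct part labels in pivot order.
#' @return An object of class `sbp_basis`: list with `V` (6x7 contrast
#'   matrix, rows orthonormal) and `parts`.
#' @export
sbp_basis <- function(parts = time_use_parts()) {
  D <- length(parts)
  if (D < 2 || anyDuplicated(parts)) {
    stop("parts must be >= 2 distinct labels", call. = FALSE)
  }
  V <- matrix(0, D - 1, D, dimnames = list(paste0("z", seq_len(D - 1)), parts))
  for (k in seq_len(D - 1)) {
    V[k, k + 1] <- sqrt(k / (k + 1))
    V[k, seq_len(k)] <- -sqrt(1 / (k * (k + 1)))
  }
  structure(list(V = V, parts = parts), class = "sbp_basis")
}

#' @export
print.sbp_basis <- function(x, ...) {
  cat("Pivot SBP ilr basis:", length(x$parts), "parts,",
      nrow(x$V), "coordinates\n")
  print(round(x$V, 4))
  invisible(x)
}

#' Isometric log-ratio transform (pivot coordinates)
#'
#' Maps strictly positive compositions to unconstrained real coordinates
#' `z = V %*% ln(x)`. Scale invariant: the closure constant cancels, so
#' closed and unclosed inputs give identical coordinates.
#'
#' @param x Composition vector or matrix (rows), strictly positive.
#' @param basis An `sbp_basis` (default: pivot basis on the canonical parts).
#' @return Numeric vector of length 6 or matrix with 6 columns (z1..z6).
#' @export
ilr <- function(x, basis = sbp_basis()) {
  m <- as_comp_matrix(x)
  if (ncol(m) != length(basis$parts)) {
    stop("composition has ", ncol(m), " parts; basis expects ",
         length(basis$parts), call. = FALSE)
  }
  check_part_names(m)
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("ilr requires strictly positive parts; replace zeros first",
         call. = FALSE)
  }
  z <- log(m) %*% t(basis$V)
  if (!is.matrix(x)) z <- stats::setNames(drop(z), rownames(basis$V))
  z
}

#' Inverse ilr transform
#'
#' Maps ilr coordinates back to the simplex and closes to `total` minutes:
#' `x = closure(exp(t(V) %*% z), total)`.
#'
#' @param z Numeric vector of 6 coordinates or matrix with 6 columns.
#' @param basis An `sbp_basis`.
#' @param total Closure total in minutes (default 1440).
#' @return Composition vector or matrix in minutes/day.
#' @export
ilr_inv <- function(z, basis = sbp_basis(), total = day_total()) {
  zm <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  if (any(!is.finite(zm))) stop("non-finite ilr coordinates", call. = FALSE)
  if (ncol(zm) != nrow(basis$V)) {
    stop("expected ", nrow(basis$V), " coordinates", call. = FALSE)
  }
  x <- exp(zm %*% basis$V)
  colnames(x) <- basis$parts
  out <- x * (total / rowSums(x))
  if (!is.matrix(z)) out <- stats::setNames(drop(out), basis$parts)
  out
}

#' Compositional (closed geometric) mean
#'
#' The compositional centre of a sample: per-part geometric means, closed to
#' `total`. Equal to `ilr_inv` of the arithmetic mean of the ilr coordinates
#' for any orthonormal basis.
#'
#' @param x Matrix of compositions (rows strictly positive), or a single
#'   composition vector (returned closed).
#' @param total Closure total (default 1440).
#' @return Composition vector of length 7.
#' @export
comp_mean <- function(x, total = day_total()) {
  m <- as_comp_matrix(x)
  if (nrow(m) == 0) stop("empty set of compositions", call. = FALSE)
  if (any(m <= 0)) stop("compositions must be strictly positive", call. = FALSE)
  g <- exp(colMeans(log(m)))
  stats::setNames(as.numeric(g * (total / sum(g))),
                  colnames(m) %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-part log-ratio difference between two compositions
#'
#' For each part p, `ln(a_p / b_p)` on the closed representatives; the
#' statistic reported between adjusted group means. Antisymmetric under
#' argument swap. Both arguments must carry the same part order.
#'
#' @param a,b Strictly positive compositions (vectors, same names/order).
#' @return Named numeric vector of length 7 of log-ratios.
#' @export
logratio_diff <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (!is.null(names(a)) && !is.null(names(b)) &&
      !identical(names(a), names(b))) {
    stop("part order mismatch between the two compositions", call. = FALSE)
  }
  if (any(a <= 0) || any(b <= 0)) {
    stop("compositions must be strictly positive", call. = FALSE)
  }
  ac <- a / sum(a)
  bc <- b / sum(b)
  stats::setNames(log(ac / bc), names(a))
}

# internal: centred log-ratio, used only as an independent distance oracle
clr <- function(x) {
  m <- as_comp_matrix(x)
  out <- log(m) - rowMeans(log(m))
  if (!is.matrix(x)) drop(out) else out
}

#' Aitchison distance between two compositions
#'
#' Euclidean distance between centred log-ratio images; equals the Euclidean
#' distance between ilr images for any orthonormal basis (isometry).
#'
#' @param a,b Strictly positive compositions.
#' @return Non-negative scalar.
#' @export
aitchison_dist <- function(a, b) {
  sqrt(sum((clr(a) - clr(b))^2))
}
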