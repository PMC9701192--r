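# The mass-response statistic: a normalized 1-D Earth Mover's Distance
# between single-cell mass distributions, and the data-driven limit of
# decision derived from it.

#' Earth Mover's Distance between equal-size sorted samples
#'
#' For two sorted samples of equal length the 1-D optimal-transport pairing
#' is the order-statistic pairing, so the distance is simply
#' \eqn{\sum_i |X_i - Z_i|}. This is the numerator of the mass-response
#' statistic and is expressed in picogram-sum units.
#'
#' @param x,z numeric vectors of equal length, sorted ascending.
#' @return The distance \eqn{\sum_i |x_i - z_i|} in pg.
#' @seealso [emd_general()] for samples of different sizes.
#' @export
emd_sorted_equal <- function(x, z) {
  x <- as_masses(x); z <- as_masses(z)
  if (length(x) != length(z))
    stop("samples differ in size (", length(x), " vs ", length(z),
         "); use emd_general()")
  if (length(x) < 1) stop("empty sample")
  sum(abs(x - z))
}

#' Earth Mover's Distance between samples of arbitrary sizes
#'
#' Computes the 1-D Wasserstein-1 distance between the two empirical
#' distributions (the integral of the absolute difference of their CDFs) and
#' scales it by `length(z)` so that for equal-size samples it coincides
#' exactly with [emd_sorted_equal()]'s sum-over-order-statistics form.
#'
#' @param x,z numeric mass vectors (any order, any sizes).
#' @return The scaled distance in pg (sum units relative to `z`).
#' @export
emd_general <- function(x, z) {
  x <- as_masses(x); z <- as_masses(z)
  if (length(x) < 1 || length(z) < 1) stop("empty sample")
  .cpp_emd_sorted(x, z)
}

# Fast path for hot loops: both inputs already sorted, equal length.
.mr_sorted <- function(xs, zs) sum(abs(xs - zs)) / sum(zs)

#' Mass response: normalized EMD against the vehicle-treated reference
#'
#' The mass response of a treated sample \eqn{X} against the vehicle-treated
#' reference \eqn{Z} is \eqn{EMD(X, Z) / \sum_i Z_i}: the transport distance
#' between the two mass distributions normalized by the reference mass, a
#' unitless fraction (reported as percent of reference mean mass). The
#' normalization makes the signal invariant to a common rescaling of all
#' masses, so it is comparable across cell types with different baseline
#' mass.
#'
#' @param x treated sample: numeric masses or a [condition_sample()].
#' @param z vehicle-treated reference sample.
#' @param ci if `TRUE`, attach a BCa bootstrap confidence interval (see
#'   [bca_ci()]).
#' @param ci_level,R_ci,seed confidence-interval parameters, used when
#'   `ci = TRUE`.
#' @param min_n samples smaller than this carry a `low_n` flag (default 100).
#' @return An object of class `mass_response_result` with elements `value`
#'   (fraction), `n_x`, `n_z`, `direction_hint` (sign of
#'   `mean(x) - mean(z)`, metadata only — the statistic itself is
#'   non-negative), `low_n`, and CI fields when requested.
#' @examples
#' z <- rlnorm(500, log(60), 0.3)
#' mass_response(z * 1.10, z)$value # uniform +10% shift -> exactly 0.10
#' @export
mass_response <- function(x, z, ci = FALSE, ci_level = 0.90, R_ci = 5000,
                          seed = NULL, min_n = 100) {
  xs <- as_masses(x); zs <- as_masses(z)
  if (mean(zs) <= 0) stop("reference sample has non-positive mean mass")
  d <- if (length(xs) == length(zs)) sum(abs(xs - zs)) else emd_general(xs, zs)
  value <- d / sum(zs)
  res <- structure(list(value = value,
                        n_x = length(xs), n_z = length(zs),
                        ci_low = NA_real_, ci_high = NA_real_,
                        ci_level = NA_real_, R_ci = NA_integer_,
                        direction_hint = sign(mean(xs) - mean(zs)),
                        low_n = (length(xs) < min_n || length(zs) < min_n)),
                   class = "mass_response_result")
  if (ci) {
    interval <- bca_ci(xs, zs, level = ci_level, R_ci = R_ci, seed = seed)
    res$ci_low <- interval[["ci_low"]]
    res$ci_high <- interval[["ci_high"]]
    res$ci_level <- ci_level
    res$R_ci <- as.integer(R_ci)
  }
  res
}

#' @export
print.mass_response_result <- function(x, ...) {
  cat(sprintf("mass response: %.2f%% (n_x=%d, n_z=%d)%s\n",
              100 * x$value, x$n_x, x$n_z,
              if (x$low_n) " [low n]" else ""))
  if (!is.na(x$ci_low))
    cat(sprintf("  %.0f%% CI (BCa, R=%d): [%.2f%%, %.2f%%]\n",
                100 * x$ci_level, x$R_ci, 100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

#' Data-driven limit of decision
#'
#' Estimates the three-sigma limit of decision from a measured population:
#' pairs of `n_sub`-cell subsamples are repeatedly drawn from `z`, the mass
#' response between the pair members is computed, and three times the
#' standard deviation of those distances is returned. Applied to a typical
#' cell population with 500-cell subsamples this reproduces the universal 3%
#' threshold used as the default null boundary.
#'
#' @param z population sample (numeric masses or [condition_sample()]).
#' @param n_sub cells per subsample (default 500).
#' @param reps number of subsample pairs (default 1000; at least 100
#'   recommended).
#' @param disjoint if `TRUE`, the two members of each pair are drawn jointly
#'   without replacement so they share no cell (requires
#'   `length(z) >= 2 * n_sub`); the default draws each member independently
#'   with replacement.
#' @param seed integer seed.
#' @return The limit of decision as a fraction (e.g. 0.03 for 3%).
#' @export
decision_limit <- function(z, n_sub = 500, reps = 1000, disjoint = FALSE,
                           seed = NULL) {
  zs <- as_masses(z)
  m <- length(zs)
  if (m < n_sub) stop("population smaller than the subsample size")
  if (disjoint && m < 2 * n_sub)
    stop("disjoint pairs require at least 2 * n_sub cells")
  if (reps < 2) stop("reps must be at least 2")
  with_seed(seed, {
    vals <- vapply(seq_len(reps), function(i) {
      if (disjoint) {
        idx <- sample.int(m, 2 * n_sub)
        a <- zs[idx[seq_len(n_sub)]]
        b <- zs[idx[n_sub + seq_len(n_sub)]]
      } else {
        a <- zs[sample.int(m, n_sub, replace = TRUE)]
        b <- zs[sample.int(m, n_sub, replace = TRUE)]
      }
      .mr_sorted(sort(a), sort(b))
    }, numeric(1))
    3 * sd(vals)
  })
}
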