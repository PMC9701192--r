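# Inference: BCa confidence intervals for the mass-response signal, the
# theta test statistic (TEST minus CTRL signal), and the embedded
# bootstrap-t hypothesis test against the limit of decision.
#
# The null is non-zero (H0: theta <= theta0), so the test is calibrated with
# a studentized pivot T = (theta_hat - theta)/S whose bootstrap distribution
# is simulated by an outer resampling loop, each replicate carrying its own
# inner-bootstrap standard error ("embedded bootstrap").

# theta for sorted inputs; fast order-statistic path when all sizes agree.
.theta_sorted <- function(xs, ys, zs) {
  n <- length(zs)
  if (length(xs) == n && length(ys) == n)
    (sum(abs(xs - zs)) - sum(abs(ys - zs))) / sum(zs)
  else
    (emd_general(xs, zs) - emd_general(ys, zs)) / sum(zs)
}

#' Test statistic: TEST signal minus CTRL signal
#'
#' \eqn{\theta(X, Y, Z)} is the mass response of the drug-treated sample
#' \eqn{X} against the reference \eqn{Z}, minus the mass response of the
#' vehicle-treated control \eqn{Y} against the same reference. The second
#' term captures phenotypic drift over the measurement session and the
#' finite-sample noise floor, so \eqn{\theta} may be negative.
#'
#' @param x drug-treated sample (masses or [condition_sample()]).
#' @param y vehicle-treated control sample (measured last).
#' @param z vehicle-treated reference sample (measured first).
#' @return \eqn{\theta} as a unitless fraction.
#' @export
theta_stat <- function(x, y, z) {
  .theta_sorted(as_masses(x), as_masses(y), as_masses(z))
}

#' BCa bootstrap confidence interval for the mass response
#'
#' Resamples `x` and `z` independently with replacement (sizes preserved),
#' recomputes the mass response for each replicate, and forms the
#' bias-corrected and accelerated interval: the bias correction comes from
#' the fraction of replicates below the point estimate, the acceleration
#' from the skewness of combined delete-one jackknife values over both
#' samples.
#'
#' @param x,z treated and reference samples.
#' @param level confidence level (default 0.90).
#' @param R_ci bootstrap replicates (default 5000; at least 1000
#'   recommended).
#' @param method `"bca"` (default) or `"percentile"`.
#' @param seed integer seed.
#' @return Named numeric `c(ci_low, ci_high)`. When resampling is degenerate
#'   (all replicates identical) the zero-width interval at the point
#'   estimate is returned with attribute `degenerate = TRUE`.
#' @export
bca_ci <- function(x, z, level = 0.90, R_ci = 5000,
                   method = c("bca", "percentile"), seed = NULL) {
  method <- match.arg(method)
  xs <- as_masses(x); zs <- as_masses(z)
  if (length(xs) < 1 || length(zs) < 1) stop("empty sample")
  est <- if (length(xs) == length(zs)) .mr_sorted(xs, zs)
         else emd_general(xs, zs) / sum(zs)
  alpha <- (1 - level) / 2

  kernel_seed <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 1))
  boots <- .cpp_mr_boot(xs, zs, as.integer(R_ci), kernel_seed)

  if (max(boots) - min(boots) < .Machine$double.eps * 16) {
    out <- c(ci_low = est, ci_high = est)
    attr(out, "degenerate") <- TRUE
    out
  } else if (method == "percentile") {
    q <- unname(quantile(boots, c(alpha, 1 - alpha), type = 6))
    c(ci_low = q[1], ci_high = q[2])
  } else {
    # bias correction: fraction of replicates below the point estimate
    prop <- (sum(boots < est) + 0.5 * sum(boots == est)) / R_ci
    prop <- min(max(prop, 1 / (R_ci + 1)), R_ci / (R_ci + 1))
    z0 <- qnorm(prop)

    # acceleration: combined delete-one jackknife over both samples
    jack <- c(
      vapply(seq_along(xs), function(i)
        emd_general(xs[-i], zs) / sum(zs), numeric(1)),
      vapply(seq_along(zs), function(i) {
        zi <- zs[-i]
        emd_general(xs, zi) / sum(zi)
      }, numeric(1)))
    u <- mean(jack) - jack
    denom <- sum(u^2)^1.5
    a <- if (denom > 0) sum(u^3) / (6 * denom) else 0

    zl <- qnorm(alpha); zu <- qnorm(1 - alpha)
    a1 <- pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
    a2 <- pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
    q <- unname(quantile(boots, c(a1, a2), type = 6))
    c(ci_low = q[1], ci_high = q[2])
  }
}

# mass response for two sorted vectors of possibly different lengths
.mr_sorted_pair <- function(xs, zs) {
  if (length(xs) == length(zs)) .mr_sorted(xs, zs)
  else emd_general(xs, zs) / sum(zs)
}

#' Embedded bootstrap-t test of mass response against the limit of decision
#'
#' Tests the one-sided null hypothesis \eqn{H_0: \theta \le \theta_0} where
#' \eqn{\theta} is the TEST-minus-CTRL signal difference and \eqn{\theta_0}
#' the limit of decision (default 3%). Because the null is non-zero, a
#' studentized pivot is used: \eqn{t_{obs} = (\hat\theta - \theta_0)/S} with
#' \eqn{S} the inner-bootstrap standard error of \eqn{\hat\theta}, compared
#' against the bootstrap distribution
#' \eqn{T^* = (\hat\theta^* - \hat\theta)/S^*} in which every outer
#' replicate carries its own inner-bootstrap standard error. The p-value is
#' \eqn{(1 + \#\{T^* \ge t_{obs}\}) / (1 + R)}, so with \eqn{R = 999} the
#' smallest attainable p-value is 0.001.
#'
#' Samples larger than `cfg$N` are first subsampled to `N` cells without
#' replacement (seeded); smaller samples are used whole and flagged when
#' below `cfg$min_n`. Resampling is cell-wise within each of X, Y, Z
#' independently, preserving sizes. Each outer replicate runs under its own
#' seed spawned from the master seed, so results do not depend on execution
#' order. An outer replicate whose inner resamples are degenerate
#' (\eqn{S^* = 0}) contributes \eqn{T^* = \pm\infty} by the sign of its
#' numerator (0 when the numerator is 0).
#'
#' @param x drug-treated sample; @param y vehicle-treated control;
#'   @param z vehicle-treated reference (masses or [condition_sample()]s).
#' @param cfg an [inference_config()].
#' @param condition_id label carried into the result.
#' @param seed master seed (defaults to `cfg$seed`).
#' @return An object of class `test_result` with elements `condition_id`,
#'   `test_signal`, `ctrl_signal`, `theta_hat`, `se_hat`, `t_obs`,
#'   `p_value`, `call` (set by [call_response()]), `n_used`, `low_n`,
#'   `seed`.
#' @export
bootstrap_t_test <- function(x, y, z, cfg = inference_config(),
                             condition_id = "test", seed = cfg$seed) {
  xs <- as_masses(x); ys <- as_masses(y); zs <- as_masses(z)
  if (length(xs) == 0 || length(ys) == 0 || length(zs) == 0)
    stop("empty sample passed to bootstrap_t_test")

  seeds <- spawn_seeds(seed %||% sample.int(.Machine$integer.max - 1L, 1),
                       cfg$R_test + 2L)

  # fixed-N convention: subsample large samples once, seeded
  sub <- function(v, s) {
    if (length(v) > cfg$N) with_seed(s, sort(v[sample.int(length(v), cfg$N)]))
    else v
  }
  xs <- sub(xs, seeds[1]); ys <- sub(ys, seeds[1]); zs <- sub(zs, seeds[1])
  low_n <- min(length(xs), length(ys), length(zs)) < cfg$min_n

  test_signal <- .mr_sorted_pair(xs, zs)
  ctrl_signal <- .mr_sorted_pair(ys, zs)
  theta_hat <- test_signal - ctrl_signal

  se_hat <- .cpp_inner_se(xs, ys, zs, cfg$r_inner, seeds[2])
  if (!is.finite(se_hat) || se_hat == 0)
    stop("degenerate inner bootstrap: zero-variance standard error ",
         "(are the samples constant?)")
  t_obs <- (theta_hat - cfg$theta0) / se_hat

  t_star <- vapply(seq_len(cfg$R_test), function(b) {
    .cpp_tstar(xs, ys, zs, theta_hat, cfg$r_inner, seeds[2 + b])
  }, numeric(1))

  p_value <- (1 + sum(t_star >= t_obs)) / (1 + cfg$R_test)

  res <- structure(list(condition_id = condition_id,
                        test_signal = test_signal,
                        ctrl_signal = ctrl_signal,
                        theta_hat = theta_hat,
                        se_hat = se_hat,
                        t_obs = t_obs,
                        p_value = p_value,
                        call = NA_character_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        ci_level = NA_real_,
                        n_used = c(x = length(xs), y = length(ys),
                                   z = length(zs)),
                        low_n = low_n,
                        seed = if (is.null(seed)) NA_integer_
                               else as.integer(seed)),
                   class = "test_result")
  call_response(res, cfg)
}

#' Turn a test result into a response call
#'
#' The decision rule: if the CTRL signal (reference-to-control distance)
#' exceeds the drift limit (default 10%), phenotypic drift is too high and
#' the call is `inconclusive` regardless of the p-value; otherwise the call
#' is `response` when `p_value < alpha` and `no_response` otherwise.
#'
#' @param result a `test_result`.
#' @param cfg an [inference_config()].
#' @return The `test_result` with `call` set.
#' @export
call_response <- function(result, cfg = inference_config()) {
  stopifnot(inherits(result, "test_result"))
  result$call <-
    if (result$ctrl_signal > cfg$drift_limit) "inconclusive"
    else if (result$p_value < cfg$alpha) "response"
    else "no_response"
  result
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s\n", x$condition_id))
  cat(sprintf("  TEST %.2f%%  CTRL %.2f%%  theta %.2f%%  (SE %.2f%%)\n",
              100 * x$test_signal, 100 * x$ctrl_signal, 100 * x$theta_hat,
              100 * x$se_hat))
  if (!is.na(x$ci_low))
    cat(sprintf("  %.0f%% CI of TEST signal: [%.2f%%, %.2f%%]\n",
                100 * x$ci_level, 100 * x$ci_low, 100 * x$ci_high))
  cat(sprintf("  t_obs %.2f  p %.4g  call: %s%s\n",
              x$t_obs, x$p_value, x$call,
              if (isTRUE(x$low_n)) " [low n]" else ""))
  invisible(x)
}

#' @export
as.data.frame.test_result <- function(x, ...) {
  data.frame(condition_id = x$condition_id,
             test_signal = x$test_signal,
             ctrl_signal = x$ctrl_signal,
             theta_hat = x$theta_hat,
             se_hat = x$se_hat,
             t_obs = x$t_obs,
             p_value = x$p_value,
             call = x$call,
             ci_low = x$ci_low,
             ci_high = x$ci_high,
             ci_level = x$ci_level,
             n_x = unname(x$n_used["x"]),
             n_y = unname(x$n_used["y"]),
             n_z = unname(x$n_used["z"]),
             low_n = x$low_n,
             seed = x$seed,
             stringsAsFactors = FALSE)
}
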