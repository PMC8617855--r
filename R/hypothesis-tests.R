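# Z1 (one-sided non-inferiority) and Z2 (two-sided) concordance tests.

#' Empirical variance components for Objective 1
#'
#' Divide-by-n empirical variances of the per-subject concordance scores,
#' the consistent estimators of the asymptotic variances of
#' `sqrt(n) (p^r - pr)` and `sqrt(n) (p^s - ps)`.
#'
#' @param data `concordance_data1` object with at least 2 subjects.
#' @return named vector `c(sigma_r_sq, sigma_s_sq)`.
#' @export
variance_components_obj1 <- function(data) {
  stopifnot(inherits(data, "concordance_data1"))
  if (data$n < 2L) stop("need at least n = 2 subjects", call. = FALSE)
  c(sigma_r_sq = mean((data$r_i - mean(data$r_i))^2),
    sigma_s_sq = mean((data$s_i - mean(data$s_i))^2))
}

.check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 0.5) {
    stop("alpha must be a single value in (0, 0.5)", call. = FALSE)
  }
}

#' Objective-1 non-inferiority test of device-radiologist concordance
#'
#' Tests `H1: ps <= pr - delta1` against `H1bar: ps > pr - delta1`, where
#' `pr` is the concordance rate among radiologists, `ps` the rate between
#' the device and radiologists, and `delta1 > 0` the similarity margin.
#' The statistic is
#' \deqn{Z_1 = \sqrt{n}\,(\hat p_s - \hat p_r + \delta_1)/\hat\sigma_1,}
#' rejecting when `Z1 > qnorm(1 - alpha)` (one-sided upper).  Two variance
#' estimators are available:
#' * `"null_anchored"` (default, the form whose operating characteristics
#'   the package's simulations target):
#'   `sigma1^2 = mean((s_i - r_i + delta1)^2)`, anchored at the null
#'   boundary `ps = pr - delta1`;
#' * `"gee_robust"`: the centered GEE sandwich estimator
#'   `mean(((s_i - r_i) - (p^s - p^r))^2)` under working independence,
#'   asymptotically identical to the null-anchored form under `H1`.
#'
#' @param data `concordance_data1` object, n >= 2.
#' @param delta1 similarity margin, > 0.
#' @param alpha one-sided level in (0, 0.5).
#' @param variance_flavor `"null_anchored"` or `"gee_robust"`.
#' @return object of class `concord_test`: statistic, p-value, critical
#'   value, reject flag, estimates and the variance used.
#' @examples
#' d <- concordance_data1(
#'   r_indicators = matrix(c(1, 0, 1, 0, 1, 1, 0, 1, 0, 0, 1, 1), 4, 3),
#'   s_indicators = matrix(c(1, 1, 0, 1, 0, 1, 1, 0, 1, 0, 1, 1), 4, 3)
#' )
#' test_objective1(d, delta1 = 0.1)
#' @export
test_objective1 <- function(data, delta1, alpha = 0.05,
                            variance_flavor = c("null_anchored", "gee_robust")) {
  stopifnot(inherits(data, "concordance_data1"))
  variance_flavor <- match.arg(variance_flavor)
  .check_alpha(alpha)
  if (!is.numeric(delta1) || length(delta1) != 1L || delta1 <= 0) {
    stop("similarity margin delta1 must be a single positive value", call. = FALSE)
  }
  if (data$n < 2L) stop("need at least n = 2 subjects", call. = FALSE)
  n <- data$n
  d0 <- data$s_i - data$r_i
  ps_hat <- mean(data$s_i)
  pr_hat <- mean(data$r_i)
  v <- switch(variance_flavor,
    null_anchored = mean((d0 + delta1)^2),
    gee_robust = mean((d0 - (ps_hat - pr_hat))^2)
  )
  if (v <= 0) {
    stop("degenerate variance: all s_i - r_i identical and equal to -delta1",
         call. = FALSE)
  }
  z <- sqrt(n) * (ps_hat - pr_hat + delta1) / sqrt(v)
  crit <- qnorm(1 - alpha)
  structure(
    list(objective = 1L, statistic = z, sidedness = "one_sided_upper",
         alpha = alpha, critical_value = crit, reject = z > crit,
         p_value = pnorm(z, lower.tail = FALSE),
         estimates = list(ps = ps_hat, pr = pr_hat, delta1 = delta1),
         variance_estimate = v, variance_flavor = variance_flavor, n = n),
    class = "concord_test"
  )
}

#' Objective-2 test comparing device concordance across experience groups
#'
#' Tests `H2: px = py` (device equally concordant with senior and junior
#' radiologists) with the two-sided statistic
#' \deqn{Z_2 = \sqrt{n}\,(\hat p_x - \hat p_y)/\hat\sigma_2,\qquad
#'       \hat\sigma_2^2 = n^{-1}\sum_i (x_i - y_i)^2,}
#' rejecting when `|Z2| > qnorm(1 - alpha/2)`.
#'
#' @param data `concordance_data2` object, n >= 2.
#' @param alpha two-sided level in (0, 0.5).
#' @return object of class `concord_test`.
#' @export
test_objective2 <- function(data, alpha = 0.05) {
  stopifnot(inherits(data, "concordance_data2"))
  .check_alpha(alpha)
  if (data$n < 2L) stop("need at least n = 2 subjects", call. = FALSE)
  n <- data$n
  d0 <- data$x_i - data$y_i
  v <- mean(d0^2)
  if (v <= 0) {
    stop("degenerate variance: x_i and y_i are identical for every subject",
         call. = FALSE)
  }
  z <- sqrt(n) * mean(d0) / sqrt(v)
  crit <- qnorm(1 - alpha / 2)
  structure(
    list(objective = 2L, statistic = z, sidedness = "two_sided",
         alpha = alpha, critical_value = crit, reject = abs(z) > crit,
         p_value = 2 * pnorm(abs(z), lower.tail = FALSE),
         estimates = list(px = mean(data$x_i), py = mean(data$y_i)),
         variance_estimate = v, variance_flavor = "null_anchored", n = n),
    class = "concord_test"
  )
}

#' @export
print.concord_test <- function(x, ...) {
  lab <- if (x$objective == 1L) "Z1 (one-sided non-inferiority)" else "Z2 (two-sided)"
  cat(sprintf("Concordance test, Objective %d: %s\n", x$objective, lab))
  cat(sprintf("  n = %d, statistic = %.5f, critical value = %.5f (alpha = %g)\n",
              x$n, x$statistic, x$critical_value, x$alpha))
  est <- unlist(x$estimates)
  cat("  estimates:", paste(sprintf("%s = %.4f", names(est), est), collapse = ", "), "\n")
  cat(sprintf("  variance (%s) = %.6f, p-value = %.5f\n",
              x$variance_flavor, x$variance_estimate, x$p_value))
  cat(sprintf("  decision: %s\n", if (x$reject) "reject null" else "do not reject null"))
  invisible(x)
}

#' Serialize a test result to JSON
#'
#' @param result `concord_test` object.
#' @param ... passed to [jsonlite::toJSON()].
#' @return JSON string.
#' @export
test_result_json <- function(result, ...) {
  stopifnot(inherits(result, "concord_test"))
  jsonlite::toJSON(
    list(objective = result$objective, statistic = result$statistic,
         p_value = result$p_value, alpha = result$alpha,
         sidedness = result$sidedness, reject = result$reject,
         estimates = result$estimates,
         variance_estimate = result$variance_estimate,
         variance_flavor = result$variance_flavor, n = result$n),
    auto_unbox = TRUE, digits = NA, ...
  )
}
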