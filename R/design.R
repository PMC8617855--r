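# Asymptotic variances, power functions and sample-size formulas for the
# two study objectives.

.resolve_components1 <- function(m, components, rho1, offsets) {
  if (!is.null(components) && !is.null(rho1)) {
    warning("both components and rho1 given; components take precedence")
    rho1 <- NULL
  }
  if (is.null(components)) {
    if (is.null(rho1)) stop("give either components or rho1", call. = FALSE)
    components <- solve_components_obj1(rho1, m = m, offsets = offsets)
  }
  stopifnot(inherits(components, "component_correlations1"))
  if (components$m != m) {
    stop(sprintf("components were built for m = %d, design requests m = %d",
                 components$m, m), call. = FALSE)
  }
  components
}

.resolve_components2 <- function(m, components, rho2, offset) {
  if (!is.null(components) && !is.null(rho2)) {
    warning("both components and rho2 given; components take precedence")
    rho2 <- NULL
  }
  if (is.null(components)) {
    if (is.null(rho2)) stop("give either components or rho2", call. = FALSE)
    components <- solve_components_obj2(rho2, m = m, offset = offset)
  }
  stopifnot(inherits(components, "component_correlations2"))
  if (components$m != m) {
    stop(sprintf("components were built for m = %d, design requests m = %d",
                 components$m, m), call. = FALSE)
  }
  components
}

.check_power <- function(power) {
  if (!is.numeric(power) || length(power) != 1L || power <= 0.5 || power >= 1) {
    stop("target power must lie in (0.5, 1)", call. = FALSE)
  }
}

#' Objective-1 design specification
#'
#' Collects the parameters of an Objective-1 non-inferiority design: the
#' one-sided level, target power, number of radiologists, anticipated
#' radiologist-radiologist concordance rate `pr`, similarity margin
#' `delta1`, and the indicator correlation structure.  Sample size is
#' computed under the alternative `ps = pr`.  The correlation structure
#' may be supplied as explicit [component_correlations1()] or as a scalar
#' `rho1` target, in which case components are solved with
#' [solve_components_obj1()] under `offsets`; if both are given the
#' components win and the implied `rho1` is reported.
#'
#' @param m number of radiologists (>= 2).
#' @param pr anticipated concordance rate among radiologists, in (0, 1).
#' @param delta1 similarity margin, 0 < delta1 < pr.
#' @param alpha one-sided level in (0, 0.5).
#' @param power target power in (0.5, 1).
#' @param components optional [component_correlations1()].
#' @param rho1 optional scalar compound correlation target.
#' @param offsets offsets for [solve_components_obj1()] when solving from
#'   `rho1`.
#' @return object of class `design1_spec`.
#' @examples
#' spec <- design1_spec(m = 10, pr = 0.3, delta1 = 0.05, rho1 = 0.1)
#' samplesize_objective1(spec)  # 210
#' @export
design1_spec <- function(m, pr, delta1, alpha = 0.05, power = 0.8,
                         components = NULL, rho1 = NULL,
                         offsets = c(0.1, 0.1, 0.1)) {
  .check_alpha(alpha)
  .check_power(power)
  if (!is.numeric(pr) || pr <= 0 || pr >= 1) {
    stop("pr must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(delta1) || delta1 <= 0 || delta1 >= pr) {
    stop("similarity margin delta1 must satisfy 0 < delta1 < pr", call. = FALSE)
  }
  components <- .resolve_components1(m, components, rho1, offsets)
  structure(
    list(m = as.integer(m), pr = pr, delta1 = delta1, alpha = alpha,
         power = power, components = components,
         rho1 = rho1_from_components(components)),
    class = "design1_spec"
  )
}

#' Objective-2 design specification
#'
#' Parameters of an Objective-2 comparison design: two-sided level, target
#' power, radiologists per experience group, anticipated device-senior
#' concordance rate `px`, difference `delta2 = px - py` under the
#' alternative, and the correlation structure (explicit
#' [component_correlations2()] or scalar `rho2` solved under the offset
#' constraint).
#'
#' @param m radiologists per experience group (>= 2).
#' @param px anticipated device-senior concordance rate, in (0, 1).
#' @param delta2 anticipated difference px - py, 0 < delta2 < px.
#' @param alpha two-sided level in (0, 0.5).
#' @param power target power in (0.5, 1).
#' @param components optional [component_correlations2()].
#' @param rho2 optional scalar compound correlation target.
#' @param offset offset for [solve_components_obj2()].
#' @return object of class `design2_spec`.
#' @examples
#' spec <- design2_spec(m = 5, px = 0.3, delta2 = 0.05, rho2 = 0.1)
#' samplesize_objective2(spec)  # 348
#' @export
design2_spec <- function(m, px, delta2, alpha = 0.05, power = 0.8,
                         components = NULL, rho2 = NULL, offset = 0.1) {
  .check_alpha(alpha)
  .check_power(power)
  if (!is.numeric(px) || px <= 0 || px >= 1) {
    stop("px must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(delta2) || delta2 <= 0 || delta2 >= px) {
    stop("delta2 must satisfy 0 < delta2 < px", call. = FALSE)
  }
  components <- .resolve_components2(m, components, rho2, offset)
  structure(
    list(m = as.integer(m), px = px, delta2 = delta2, alpha = alpha,
         power = power, components = components,
         rho2 = rho2_from_components(components)),
    class = "design2_spec"
  )
}

#' @export
print.design1_spec <- function(x, ...) {
  cat(sprintf(paste0("Objective-1 design: m = %d, pr = %g, delta1 = %g, ",
                     "alpha = %g (one-sided), power = %g, rho1 = %.4f\n"),
              x$m, x$pr, x$delta1, x$alpha, x$power, x$rho1))
  invisible(x)
}

#' @export
print.design2_spec <- function(x, ...) {
  cat(sprintf(paste0("Objective-2 design: m = %d per group, px = %g, delta2 = %g, ",
                     "alpha = %g (two-sided), power = %g, rho2 = %.4f\n"),
              x$m, x$px, x$delta2, x$alpha, x$power, x$rho2))
  invisible(x)
}

#' Asymptotic variance of sqrt(n) (p^s - p^r) under ps = pr
#'
#' \deqn{\sigma_1^2 = \mathrm{var}(s_i) + \mathrm{var}(r_i)
#'   - 2\rho_1\sqrt{\mathrm{var}(s_i)\,\mathrm{var}(r_i)}}
#' with `var(s_i) = pr(1-pr)[1/m + (m-1) rho_ss / m]` and
#' `var(r_i) = pr(1-pr)[2/(m(m-1)) + 4(m-2) rho_r1/(m(m-1)) +
#' (m-2)(m-3) rho_r2/(m(m-1))]`.
#'
#' @param spec [design1_spec()] object.
#' @return the variance `sigma1^2`.
#' @export
sigma1_sq <- function(spec) {
  stopifnot(inherits(spec, "design1_spec"))
  comp <- spec$components
  m <- spec$m
  bern <- spec$pr * (1 - spec$pr)
  var_s <- bern * .score_factor_s(m, comp$rho_ss)
  var_r <- bern * .score_factor_r(m, comp$rho_r1, comp$rho_r2)
  out <- var_s + var_r - 2 * spec$rho1 * sqrt(var_s * var_r)
  if (out < 0) {
    stop(sprintf("negative variance (%.4g): infeasible correlation structure", out),
         call. = FALSE)
  }
  out
}

#' Asymptotic variance of sqrt(n) (p^x - p^y - delta2) under the
#' alternative px = py + delta2
#'
#' \deqn{\sigma_2^2 = \mathrm{var}(x_i) + \mathrm{var}(y_i)
#'   - 2\rho_2\sqrt{\mathrm{var}(x_i)\,\mathrm{var}(y_i)}}
#' with `var(x_i) = px(1-px)[1/m + (m-1) rho_xx / m]` and
#' `var(y_i) = (px-delta2)(1-px+delta2)[1/m + (m-1) rho_yy / m]`.
#'
#' @param spec [design2_spec()] object.
#' @return the variance `sigma2^2`.
#' @export
sigma2_sq <- function(spec) {
  stopifnot(inherits(spec, "design2_spec"))
  comp <- spec$components
  m <- spec$m
  py <- spec$px - spec$delta2
  var_x <- spec$px * (1 - spec$px) * .score_factor_s(m, comp$rho_xx)
  var_y <- py * (1 - py) * .score_factor_s(m, comp$rho_yy)
  out <- var_x + var_y - 2 * spec$rho2 * sqrt(var_x * var_y)
  if (out < 0) {
    stop(sprintf("negative variance (%.4g): infeasible correlation structure", out),
         call. = FALSE)
  }
  out
}

# shared power kernel: survivor function of the standard normal evaluated
# at (z_crit * sqrt(sigma^2 + delta^2) - sqrt(n) delta) / sigma
.power_kernel <- function(n, z_crit, sigma_sq, delta) {
  pnorm((z_crit * sqrt(sigma_sq + delta^2) - sqrt(n) * delta) / sqrt(sigma_sq),
        lower.tail = FALSE)
}

.samplesize_kernel <- function(z_crit, z_beta, sigma_sq, delta) {
  ((z_crit * sqrt(sigma_sq + delta^2) + z_beta * sqrt(sigma_sq)) / delta)^2
}

#' Power of the Objective-1 test at sample size n
#'
#' Evaluates the asymptotic power of the one-sided `Z1` test under the
#' alternative `ps = pr`:
#' \deqn{1-\beta = \bar\Phi\!\left(\frac{z_{1-\alpha}
#'   \sqrt{\sigma_1^2+\delta_1^2} - \sqrt{n}\,\delta_1}{\sigma_1}\right).}
#'
#' @param n sample size (>= 1; non-integer values are allowed, which makes
#'   the function the exact inverse of the sample-size formula).
#' @param spec [design1_spec()] object.
#' @return power in (0, 1).
#' @export
power_objective1 <- function(n, spec) {
  stopifnot(inherits(spec, "design1_spec"))
  if (any(n < 1)) stop("n must be at least 1", call. = FALSE)
  .power_kernel(n, qnorm(1 - spec$alpha), sigma1_sq(spec), spec$delta1)
}

#' Required sample size for the Objective-1 test
#'
#' Inverts the power function at the target power:
#' \deqn{n = \left(\frac{z_{1-\alpha}\sqrt{\sigma_1^2+\delta_1^2}
#'   + z_{1-\beta}\,\sigma_1}{\delta_1}\right)^{\!2},}
#' rounded up to the next integer.  The unrounded value is attached as
#' attribute `n_exact`.
#'
#' @param spec [design1_spec()] object.
#' @return integer sample size with attribute `n_exact`.
#' @export
samplesize_objective1 <- function(spec) {
  stopifnot(inherits(spec, "design1_spec"))
  n_exact <- .samplesize_kernel(qnorm(1 - spec$alpha), qnorm(spec$power),
                                sigma1_sq(spec), spec$delta1)
  structure(as.integer(ceiling(n_exact - 1e-9)), n_exact = n_exact)
}

#' Power of the Objective-2 test at sample size n
#'
#' Asymptotic power of the two-sided `Z2` test under the alternative
#' `px = py + delta2`, using the two-sided critical value and neglecting
#' the far-tail rejection probability:
#' \deqn{1-\beta = \bar\Phi\!\left(\frac{z_{1-\alpha/2}
#'   \sqrt{\sigma_2^2+\delta_2^2} - \sqrt{n}\,\delta_2}{\sigma_2}\right).}
#'
#' @inheritParams power_objective1
#' @param spec [design2_spec()] object.
#' @return power in (0, 1).
#' @export
power_objective2 <- function(n, spec) {
  stopifnot(inherits(spec, "design2_spec"))
  if (any(n < 1)) stop("n must be at least 1", call. = FALSE)
  .power_kernel(n, qnorm(1 - spec$alpha / 2), sigma2_sq(spec), spec$delta2)
}

#' Required sample size for the Objective-2 test
#'
#' \deqn{n = \left(\frac{z_{1-\alpha/2}\sqrt{\sigma_2^2+\delta_2^2}
#'   + z_{1-\beta}\,\sigma_2}{\delta_2}\right)^{\!2},}
#' rounded up; the unrounded value is attached as attribute `n_exact`.
#'
#' @param spec [design2_spec()] object.
#' @return integer sample size with attribute `n_exact`.
#' @export
samplesize_objective2 <- function(spec) {
  stopifnot(inherits(spec, "design2_spec"))
  n_exact <- .samplesize_kernel(qnorm(1 - spec$alpha / 2), qnorm(spec$power),
                                sigma2_sq(spec), spec$delta2)
  structure(as.integer(ceiling(n_exact - 1e-9)), n_exact = n_exact)
}
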