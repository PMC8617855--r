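# Compound correlation algebra: from pairwise indicator correlations to
# the correlation between per-subject concordance scores, and back.

#' Objective-1 component correlations
#'
#' The five pairwise correlations among Objective-1 concordance
#' indicators, classified by how many readers the indicator pair shares:
#' * `rho_r1 = corr(r_i12, r_i13)`: radiologist pairs sharing one reader;
#' * `rho_r2 = corr(r_i12, r_i34)`: disjoint radiologist pairs;
#' * `rho_s1 = corr(r_i12, s_i1)`: pair and device score sharing a reader;
#' * `rho_s2 = corr(r_i12, s_i3)`: pair and device score, no shared reader;
#' * `rho_ss = corr(s_i1, s_i2)`: two device-radiologist scores.
#'
#' @param m number of radiologists (>= 2).
#' @param rho_r1,rho_r2,rho_s1,rho_s2,rho_ss component correlations in
#'   (-1, 1).
#' @return object of class `component_correlations1`.
#' @export
component_correlations1 <- function(m, rho_r1, rho_r2, rho_s1, rho_s2, rho_ss) {
  m <- as.integer(m)
  if (is.na(m) || m < 2L) stop("need m >= 2 radiologists", call. = FALSE)
  vals <- c(rho_r1 = rho_r1, rho_r2 = rho_r2, rho_s1 = rho_s1,
            rho_s2 = rho_s2, rho_ss = rho_ss)
  if (any(!is.finite(vals)) || any(abs(vals) >= 1)) {
    bad <- names(vals)[!is.finite(vals) | abs(vals) >= 1][1]
    stop(sprintf("component correlation %s must lie in (-1, 1)", bad),
         call. = FALSE)
  }
  structure(c(list(m = m), as.list(vals)), class = "component_correlations1")
}

#' Objective-2 component correlations
#'
#' * `rho_xx = corr(x_i1, x_i2)`: two device-senior scores;
#' * `rho_yy = corr(y_i1, y_i2)`: two device-junior scores;
#' * `rho_xy = corr(x_ij, y_ij')`: one of each.
#'
#' @param m radiologists per experience group (>= 2).
#' @param rho_xx,rho_yy,rho_xy component correlations in (-1, 1).
#' @return object of class `component_correlations2`.
#' @export
component_correlations2 <- function(m, rho_xx, rho_yy, rho_xy) {
  m <- as.integer(m)
  if (is.na(m) || m < 2L) stop("need m >= 2 per group", call. = FALSE)
  vals <- c(rho_xx = rho_xx, rho_yy = rho_yy, rho_xy = rho_xy)
  if (any(!is.finite(vals)) || any(abs(vals) >= 1)) {
    bad <- names(vals)[!is.finite(vals) | abs(vals) >= 1][1]
    stop(sprintf("component correlation %s must lie in (-1, 1)", bad),
         call. = FALSE)
  }
  structure(c(list(m = m), as.list(vals)), class = "component_correlations2")
}

#' @export
print.component_correlations1 <- function(x, ...) {
  cat(sprintf("Objective-1 component correlations (m = %d):\n", x$m))
  cat(sprintf("  rho_r1 = %.6f, rho_r2 = %.6f, rho_s1 = %.6f, rho_s2 = %.6f, rho_ss = %.6f\n",
              x$rho_r1, x$rho_r2, x$rho_s1, x$rho_s2, x$rho_ss))
  cat(sprintf("  implied rho1 = corr(r_i, s_i) = %.6f\n", rho1_from_components(x)))
  invisible(x)
}

#' @export
print.component_correlations2 <- function(x, ...) {
  cat(sprintf("Objective-2 component correlations (m = %d per group):\n", x$m))
  cat(sprintf("  rho_xx = %.6f, rho_yy = %.6f, rho_xy = %.6f\n",
              x$rho_xx, x$rho_yy, x$rho_xy))
  cat(sprintf("  implied rho2 = corr(x_i, y_i) = %.6f\n", rho2_from_components(x)))
  invisible(x)
}

# variance inflation factors of the per-subject means, relative to the
# Bernoulli variance of a single indicator:
#   var(s_i) = p(1-p) * .score_factor_s ; var(r_i) = p(1-p) * .score_factor_r
.score_factor_s <- function(m, rho_ss) 1 / m + (m - 1) * rho_ss / m

.score_factor_r <- function(m, rho_r1, rho_r2) {
  2 / (m * (m - 1)) + 4 * (m - 2) * rho_r1 / (m * (m - 1)) +
    (m - 2) * (m - 3) * rho_r2 / (m * (m - 1))
}

#' Compound correlation rho1 between r_i and s_i
#'
#' Correlation between the per-subject radiologist-radiologist score `r_i`
#' and device-radiologist score `s_i` implied by the five component
#' correlations:
#' \deqn{\rho_1 = \frac{(2/m)\rho_{s1} + ((m-2)/m)\rho_{s2}}
#'   {\sqrt{\left[\frac{2}{m(m-1)} + \frac{4(m-2)}{m(m-1)}\rho_{r1}
#'     + \frac{(m-2)(m-3)}{m(m-1)}\rho_{r2}\right]
#'     \left[\frac1m + \frac{m-1}{m}\rho_{ss}\right]}}.}
#'
#' @param components [component_correlations1()] object.
#' @return the implied `rho1 = corr(r_i, s_i)`.
#' @examples
#' comp <- component_correlations1(10, 0.201, 0.101, 0.101, 0.001, 0.201)
#' rho1_from_components(comp)  # ~0.100
#' @export
rho1_from_components <- function(components) {
  stopifnot(inherits(components, "component_correlations1"))
  m <- components$m
  fr <- .score_factor_r(m, components$rho_r1, components$rho_r2)
  fs <- .score_factor_s(m, components$rho_ss)
  if (fr <= 0 || fs <= 0) {
    stop(sprintf(paste0("infeasible components: variance factors must be positive ",
                        "(r-factor = %.6g, s-factor = %.6g)"), fr, fs),
         call. = FALSE)
  }
  ((2 / m) * components$rho_s1 + ((m - 2) / m) * components$rho_s2) / sqrt(fr * fs)
}

#' Compound correlation rho2 between x_i and y_i
#'
#' Correlation between the per-subject device-senior score `x_i` and
#' device-junior score `y_i`:
#' \deqn{\rho_2 = \frac{\rho_{xy}}
#'   {\sqrt{\left[\frac1m + \frac{m-1}{m}\rho_{xx}\right]
#'          \left[\frac1m + \frac{m-1}{m}\rho_{yy}\right]}}.}
#' The form follows from `cov(x_i, y_i) = rho_xy * sd(x_ij) * sd(y_ij)`
#' (all m^2 cross terms share the same correlation) divided by the
#' standard deviations of the two score means; the marginal Bernoulli
#' factors cancel.  It is validated in the test suite against a
#' Monte-Carlo oracle and the printed design tuples.
#'
#' @param components [component_correlations2()] object.
#' @return the implied `rho2 = corr(x_i, y_i)`.
#' @examples
#' rho2_from_components(component_correlations2(5, 0.13, 0.13, 0.03))  # ~0.099
#' @export
rho2_from_components <- function(components) {
  stopifnot(inherits(components, "component_correlations2"))
  m <- components$m
  fx <- .score_factor_s(m, components$rho_xx)
  fy <- .score_factor_s(m, components$rho_yy)
  if (fx <= 0 || fy <= 0) {
    stop(sprintf(paste0("infeasible components: variance factors must be positive ",
                        "(x-factor = %.6g, y-factor = %.6g)"), fx, fy),
         call. = FALSE)
  }
  components$rho_xy / sqrt(fx * fy)
}

# components as a function of the free parameter t = rho_s2 under the
# offset constraints; offsets = c(s1_minus_s2, r1_minus_r2, ss_minus_s1)
.components1_from_free <- function(t, m, offsets) {
  rho_s2 <- t
  rho_s1 <- t + offsets[1]
  rho_ss <- rho_s1 + offsets[3]
  rho_r1 <- rho_ss             # constraint: rho_r1 = rho_ss
  rho_r2 <- rho_r1 - offsets[2]
  component_correlations1(m, rho_r1, rho_r2, rho_s1, rho_s2, rho_ss)
}

#' Solve Objective-1 component correlations from a target rho1
#'
#' Inverts [rho1_from_components()] under the offset constraints used for
#' design calculations: `rho_s1 = rho_s2 + offsets[1]`,
#' `rho_r1 = rho_r2 + offsets[2]`, `rho_ss = rho_r1 = rho_s1 + offsets[3]`
#' (defaults all 0.1).  A bracketed root-find over the free parameter
#' `rho_s2` locates the unique component tuple whose implied compound
#' correlation equals `rho1_target`.
#'
#' @param rho1_target desired `corr(r_i, s_i)`.
#' @param m number of radiologists.
#' @param offsets numeric length-3 vector of offsets
#'   `(rho_s1 - rho_s2, rho_r1 - rho_r2, rho_ss - rho_s1)`.
#' @param tol root-finding tolerance on `rho_s2`.
#' @return [component_correlations1()] object.
#' @examples
#' solve_components_obj1(0.1, m = 10)  # rho_s1 ~ 0.101, rho_s2 ~ 0.001, ...
#' @export
solve_components_obj1 <- function(rho1_target, m = 10,
                                  offsets = c(0.1, 0.1, 0.1), tol = 1e-12) {
  if (length(offsets) != 3L || any(!is.finite(offsets))) {
    stop("offsets must be a finite numeric vector of length 3", call. = FALSE)
  }
  shifts <- c(0, offsets[1], offsets[1] + offsets[3],
              offsets[1] + offsets[3], offsets[1] + offsets[3] - offsets[2])
  eps <- 1e-9
  lo <- -1 - min(shifts) + eps
  hi <- 1 - max(shifts) - eps
  if (lo >= hi) stop("offsets leave no feasible component range", call. = FALSE)
  # vectorized evaluation of the implied rho1 over the free parameter,
  # NA where a variance factor is nonpositive
  g <- function(t) {
    rho_s1 <- t + offsets[1]
    rho_ss <- rho_s1 + offsets[3]
    rho_r1 <- rho_ss
    rho_r2 <- rho_r1 - offsets[2]
    fr <- .score_factor_r(m, rho_r1, rho_r2)
    fs <- .score_factor_s(m, rho_ss)
    bad <- fr <= 0 | fs <= 0
    prod <- fr * fs
    prod[bad] <- 1
    out <- ((2 / m) * rho_s1 + ((m - 2) / m) * t) / sqrt(prod)
    out[bad] <- NA_real_
    out
  }
  grid <- seq(lo, hi, length.out = 1024L)
  vals <- g(grid)
  ok <- which(is.finite(vals))
  if (!length(ok)) stop("no feasible component tuple for these offsets", call. = FALSE)
  f <- vals[ok] - rho1_target
  sgn <- sign(f)
  cross <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
  if (!length(cross)) {
    stop(sprintf(paste0("rho1 target %.4g unattainable under these offsets; ",
                        "attainable range is [%.4f, %.4f]"),
                 rho1_target, min(vals[ok]), max(vals[ok])), call. = FALSE)
  }
  k <- cross[1]
  root <- uniroot(function(t) g(t) - rho1_target,
                  lower = grid[ok[k]], upper = grid[ok[k + 1L]],
                  tol = tol)$root
  .components1_from_free(root, m, offsets)
}

#' Solve Objective-2 component correlations from a target rho2
#'
#' Inverts [rho2_from_components()] under the constraint
#' `rho_xx = rho_yy = rho_xy + offset` (default offset 0.1).  The solution
#' is closed form:
#' \deqn{\rho_{xy} = \frac{\rho_2\,[1/m + \mathrm{offset}\,(m-1)/m]}
#'                        {1 - \rho_2 (m-1)/m}.}
#'
#' @param rho2_target desired `corr(x_i, y_i)`.
#' @param m radiologists per experience group.
#' @param offset `rho_xx - rho_xy`.
#' @return [component_correlations2()] object.
#' @examples
#' solve_components_obj2(0.3, m = 5)  # rho_xy ~ 0.11, rho_xx = rho_yy ~ 0.21
#' @export
solve_components_obj2 <- function(rho2_target, m = 5, offset = 0.1) {
  denom <- 1 - rho2_target * (m - 1) / m
  if (denom <= 0) {
    stop(sprintf("rho2 target %.4g unattainable: requires rho2 < m/(m-1) = %.4f",
                 rho2_target, m / (m - 1)), call. = FALSE)
  }
  rho_xy <- rho2_target * (1 / m + offset * (m - 1) / m) / denom
  rho_xx <- rho_xy + offset
  if (abs(rho_xy) >= 1 || abs(rho_xx) >= 1) {
    stop(sprintf(paste0("solved components outside (-1, 1): rho_xy = %.4f, ",
                        "rho_xx = rho_yy = %.4f"), rho_xy, rho_xx), call. = FALSE)
  }
  component_correlations2(m, rho_xx, rho_xx, rho_xy)
}

#' Estimate component correlations from pilot data
#'
#' Pools empirical Pearson correlations over all indicator column pairs in
#' each structural class (shared-reader radiologist pairs, disjoint pairs,
#' etc.) to estimate the component correlations from observed indicator
#' data, e.g. a pilot or first-stage sample used to (re)compute the final
#' sample size.
#'
#' @param data `concordance_data1` or `concordance_data2` object.
#' @return [component_correlations1()] or [component_correlations2()]
#'   object matching the data's objective.
#' @export
estimate_components_from_pilot <- function(data) {
  if (inherits(data, "concordance_data1")) {
    ind <- cbind(data$r_indicators, data$s_indicators)
    classes <- indicator_pair_classes(1, data$m)
  } else if (inherits(data, "concordance_data2")) {
    ind <- cbind(data$x_indicators, data$y_indicators)
    classes <- indicator_pair_classes(2, data$m)
  } else {
    stop("data must be a concordance_data1 or concordance_data2 object",
         call. = FALSE)
  }
  if (data$n < 10L) {
    warning(sprintf("only n = %d subjects; component correlation estimates will be unstable",
                    data$n))
  }
  sds <- apply(ind, 2, sd)
  if (any(sds == 0)) {
    bad <- classes$labels[which(sds == 0)[1]]
    stop(sprintf(paste0("indicator column '%s' is constant; its correlations are ",
                        "undefined"), bad), call. = FALSE)
  }
  cm <- cor(ind)
  # classes with no member pairs (e.g. disjoint radiologist pairs need
  # m >= 4) are reported as 0; they carry zero weight in the compound
  # correlation formulas at such m
  pooled <- vapply(classes$class_names, function(cl) {
    idx <- classes$pairs[classes$pairs$class == cl, , drop = FALSE]
    if (nrow(idx) == 0L) return(0)
    mean(cm[cbind(idx$a, idx$b)])
  }, numeric(1))
  if (inherits(data, "concordance_data1")) {
    component_correlations1(data$m,
                            rho_r1 = pooled[["rho_r1"]], rho_r2 = pooled[["rho_r2"]],
                            rho_s1 = pooled[["rho_s1"]], rho_s2 = pooled[["rho_s2"]],
                            rho_ss = pooled[["rho_ss"]])
  } else {
    component_correlations2(data$m,
                            rho_xx = pooled[["rho_xx"]], rho_yy = pooled[["rho_yy"]],
                            rho_xy = pooled[["rho_xy"]])
  }
}
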