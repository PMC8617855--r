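# Monte-Carlo operating characteristics: simulate under the null and the
# design alternative at the computed sample size, and report empirical
# type-I error and power.

#' Monte-Carlo scenario for one design cell
#'
#' @param objective 1 or 2.
#' @param m radiologists (per group for objective 2).
#' @param rate anticipated concordance rate (`pr` for objective 1, `px`
#'   for objective 2).
#' @param delta margin `delta1` (objective 1) or difference `delta2`
#'   (objective 2).
#' @param rho compound correlation target (`rho1` or `rho2`), inverted to
#'   component correlations under the default offset constraints.
#' @param alpha test level (one-sided for objective 1, two-sided for 2).
#' @param power target power used for the sample-size calculation.
#' @param reps simulation replicates (>= 100).
#' @param seed master RNG seed for the cell.
#' @return object of class `concord_scenario`.
#' @export
scenario <- function(objective, m, rate, delta, rho, alpha = 0.05,
                     power = 0.8, reps = 10000, seed = 1) {
  objective <- as.integer(match.arg(as.character(objective), c("1", "2")))
  if (reps < 100) stop("reps must be at least 100", call. = FALSE)
  structure(
    list(objective = objective, m = as.integer(m), rate = rate, delta = delta,
         rho = rho, alpha = alpha, power = power, reps = as.integer(reps),
         seed = as.integer(seed)),
    class = "concord_scenario"
  )
}

# rejection counts over reps simulated datasets drawn from `model`;
# statistics are computed in vectorized batches (capped at ~2e7 latent
# draws per batch)
.reject_fraction <- function(model, n, reps, objective, delta1, crit) {
  layout <- model$layout
  m <- layout$m
  d <- length(layout$labels)
  batch <- max(1L, min(reps, as.integer(floor(2e7 / (n * d)))))
  done <- 0L
  rej <- 0L
  degen <- 0L
  K <- if (objective == 1L) m * (m - 1L) / 2L else m
  while (done < reps) {
    B <- min(batch, reps - done)
    ind <- .draw_indicators(model, n * B)
    a_i <- rowMeans(ind[, seq_len(K), drop = FALSE])
    b_i <- rowMeans(ind[, K + seq_len(m), drop = FALSE])
    D <- if (objective == 1L) {
      matrix(b_i - a_i + delta1, n, B)   # s_i - r_i + delta1
    } else {
      matrix(a_i - b_i, n, B)            # x_i - y_i
    }
    msq <- colMeans(D * D)
    z <- sqrt(n) * colMeans(D) / sqrt(msq)
    degen <- degen + sum(msq == 0)
    keep <- msq > 0
    rej <- rej + if (objective == 1L) sum(z[keep] > crit) else sum(abs(z[keep]) > crit)
    done <- done + B
  }
  list(rej = rej, degen = degen)
}

#' Run one Monte-Carlo scenario
#'
#' Solves the component correlations from the scenario's compound
#' correlation target, computes the required sample size `n`, then
#' simulates `reps` datasets of size `n` under the null (`ps = pr -
#' delta1` for objective 1; `px = py = rate` for objective 2) and under
#' the design alternative (`ps = pr`; `py = px - delta2`), applying the
#' corresponding test to each.  Null and alternative streams use
#' independent sub-seeds drawn deterministically from the scenario seed.
#'
#' @param s [scenario()] object.
#' @return object of class `scenario_result` with the computed `n`,
#'   empirical rejection rates `alpha_hat` and `power_hat`, binomial
#'   Monte-Carlo standard errors, degenerate-replicate counts, `reps`,
#'   and `seed`.
#' @export
run_scenario <- function(s) {
  stopifnot(inherits(s, "concord_scenario"))
  if (s$objective == 1L) {
    spec <- design1_spec(m = s$m, pr = s$rate, delta1 = s$delta,
                         alpha = s$alpha, power = s$power, rho1 = s$rho)
    n <- as.integer(samplesize_objective1(spec))
    comp <- spec$components
    layout_null <- assemble_layout(1, s$m, c(s$rate, s$rate - s$delta), comp)
    layout_alt <- assemble_layout(1, s$m, c(s$rate, s$rate), comp)
    crit <- qnorm(1 - s$alpha)
  } else {
    spec <- design2_spec(m = s$m, px = s$rate, delta2 = s$delta,
                         alpha = s$alpha, power = s$power, rho2 = s$rho)
    n <- as.integer(samplesize_objective2(spec))
    comp <- spec$components
    layout_null <- assemble_layout(2, s$m, c(s$rate, s$rate), comp)
    layout_alt <- assemble_layout(2, s$m, c(s$rate, s$rate - s$delta), comp)
    crit <- qnorm(1 - s$alpha / 2)
  }
  model_null <- latent_model(layout_null)
  model_alt <- latent_model(layout_alt)

  set.seed(s$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 2L)
  set.seed(sub[1])
  null_res <- .reject_fraction(model_null, n, s$reps, s$objective, s$delta, crit)
  set.seed(sub[2])
  alt_res <- .reject_fraction(model_alt, n, s$reps, s$objective, s$delta, crit)

  degen <- c(null = null_res$degen, alt = alt_res$degen)
  if (any(degen > 0.001 * s$reps)) {
    stop(sprintf("more than 0.1%% of replicates had degenerate variance (null %d, alt %d of %d)",
                 degen["null"], degen["alt"], s$reps), call. = FALSE)
  }
  alpha_hat <- null_res$rej / (s$reps - null_res$degen)
  power_hat <- alt_res$rej / (s$reps - alt_res$degen)
  structure(
    list(scenario = s, n = n,
         alpha_hat = alpha_hat, power_hat = power_hat,
         mc_se_alpha = sqrt(alpha_hat * (1 - alpha_hat) / s$reps),
         mc_se_power = sqrt(power_hat * (1 - power_hat) / s$reps),
         degenerate = degen, reps = s$reps, seed = s$seed),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$scenario
  cat(sprintf("Scenario (objective %d): m = %d, rate = %g, delta = %g, rho = %g\n",
              s$objective, s$m, s$rate, s$delta, s$rho))
  cat(sprintf("  n = %d; empirical type-I error = %.4f (SE %.4f); empirical power = %.4f (SE %.4f)\n",
              x$n, x$alpha_hat, x$mc_se_alpha, x$power_hat, x$mc_se_power))
  cat(sprintf("  reps = %d, seed = %d\n", x$reps, x$seed))
  invisible(x)
}

.table_grid <- function(table) {
  rates <- c(0.3, 0.5, 0.7)
  deltas <- c(0.05, 0.1)
  rhos <- c(0.1, 0.3, 0.5, 0.7)
  powers <- c(0.8, 0.9)
  grid <- expand.grid(power_target = powers, rho = rhos, delta = deltas,
                      rate = rates)[, c("rate", "delta", "rho", "power_target")]
  grid$objective <- if (table == 1L) 1L else 2L
  grid$m <- if (table == 1L) 10L else 5L
  grid
}

#' Reproduce an operating-characteristic table
#'
#' Runs [run_scenario()] over the full design grid of one of the
#' package's reference tables (objective 1: m = 10; objective 2: m = 5
#' per group; rates 0.3/0.5/0.7, deltas 0.05/0.1, compound correlations
#' 0.1/0.3/0.5/0.7, target powers 0.8/0.9, alpha = 0.05), reporting the
#' computed sample size and empirical type-I error and power for each
#' cell.  Per-cell seeds are drawn deterministically from the master
#' seed (a fixed `sample.int` stream indexed by row), so any subset of
#' cells reproduces independently of the others.
#'
#' @param table 1 (objective 1) or 2 (objective 2).
#' @param reps simulation replicates per cell.
#' @param seed master seed.
#' @param cells optional integer vector of row indices (1..48) to run.
#' @param verbose print per-cell progress to stderr.
#' @return data frame with one row per cell: design parameters, `n`,
#'   `alpha_hat`, `power_hat`, Monte-Carlo standard errors, `reps` and
#'   the cell seed.  Cells whose simulation fails are reported with `NA`
#'   results and collected in the `failures` attribute.
#' @export
reproduce_table <- function(table = 1, reps = 10000, seed = 1, cells = NULL,
                            verbose = FALSE) {
  table <- as.integer(match.arg(as.character(table), c("1", "2")))
  grid <- .table_grid(table)
  set.seed(seed)
  row_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  if (is.null(cells)) cells <- seq_len(nrow(grid))
  if (any(cells < 1L | cells > nrow(grid))) {
    stop(sprintf("cells must be indices in 1..%d", nrow(grid)), call. = FALSE)
  }
  grid$n <- NA_integer_
  grid$alpha_hat <- NA_real_
  grid$power_hat <- NA_real_
  grid$mc_se_alpha <- NA_real_
  grid$mc_se_power <- NA_real_
  grid$reps <- NA_integer_
  grid$seed <- NA_integer_
  failures <- list()
  for (k in cells) {
    res <- tryCatch(
      run_scenario(scenario(objective = grid$objective[k], m = grid$m[k],
                            rate = grid$rate[k], delta = grid$delta[k],
                            rho = grid$rho[k], power = grid$power_target[k],
                            reps = reps, seed = row_seeds[k])),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(cell = k, message = conditionMessage(res))
      next
    }
    grid$n[k] <- res$n
    grid$alpha_hat[k] <- res$alpha_hat
    grid$power_hat[k] <- res$power_hat
    grid$mc_se_alpha[k] <- res$mc_se_alpha
    grid$mc_se_power[k] <- res$mc_se_power
    grid$reps[k] <- res$reps
    grid$seed[k] <- row_seeds[k]
    if (verbose) {
      message(sprintf("cell %d/%d: rate %g delta %g rho %g power %g -> n = %d (%.3f, %.3f)",
                      k, nrow(grid), grid$rate[k], grid$delta[k], grid$rho[k],
                      grid$power_target[k], res$n, res$alpha_hat, res$power_hat))
    }
  }
  if (length(failures)) {
    warning(sprintf("%d cell(s) failed; see attr(result, 'failures')",
                    length(failures)))
  }
  out <- grid[cells, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}
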