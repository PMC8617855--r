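# Compound correlation algebra: forward formulas, inverse solvers,
# pilot estimation.

test_that("rho1 formula reproduces the reference design tuples", {
  # first tuple is quoted to 3 decimals, the rest to 2; agreement is to
  # the quoted rounding precision
  tuples <- list(
    list(rho1 = 0.1, c = c(0.101, 0.001, 0.201, 0.201, 0.101), tol = 0.002),
    list(rho1 = 0.3, c = c(0.16, 0.06, 0.26, 0.26, 0.16), tol = 0.01),
    list(rho1 = 0.5, c = c(0.26, 0.16, 0.36, 0.36, 0.26), tol = 0.01),
    list(rho1 = 0.7, c = c(0.48, 0.38, 0.58, 0.58, 0.48), tol = 0.01)
  )
  for (t in tuples) {
    comp <- component_correlations1(10, rho_s1 = t$c[1], rho_s2 = t$c[2],
                                    rho_ss = t$c[3], rho_r1 = t$c[4],
                                    rho_r2 = t$c[5])
    expect_lt(abs(rho1_from_components(comp) - t$rho1), t$tol)
  }
  zero <- component_correlations1(10, 0, 0, 0, 0, 0)
  expect_equal(rho1_from_components(zero), 0)
})

test_that("rho2 formula reproduces the reference design tuples", {
  tuples <- list(
    list(rho2 = 0.1, c = c(0.13, 0.13, 0.03)),
    list(rho2 = 0.3, c = c(0.21, 0.21, 0.11)),
    list(rho2 = 0.5, c = c(0.33, 0.33, 0.23)),
    list(rho2 = 0.7, c = c(0.55, 0.55, 0.45))
  )
  for (t in tuples) {
    comp <- component_correlations2(5, t$c[1], t$c[2], t$c[3])
    expect_lt(abs(rho2_from_components(comp) - t$rho2), 0.005)
  }
  expect_equal(rho2_from_components(component_correlations2(5, 0.3, 0.2, 0)), 0)
})

test_that("obj-1 solver reproduces the reference tuples and round-trips", {
  sol <- solve_components_obj1(0.1, m = 10)
  expect_equal(round(c(sol$rho_s1, sol$rho_s2, sol$rho_ss, sol$rho_r1, sol$rho_r2), 3),
               c(0.101, 0.001, 0.201, 0.201, 0.101))
  sol7 <- solve_components_obj1(0.7, m = 10)
  expect_equal(round(c(sol7$rho_s1, sol7$rho_s2, sol7$rho_ss, sol7$rho_r1, sol7$rho_r2), 2),
               c(0.48, 0.38, 0.58, 0.58, 0.48))
  for (t in seq(0.1, 0.7, by = 0.1)) {
    expect_equal(rho1_from_components(solve_components_obj1(t, 10)), t,
                 tolerance = 1e-8)
  }
  expect_error(solve_components_obj1(0.999, 10), "unattainable")
})

test_that("obj-2 solver is the documented closed form and round-trips", {
  sol <- solve_components_obj2(0.3, m = 5)
  expect_equal(round(c(sol$rho_xx, sol$rho_yy, sol$rho_xy), 2), c(0.21, 0.21, 0.11))
  sol5 <- solve_components_obj2(0.5, m = 5)
  expect_equal(round(c(sol5$rho_xx, sol5$rho_yy, sol5$rho_xy), 2), c(0.33, 0.33, 0.23))
  sol0 <- solve_components_obj2(0, m = 5)
  expect_equal(sol0$rho_xy, 0)
  expect_equal(sol0$rho_xx, 0.1)
  for (t in seq(0.1, 0.7, by = 0.2)) {
    expect_equal(rho2_from_components(solve_components_obj2(t, 5)), t,
                 tolerance = 1e-12)
  }
  expect_error(solve_components_obj2(0.95, 2), "outside")
})

test_that("rho1 is monotone in each component on a grid", {
  base <- c(rho_r1 = 0.2, rho_r2 = 0.1, rho_s1 = 0.15, rho_s2 = 0.05,
            rho_ss = 0.25)
  signs <- c(rho_r1 = -1, rho_r2 = -1, rho_s1 = 1, rho_s2 = 1, rho_ss = -1)
  for (nm in names(base)) {
    vals <- vapply(seq(0.02, 0.4, by = 0.02), function(v) {
      args <- as.list(base)
      args[[nm]] <- v
      rho1_from_components(do.call(component_correlations1, c(list(m = 10), args)))
    }, numeric(1))
    expect_true(all(sign(diff(vals)) == signs[[nm]]),
                info = sprintf("monotonicity in %s", nm))
  }
})

test_that("Monte-Carlo oracle confirms the compound correlation formulas", {
  # empirical corr of the per-subject scores over many subjects matches
  # the closed forms (this is the validation gate for the derived rho2)
  comp1 <- solve_components_obj1(0.5, 10)
  d1 <- simulate_dataset(assemble_layout(1, 10, c(0.5, 0.5), comp1),
                         1e5, seed = 31)
  expect_lt(abs(cor(d1$r_i, d1$s_i) - rho1_from_components(comp1)), 0.01)

  comp2 <- solve_components_obj2(0.7, 5)
  d2 <- simulate_dataset(assemble_layout(2, 5, c(0.7, 0.7), comp2),
                         1e5, seed = 32)
  expect_lt(abs(cor(d2$x_i, d2$y_i) - rho2_from_components(comp2)), 0.01)
})

test_that("pilot estimation recovers known components", {
  comp <- solve_components_obj1(0.3, 10)
  d <- simulate_dataset(assemble_layout(1, 10, c(0.5, 0.5), comp),
                        5000, seed = 77)
  est <- estimate_components_from_pilot(d)
  for (nm in c("rho_r1", "rho_r2", "rho_s1", "rho_s2", "rho_ss")) {
    expect_lt(abs(est[[nm]] - comp[[nm]]), 0.03)
  }

  comp2 <- solve_components_obj2(0.3, 5)
  d2 <- simulate_dataset(assemble_layout(2, 5, c(0.6, 0.5), comp2),
                         5000, seed = 78)
  est2 <- estimate_components_from_pilot(d2)
  for (nm in c("rho_xx", "rho_yy", "rho_xy")) {
    expect_lt(abs(est2[[nm]] - comp2[[nm]]), 0.03)
  }
})

test_that("pilot estimation is deterministic and rejects degenerate data", {
  comp <- solve_components_obj1(0.3, 4)
  d <- simulate_dataset(assemble_layout(1, 4, c(0.5, 0.5), comp), 200, seed = 5)
  expect_identical(unlist(estimate_components_from_pilot(d)),
                   unlist(estimate_components_from_pilot(d)))
  perfect <- concordance_data1(matrix(1, 20, 6), matrix(1, 20, 4))
  expect_error(estimate_components_from_pilot(perfect), "constant")
  small <- simulate_dataset(assemble_layout(1, 4, c(0.5, 0.5), comp), 5, seed = 6)
  expect_warning(try(estimate_components_from_pilot(small), silent = TRUE),
                 "unstable")
})

test_that("component constructors validate their domain", {
  expect_error(component_correlations1(10, 1.2, 0, 0, 0, 0), "rho_r1")
  expect_error(component_correlations2(5, 0.1, 0.1, -1), "rho_xy")
  expect_error(component_correlations1(1, 0, 0, 0, 0, 0), "m >= 2")
  bad <- component_correlations1(10, rho_r1 = -0.9, rho_r2 = -0.9,
                                 rho_s1 = 0, rho_s2 = 0, rho_ss = -0.9)
  expect_error(rho1_from_components(bad), "infeasible")
})
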