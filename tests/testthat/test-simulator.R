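# Latent Gaussian dichotomization machinery.

test_that("pair classification counts match combinatorial formulas", {
  m <- 10
  cls <- indicator_pair_classes(1, m)
  counts <- table(cls$pairs$class)
  K <- m * (m - 1) / 2
  expect_equal(unname(counts[["rho_r1"]]), m * (m - 1) * (m - 2) / 2)  # 360
  expect_equal(unname(counts[["rho_r2"]]), 3 * choose(m, 4))           # 630
  expect_equal(unname(counts[["rho_s1"]]), 2 * K)                      # 90
  expect_equal(unname(counts[["rho_s2"]]), K * (m - 2))                # 360
  expect_equal(unname(counts[["rho_ss"]]), choose(m, 2))               # 45
  expect_equal(sum(counts), choose(K + m, 2))

  # m = 3: no disjoint radiologist pairs exist
  cls3 <- indicator_pair_classes(1, 3)
  expect_false("rho_r2" %in% cls3$pairs$class)
  expect_equal(length(cls3$labels), 6L)

  cls2 <- indicator_pair_classes(2, 5)
  counts2 <- table(cls2$pairs$class)
  expect_equal(unname(counts2[["rho_xx"]]), 10)
  expect_equal(unname(counts2[["rho_yy"]]), 10)
  expect_equal(unname(counts2[["rho_xy"]]), 25)
})

test_that("binary feasibility bounds are enforced", {
  b <- binary_corr_bounds(0.5, 0.5)
  expect_equal(unname(b), c(-1, 1))
  b2 <- binary_corr_bounds(0.1, 0.9)
  expect_equal(unname(b2["upper"]), 1 / 9)
  expect_error(solve_latent_correlation(0.1, 0.9, 0.5), "infeasible")
  comp <- component_correlations2(5, 0.5, 0.5, 0.4)
  expect_error(assemble_layout(2, 5, c(0.05, 0.95), comp), "feasibility")
})

test_that("latent correlation solve matches closed forms and the quadrature oracle", {
  expect_equal(solve_latent_correlation(0.5, 0.5, 0.5), sin(pi * 0.5 / 2),
               tolerance = 1e-9)
  expect_identical(solve_latent_correlation(0.3, 0.7, 0), 0)
  # half marginals admit the arcsine closed form for any target
  for (rb in c(-0.4, 0.25, 0.8)) {
    expect_equal(solve_latent_correlation(0.5, 0.5, rb), sin(pi * rb / 2),
                 tolerance = 1e-8)
  }
  # independent 2-D quadrature oracle for asymmetric marginals
  skip_if_not_installed("pracma")
  rho_star <- solve_latent_correlation(0.3, 0.7, 0.2)
  tau_j <- qnorm(0.3, lower.tail = FALSE)
  tau_k <- qnorm(0.7, lower.tail = FALSE)
  s <- sqrt(1 - rho_star^2)
  dens <- function(x, y) {
    exp(-(x^2 - 2 * rho_star * x * y + y^2) / (2 * s^2)) / (2 * pi * s)
  }
  p11 <- pracma::integral2(dens, tau_j, 9, tau_k, 9, reltol = 1e-10)$Q
  induced <- (p11 - 0.3 * 0.7) / sqrt(0.3 * 0.7 * 0.7 * 0.3)
  expect_equal(induced, 0.2, tolerance = 1e-7)
})

test_that("induced binary correlations match their targets after the solve", {
  comp <- solve_components_obj1(0.3, 10)
  lay <- assemble_layout(1, 10, c(0.3, 0.25), comp)
  model <- latent_model(lay)
  # verify a representative entry of each class through the orthant formula
  cls <- indicator_pair_classes(1, 10)
  for (cl in cls$class_names) {
    idx <- cls$pairs[cls$pairs$class == cl, ][1, ]
    pj <- lay$marginals[idx$a]
    pk <- lay$marginals[idx$b]
    lat <- model$latent_corr[idx$a, idx$b]
    p11 <- bvn_upper_prob(qnorm(pj, lower.tail = FALSE),
                          qnorm(pk, lower.tail = FALSE), lat)
    induced <- (p11 - pj * pk) / sqrt(pj * (1 - pj) * pk * (1 - pk))
    expect_lt(abs(induced - comp[[cl]]), 1e-6)
  }
  expect_lte(model$repair_delta, 0.01)
})

test_that("simulated indicators hit marginals and correlations", {
  comp <- solve_components_obj1(0.3, 10)
  lay <- assemble_layout(1, 10, c(0.3, 0.3), comp)
  d <- simulate_dataset(lay, 4e4, seed = 21)
  ind <- cbind(d$r_indicators, d$s_indicators)
  expect_lt(max(abs(colMeans(ind) - 0.3)), 0.01)
  cm <- cor(ind)
  cls <- indicator_pair_classes(1, 10)
  for (cl in cls$class_names) {
    idx <- cls$pairs[cls$pairs$class == cl, ]
    err <- max(abs(cm[cbind(idx$a, idx$b)] - comp[[cl]]))
    expect_lt(err, 0.03)
  }
})

test_that("independent columns pass chi-square independence checks", {
  comp <- component_correlations2(5, 0, 0, 0)
  lay <- assemble_layout(2, 5, c(0.5, 0.5), comp)
  d <- simulate_dataset(lay, 1e4, seed = 23)
  ind <- cbind(d$x_indicators, d$y_indicators)
  pairs <- indicator_pair_classes(2, 5)$pairs
  pvals <- vapply(seq_len(nrow(pairs)), function(k) {
    suppressWarnings(
      stats::chisq.test(table(ind[, pairs$a[k]], ind[, pairs$b[k]]))$p.value
    )
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("simulation is reproducible given a seed", {
  comp <- solve_components_obj2(0.3, 5)
  lay <- assemble_layout(2, 5, c(0.6, 0.5), comp)
  d1 <- simulate_dataset(lay, 50, seed = 9)
  d2 <- simulate_dataset(lay, 50, seed = 9)
  expect_identical(d1$x_indicators, d2$x_indicators)
  expect_identical(d1$y_indicators, d2$y_indicators)
  d3 <- simulate_dataset(lay, 50, seed = 10)
  expect_false(identical(d1$x_indicators, d3$x_indicators))
})

test_that("layout validates component/m consistency and marginals", {
  comp <- solve_components_obj1(0.3, 10)
  expect_error(assemble_layout(1, 5, c(0.3, 0.3), comp), "m = 10")
  expect_error(assemble_layout(1, 10, c(0, 0.3), comp), "strictly inside")
  lay <- assemble_layout(1, 3, c(0.5, 0.5), solve_components_obj1(0.2, 3))
  expect_equal(dim(lay$binary_corr), c(6L, 6L))
  expect_true(isSymmetric(lay$binary_corr))
})
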