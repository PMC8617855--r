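test_that("indicators from readings match the definition of concordance", {
  df <- toy_readings()
  d <- indicators_from_readings(df, "Shape", objective = 1)

  expect_s3_class(d, "concordance_data1")
  expect_equal(d$n, 3L)
  expect_equal(d$m, 3L)
  # p1: radiologists (oval, oval, round), device oval
  expect_equal(unname(d$r_indicators[1, ]), c(1, 0, 0))
  expect_equal(d$r_i[1], 1 / 3)
  expect_equal(unname(d$s_indicators[1, ]), c(1, 1, 0))
  expect_equal(d$s_i[1], 2 / 3)
  # p2: unanimous agreement
  expect_equal(d$r_i[2], 1)
  expect_equal(d$s_i[2], 1)

  expect_equal(estimate_pr(d), 5 / 9)
  expect_equal(estimate_ps(d), mean(c(2 / 3, 1, 2 / 3)))
})

test_that("four-reader pair enumeration is lexicographic and complete", {
  # labels (a, a, b, b), device b: pairs (1,2),(1,3),(1,4),(2,3),(2,4),(3,4)
  df <- data.frame(
    subject_id = "s1",
    reader_id = c("dev", "r1", "r2", "r3", "r4"),
    reader_role = c("device", rep("radiologist", 4)),
    classification = "Shape",
    value = c("b", "a", "a", "b", "b")
  )
  d <- indicators_from_readings(df, "Shape")
  expect_equal(unname(d$r_indicators[1, ]), c(1, 0, 0, 0, 0, 1))
  expect_equal(d$r_i[1], 1 / 3)
  expect_equal(d$s_i[1], 1 / 2)
  expect_equal(reader_pairs(4)[, "j"], c(1L, 1L, 1L, 2L, 2L, 3L))
})

test_that("concordance is case/whitespace-normalized exact label match", {
  df <- data.frame(
    subject_id = "s1",
    reader_id = c("dev", "r1", "r2"),
    reader_role = c("device", "radiologist", "radiologist"),
    classification = "Shape",
    value = c("Oval", " oval ", "OVAL")
  )
  d <- indicators_from_readings(df, "Shape")
  expect_equal(d$r_i, 1)
  expect_equal(d$s_i, 1)
})

test_that("objective-2 indicators compare each group with the device", {
  df <- data.frame(
    subject_id = "s1",
    reader_id = c("dev", "sen1", "sen2", "jun1", "jun2"),
    reader_role = c("device", "senior", "senior", "junior", "junior"),
    classification = "Shape",
    value = c("oval", "oval", "round", "round", "round")
  )
  d <- indicators_from_readings(df, "Shape", objective = 2)
  expect_s3_class(d, "concordance_data2")
  expect_equal(d$x_i, 1 / 2)
  expect_equal(d$y_i, 0)
  expect_equal(unname(estimate_px_py(d)), c(1 / 2, 0))
})

test_that("missing or malformed readings raise named errors", {
  df <- toy_readings()
  expect_error(indicators_from_readings(df, "Margin"),
               "not present.*Shape")
  expect_error(indicators_from_readings(df[-2, ], "Shape"),
               "missing reading.*p1.*rad1")
  no_dev <- df[df$reader_role != "device", ]
  expect_error(indicators_from_readings(no_dev, "Shape"),
               "missing device reading")
  dup <- rbind(df, df[2, ])
  expect_error(indicators_from_readings(dup, "Shape"), "duplicate reading")
})

test_that("estimators are invariant under reader relabeling", {
  df <- toy_readings()
  base <- indicators_from_readings(df, "Shape")
  relab <- df
  relab$reader_id <- c(dev = "dev", rad1 = "zz", rad2 = "aa",
                       rad3 = "mm")[relab$reader_id]
  perm <- indicators_from_readings(relab, "Shape")
  expect_equal(estimate_pr(perm), estimate_pr(base))
  expect_equal(estimate_ps(perm), estimate_ps(base))
  expect_equal(sort(perm$r_i), sort(base$r_i))
})

test_that("estimators are unbiased under simulation", {
  # 1000 datasets of n = 30 drawn as one stream; grand means of the
  # estimators stay within 4 Monte-Carlo SEs of the truth
  comp <- solve_components_obj1(0.3, 4)
  lay <- assemble_layout(1, 4, c(0.5, 0.25), comp)
  d <- simulate_dataset(lay, 1000 * 30, seed = 42)
  pr_hats <- colMeans(matrix(d$r_i, 30))
  ps_hats <- colMeans(matrix(d$s_i, 30))
  expect_lt(abs(mean(pr_hats) - 0.5), 4 * sd(pr_hats) / sqrt(1000))
  expect_lt(abs(mean(ps_hats) - 0.25), 4 * sd(ps_hats) / sqrt(1000))

  comp2 <- solve_components_obj2(0.3, 5)
  lay2 <- assemble_layout(2, 5, c(0.7, 0.6), comp2)
  d2 <- simulate_dataset(lay2, 5000, seed = 43)
  est <- estimate_px_py(d2)
  expect_lt(abs(est[["px"]] - 0.7), 3 * sd(d2$x_i) / sqrt(5000))
  expect_lt(abs(est[["py"]] - 0.6), 3 * sd(d2$y_i) / sqrt(5000))
})

test_that("indicator CSV writer round-trips through the reader", {
  d <- indicators_from_readings(toy_readings(), "Shape")
  path <- withr::local_tempfile(fileext = ".csv")
  write_indicators(d, path)
  back <- read_indicators(path, objective = 1)
  expect_equal(back$r_indicators, d$r_indicators, ignore_attr = TRUE)
  expect_equal(back$s_indicators, d$s_indicators, ignore_attr = TRUE)
  expect_equal(back$r_i, d$r_i, ignore_attr = TRUE)

  lay2 <- assemble_layout(2, 3, c(0.5, 0.5), component_correlations2(3, 0.2, 0.2, 0.1))
  d2 <- simulate_dataset(lay2, 20, seed = 1)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_indicators(d2, path2)
  back2 <- read_indicators(path2, objective = 2)
  expect_equal(back2$x_indicators, d2$x_indicators, ignore_attr = TRUE)
  expect_equal(back2$y_indicators, d2$y_indicators, ignore_attr = TRUE)
})

test_that("simulated readings tables satisfy the complete-block contract", {
  df <- simulate_readings(5, 3, seed = 11)
  d <- indicators_from_readings(df, "Shape")
  expect_equal(d$n, 5L)
  expect_equal(d$m, 3L)
  df2 <- simulate_readings(4, 2, objective = 2, seed = 12)
  d2 <- indicators_from_readings(df2, "Shape", objective = 2)
  expect_equal(d2$m, 2L)
})
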