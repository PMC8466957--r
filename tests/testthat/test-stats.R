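test_that("normality gate calibration and guards", {
  set.seed(1)
  gates_n <- replicate(100, normality_gate(rnorm(200)))
  expect_gte(mean(gates_n == "normal"), 0.90)
  gates_ln <- replicate(50, normality_gate(rlnorm(200, sdlog = 1)))
  expect_true(all(gates_ln == "non_normal"))
  expect_error(normality_gate(c(1, 2)), "3 <= n")
  expect_error(normality_gate(rep(1, 10)), "constant")
})

test_that("descriptives match the gate's style", {
  d <- descriptives(c(1, 2, 3, 4, 5), "non_normal")
  expect_equal(d$location, 3)
  expect_equal(d$spread, 2)
  d <- descriptives(c(1, 2, 3), "normal")
  expect_equal(d$location, 2)
  expect_equal(d$spread, 1)
  expect_equal(descriptives(5, "normal")$spread, 0)
})

test_that("group comparison picks the gated test and hits exact values", {
  r <- compare_groups(c(1, 2, 3), c(10, 11, 12),
                      gate_x = "non_normal", gate_y = "non_normal")
  expect_equal(r$test_name, "mann_whitney")
  expect_equal(r$p_value, 0.1)  # U = 0, exact: 2 of C(6,3) = 20 rankings

  x <- c(1, 5, 2, 8, 3)
  r <- compare_groups(x, x)
  expect_equal(r$p_value, 1)

  r <- compare_groups(rep(2, 5), rep(2, 6))
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)

  set.seed(2)
  r <- compare_groups(rnorm(30, 0, 1), rnorm(30, 5, 1))
  expect_equal(r$test_name, "welch_t")
  expect_lt(r$p_value, 1e-6)
})

test_that("paired test handles zeros, exactness and direction", {
  expect_equal(paired_test(1:5, 1:5)$p_value, 1)
  expect_true(paired_test(1:5, 1:5)$degenerate)

  before <- c(1, 2, 3, 4, 5)
  after <- before - c(0.11, 0.23, 0.31, 0.47, 0.53)
  expect_equal(paired_test(before, after)$p_value, 2 / 32)

  expect_error(paired_test(1:3, 1:4), "length")
})

test_that("exact small-sample branches agree with enumeration oracles", {
  set.seed(5)
  # Mann-Whitney across all size splits up to n + m = 8
  for (n in 2:4) for (m in n:(8 - n)) {
    x <- round(rnorm(n), 3); y <- round(rnorm(m, 0.5), 3)
    r <- compare_groups(x, y, gate_x = "non_normal", gate_y = "non_normal")
    expect_equal(r$p_value, mw_enum_p(x, y), tolerance = 1e-10,
                 info = sprintf("MW n=%d m=%d", n, m))
  }
  # signed rank up to 8 pairs
  for (m in 2:8) {
    b <- round(rnorm(m), 3); a <- b + round(rnorm(m, 0.3), 3)
    r <- paired_test(b, a)
    expect_equal(r$p_value, signrank_enum_p(b, a), tolerance = 1e-10,
                 info = sprintf("SR m=%d", m))
  }
  # Spearman exact permutation p for n = 4..7
  for (n in 4:7) {
    x <- rnorm(n); y <- rnorm(n)
    r <- spearman_perm(x, y)
    o <- spearman_enum(x, y)
    expect_equal(r$rho, o$rho, tolerance = 1e-12)
    expect_equal(r$p_value, o$p, tolerance = 1e-10,
                 info = sprintf("spearman n=%d", n))
  }
  # Fisher vs hypergeometric enumeration for margins <= 8
  for (i in 1:12) {
    tab <- matrix(rpois(4, 3), 2)
    tab[tab > 8] <- 8
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    r <- categorical_test(tab)
    if (r$test_name == "fisher_exact") {
      expect_equal(r$p_value, fisher_enum_p(tab), tolerance = 1e-9)
    }
  }
})

test_that("Spearman handles monotone, reversed and published patterns", {
  expect_equal(spearman_perm(1:5, c(2, 4, 5, 7, 11))$rho, 1)
  expect_equal(spearman_perm(1:5, -(1:5))$rho, -1)
  r <- spearman_perm(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$rho, 0.6)
  expect_equal(r$method, "exact_permutation")
  expect_error(spearman_perm(1:3, 1:3), "n >= 4")
  expect_error(spearman_perm(1:5, rep(1, 5)), "zero variance")
})

test_that("ICC(2,1) matches a hand ANOVA oracle and its invariances", {
  m <- rbind(c(1, 2), c(2, 3), c(3, 4))
  # hand sums of squares: n=3, k=2, constant rater offset 1
  n <- 3; k <- 2
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  mse <- sum((m - outer(rowMeans(m), rep(1, k)) -
                outer(rep(1, n), colMeans(m)) + grand)^2) / ((n - 1) * (k - 1))
  expected <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  r <- icc_two_way(m)
  expect_equal(r$value, expected, tolerance = 1e-12)

  expect_equal(icc_two_way(cbind(1:4, 1:4))$value, 1)
  # common rescaling of both raters leaves ICC unchanged
  set.seed(3)
  x <- matrix(rnorm(20), 10, 2)
  expect_equal(icc_two_way(10 * x)$value, icc_two_way(x)$value,
               tolerance = 1e-12)
  expect_true(icc_two_way(matrix(c(1, 1, 1, 1), 2))$undefined)

  set.seed(4)
  noise <- cbind(rnorm(200), rnorm(200))
  expect_lt(abs(icc_two_way(noise)$value), 0.1)
})

test_that("categorical test chooses Fisher below expected-count 5", {
  r <- categorical_test(rbind(c(4, 10), c(0, 14)))
  expect_equal(r$test_name, "fisher_exact")
  expect_equal(r$p_value, 0.098, tolerance = 0.005)

  expect_equal(categorical_test(rbind(c(5, 5), c(5, 5)))$p_value, 1)

  r <- categorical_test(rbind(c(40, 10), c(20, 30)))
  expect_equal(r$test_name, "chi_squared")
  expect_error(categorical_test(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("type-I error of the gated comparison stays near nominal", {
  set.seed(6)
  rej <- replicate(400, {
    compare_groups(rnorm(14), rnorm(14))$p_value < 0.05
  })
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})

test_that("result tables recompute every row with gated tests", {
  co <- simulate_cohort(test_config(seed = 11))
  tabs <- build_results_tables(co, spearman_seed = 1)
  expect_true(all(c("scp_foveal_vd", "scp_foveal_pd", "lhep") %in%
                    tabs$table2$variable))
  expect_true(all(tabs$table1$p_value >= 0 & tabs$table1$p_value <= 1))
  expect_true(all(tabs$table2$p_value >= 0 & tabs$table2$p_value <= 1))
  expect_equal(nrow(tabs$correlations), 2L)
  expect_true(all(abs(tabs$correlations$rho) > 0.9))
  expect_lt(tabs$roi_comparison$p_value, 0.05)
  expect_lt(tabs$roi_comparison$roi_median, tabs$roi_comparison$others_median)

  co$scp_foveal_vd <- NULL
  expect_error(build_results_tables(co), "scp_foveal_vd")
})
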