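test_that("vessel network honors FAZ exclusion, masks and target fraction", {
  cfg <- test_config(seed = 7)
  truth <- generate_vessel_network(cfg, seed = 7)
  expect_true(all(truth$vessel_mask[truth$perfused_mask]))

  # no vessel pixel center inside the FAZ polygon (point-in-polygon oracle)
  n <- cfg$image_size_px
  pitch <- cfg$pixel_pitch_um / 1000
  idx <- which(truth$vessel_mask)
  xs <- (((idx - 1L) %/% n) + 0.5) * pitch
  ys <- (((idx - 1L) %% n) + 0.5) * pitch
  expect_false(any(points_in_polygon(truth$faz_polygon, xs, ys)))

  expect_lt(abs(truth$achieved_vessel_fraction - cfg$vessel_fraction) /
              cfg$vessel_fraction, 0.2)
})

test_that("degenerate fractions produce the exact boundary masks", {
  cfg <- test_config(seed = 3, image_size_px = 560L, vessel_fraction = 0)
  truth <- generate_vessel_network(cfg, seed = 3)
  expect_equal(sum(truth$vessel_mask), 0)

  cfg <- test_config(seed = 3, perfused_fraction_of_vessels = 1)
  truth <- generate_vessel_network(cfg, seed = 3)
  expect_identical(truth$perfused_mask, truth$vessel_mask)
})

test_that("realized perfused share tracks the requested fraction", {
  cfg <- test_config(seed = 7, perfused_fraction_of_vessels = 0.5)
  truth <- generate_vessel_network(cfg, seed = 7)
  expect_equal(sum(truth$perfused_mask) / sum(truth$vessel_mask), 0.5,
               tolerance = 0.02)
})

test_that("rendering is deterministic and respects brightness contracts", {
  cfg <- test_config(seed = 5, noise_sd = 0)
  truth <- generate_vessel_network(cfg, seed = 5)
  a1 <- render_angiogram(truth, cfg, seed = 5)
  a2 <- render_angiogram(truth, cfg, seed = 5)
  expect_identical(a1, a2)

  expect_true(all(a1$image[truth$vessel_mask] >= 0.75))
  expect_true(all(a1$image[!truth$vessel_mask] <= 0.3))
  expect_true(all(a1$image >= 0 & a1$image <= 1))

  # without perfused pixels and without noise, frames are identical
  cfg0 <- test_config(seed = 5, noise_sd = 0, n_frames = 3L,
                      perfused_fraction_of_vessels = 0)
  truth0 <- generate_vessel_network(cfg0, seed = 5)
  f <- render_angiogram(truth0, cfg0, seed = 5)$frames
  expect_identical(f[[1]], f[[2]])
  expect_identical(f[[2]], f[[3]])
})

test_that("cohort medians recover the published group levels", {
  # stochastic: median over replicates of group medians near the
  # generating locations (TL 16.35 / ST 20.42 for foveal SCP VD)
  set.seed(42)
  meds <- t(replicate(30, {
    co <- simulate_cohort(test_config(), seed = sample.int(1e6, 1))
    c(tl = median(co$scp_foveal_vd[co$group == "TL"]),
      st = median(co$scp_foveal_vd[co$group == "ST"]))
  }))
  expect_lt(abs(median(meds[, "tl"]) - 16.35), 1)
  expect_lt(abs(median(meds[, "st"]) - 20.42), 1)
})

test_that("TL-group tissue loss sits at the published median across replicates", {
  set.seed(99)
  meds <- replicate(100, {
    co <- simulate_cohort(test_config(), seed = sample.int(1e6, 1))
    median(co$top3_sum_mm2[co$group == "TL"])
  })
  expect_gte(median(meds), 0.07)
  expect_lte(median(meds), 0.11)
})

test_that("cohort table is reproducible, boundary-sized groups work", {
  co1 <- simulate_cohort(test_config(seed = 11))
  co2 <- simulate_cohort(test_config(seed = 11))
  expect_identical(co1, co2)
  expect_equal(nrow(co1), 28L)

  co <- simulate_cohort(test_config(n_per_group = 2L), seed = 1)
  expect_equal(nrow(co), 4L)
})

test_that("shifted-lognormal draws match requested median and IQR", {
  set.seed(4)
  x <- rlnorm_shifted(2e5, -0.62, 1.34)
  expect_equal(median(x), -0.62, tolerance = 0.02)
  expect_equal(unname(diff(quantile(x, c(0.25, 0.75)))), 1.34,
               tolerance = 0.02)
})

test_that("grader simulation hits a calibrated agreement target", {
  areas <- rlnorm_shifted(14, 0.09, 0.055)
  g <- simulate_graders(areas, 0, seed = 1)
  expect_equal(g$g1, pmax(areas, 0))
  expect_equal(grader_agreement(g$g1, g$g2)$icc$value, 1)
  expect_error(simulate_graders(0.1, 0.01), ">= 2 areas")
})
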