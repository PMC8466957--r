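test_that("normalization rescales to [0,1] and flags degenerate input", {
  expect_equal(normalize_image(rbind(c(0, 5), c(10, 5))),
               rbind(c(0, 0.5), c(1, 0.5)))
  m <- rbind(c(0, 0.3), c(1, 0.7))
  expect_equal(normalize_image(m), m)
  expect_warning(z <- normalize_image(matrix(3, 2, 2)), "constant")
  expect_true(all(z == 0))
  expect_true(attr(z, "degenerate"))
  expect_error(normalize_image(matrix(numeric(0), 0, 0)), "empty")
})

test_that("global threshold applies the closed 0.7 white-pixel band", {
  expect_false(any(global_threshold(matrix(0.69, 3, 3))))
  expect_true(all(global_threshold(matrix(0.70, 3, 3))))
  cb <- matrix(c(0.2, 0.9), 4, 4)
  expect_identical(global_threshold(cb), cb == 0.9)
})

test_that("vesselness responds to ridges, not blobs or flat areas", {
  expect_true(all(hessian_vesselness(matrix(0.5, 32, 32)) == 0))

  img <- matrix(0, 64, 64)
  img[32:33, ] <- 1  # bright horizontal line, width 2
  v <- hessian_vesselness(img, scales_px = c(1, 2))
  on_line <- v[32:33, 5:60]
  off_line <- v[c(1:25, 40:64), 5:60]
  expect_gt(mean(on_line), 5 * mean(off_line))

  # isotropic blob peaks below an equal-intensity ridge
  xy <- seq(-3, 3, length.out = 65)
  blob <- exp(-outer(xy^2, xy^2, "+") / 0.5)
  ridge <- matrix(exp(-xy^2 / 0.5), 65, 65)  # constant along x
  vb <- hessian_vesselness(blob, scales_px = c(2, 4))
  vr <- hessian_vesselness(ridge, scales_px = c(2, 4))
  expect_lt(vb[33, 33], vr[33, 33])

  expect_error(hessian_vesselness(matrix(0, 16, 16), scales_px = 5),
               "quarter")
})

test_that("vesselness is rotation-robust within the discretization bound", {
  n <- 101
  xy <- seq_len(n) - (n + 1) / 2
  d0 <- abs(matrix(xy, n, n))                       # axis-aligned ridge
  d45 <- abs(outer(xy, xy, "+")) / sqrt(2)          # 45-degree ridge
  r0 <- hessian_vesselness(exp(-d0^2 / 2), scales_px = c(1, 2))
  r45 <- hessian_vesselness(exp(-d45^2 / 2), scales_px = c(1, 2))
  m0 <- mean(r0[d0 < 0.5][10:80])
  m45 <- mean(r45[d45 < 0.5][10:80])
  expect_lt(abs(m0 - m45) / m0, 0.2)
})

test_that("adaptive threshold compares pixels to their local mean", {
  expect_false(any(adaptive_threshold(matrix(0.4, 9, 9), 3, offset = 0.01)))
  expect_true(all(adaptive_threshold(matrix(0.4, 9, 9), 3, offset = -0.01)))
  expect_error(adaptive_threshold(matrix(0.4, 9, 9), 4), "odd")

  # step image: only bright pixels near the edge exceed their local mean
  step <- cbind(matrix(0, 12, 6), matrix(1, 12, 6))
  hit <- which(adaptive_threshold(step, 3, offset = 0.1), arr.ind = TRUE)
  expect_true(all(step[hit] == 1))          # confined to the bright side
  expect_true(all(abs(hit[, "col"] - 6.5) <= 1.5))  # within 1 px of the edge
})

test_that("fusion rule is OR(global, AND(adaptive, vesselness)) + despeckle", {
  z <- matrix(FALSE, 8, 8)
  v0 <- matrix(0, 8, 8)
  expect_false(any(fuse_vessel_map(z, v0, z)$mask))

  g <- matrix(TRUE, 8, 8)
  expect_true(all(fuse_vessel_map(g, v0, z)$mask))

  # isolated blips below 5 px vanish; a 5-px component survives
  a <- matrix(FALSE, 16, 16)
  a[2, 2] <- TRUE                  # 1 px speckle
  a[10, 3:7] <- TRUE               # 5 px line
  fused <- fuse_vessel_map(a, matrix(0, 16, 16), matrix(FALSE, 16, 16))$mask
  expect_false(fused[2, 2])
  expect_true(all(fused[10, 3:7]))

  expect_error(fuse_vessel_map(z, matrix(0, 4, 4), z), "shape")
})

test_that("decorrelation formula matches hand computation and edge cases", {
  f1 <- matrix(0.5, 4, 4)
  expect_true(all(decorrelation_map(list(f1, f1)) == 0))
  expect_error(decorrelation_map(list(f1)), "2 frames")

  # alternating a, 0, a, 0 is fully decorrelated
  a <- matrix(0.8, 2, 2); z <- matrix(0, 2, 2)
  expect_true(all(decorrelation_map(list(a, z, a, z)) == 1))

  # two frames 0.8 / 0.4: D = 1 - 2*0.8*0.4 / (0.64 + 0.16) = 0.2
  expect_equal(decorrelation_map(list(matrix(0.8, 1, 1),
                                      matrix(0.4, 1, 1)))[1, 1], 0.2)
})

test_that("perfusion mask is a subset of the vessel mask at any threshold", {
  cfg <- test_config(seed = 2)
  truth <- generate_vessel_network(cfg, seed = 2)
  ang <- render_angiogram(truth, cfg, seed = 2)
  maps <- binarize_angiogram(ang)
  expect_true(all(maps$vessels$mask[maps$perfusion$mask]))

  D <- maps$perfusion$decorrelation
  expect_true(all(perfusion_map(maps$vessels, D, tau_d = 0)$mask ==
                    maps$vessels$mask))
  expect_error(perfusion_map(maps$vessels, D, tau_d = 1.5), "tau_d")

  # static frames + tau 1: nothing perfused
  static <- perfusion_map(maps$vessels,
                          decorrelation_map(list(ang$image, ang$image)),
                          tau_d = 1)
  expect_false(any(static$mask))
})

test_that("raising cuts never adds pixels (pipeline monotonicity)", {
  cfg <- test_config(seed = 4)
  truth <- generate_vessel_network(cfg, seed = 4)
  ang <- render_angiogram(truth, cfg, seed = 4)
  img <- normalize_image(ang$image)
  g <- global_threshold(img)
  v <- hessian_vesselness(img)
  a <- adaptive_threshold(img)
  m1 <- fuse_vessel_map(g, v, a, vesselness_cut = 0.05)$mask
  m2 <- fuse_vessel_map(g, v, a, vesselness_cut = 0.2)$mask
  expect_true(all(m1[m2]))

  D <- decorrelation_map(ang$frames)
  vm <- fuse_vessel_map(g, v, a)
  p1 <- perfusion_map(vm, D, 0.05)$mask
  p2 <- perfusion_map(vm, D, 0.2)$mask
  expect_true(all(p1[p2]))
})

test_that("binarization recovers ground truth on a clean synthetic", {
  cfg <- test_config(seed = 13, noise_sd = 0.02,
                     perfused_fraction_of_vessels = 0.5)
  truth <- generate_vessel_network(cfg, seed = 13)
  ang <- render_angiogram(truth, cfg, seed = 13)
  maps <- binarize_angiogram(ang)
  expect_gte(dice_coefficient(maps$vessels$mask, truth$vessel_mask), 0.8)
  est <- sum(maps$perfusion$mask) / sum(maps$vessels$mask)
  expect_lt(abs(est - 0.5), 0.05)
})

test_that("PD is refused without a frame stack", {
  cfg <- test_config(seed = 6)
  truth <- generate_vessel_network(cfg, seed = 6)
  ang <- render_angiogram(truth, cfg, seed = 6)
  ang$frames <- NULL
  maps <- binarize_angiogram(ang)
  expect_null(maps$perfusion)
})
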