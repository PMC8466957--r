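test_that("density arithmetic and edge cases", {
  m <- matrix(FALSE, 4, 4)
  expect_equal(vessel_density(m, 1:8), 0)
  m[1:3] <- TRUE
  expect_equal(vessel_density(m, 1:8), 37.5)
  expect_equal(vessel_density(matrix(TRUE, 2, 2), 1:4), 100)
  expect_error(vessel_density(m, integer(0)), "empty region")

  # half the vessel pixels perfused halves the density
  p <- m; p[1] <- p[2] <- FALSE; p[3] <- TRUE
  expect_equal(perfusion_density(p, 1:8), vessel_density(m, 1:8) / 3)
})

test_that("PD <= VD per region and totals conserve pixel-weighted means", {
  cfg <- test_config(seed = 8)
  truth <- generate_vessel_network(cfg, seed = 8)
  ang <- render_angiogram(truth, cfg, seed = 8)
  maps <- binarize_angiogram(ang)
  ext <- cfg$image_size_px * cfg$pixel_pitch_um / 1000
  g <- build_grid(c(ext / 2, ext / 2), roi_angle_deg = 45)
  rr <- rasterize_regions(g, cfg$image_size_px, cfg$pixel_pitch_um)
  tab <- region_metrics(maps$vessels, maps$perfusion, rr)

  expect_true(all(tab$pd_percent <= tab$vd_percent + 1e-9))

  # zone totals equal the pixel-count-weighted means of their sectors
  for (z in c("foveal", "parafoveal")) {
    sect <- tab[tab$zone == z & tab$quadrant_name != "total", ]
    tot <- tab[tab$zone == z & tab$quadrant_name == "total", ]
    expect_equal(tot$vd_percent,
                 sum(sect$vd_percent * sect$pixel_count) / tot$pixel_count)
    expect_equal(tot$pixel_count, sum(sect$pixel_count))
  }
  grid_tot <- tab[tab$zone == "grid", ]
  zone_tot <- tab[tab$quadrant_name == "total" & tab$zone != "grid", ]
  expect_equal(grid_tot$vd_percent,
               sum(zone_tot$vd_percent * zone_tot$pixel_count) /
                 grid_tot$pixel_count)
})

test_that("marching-squares perimeter of a disk stays within 2% of 2*pi*r", {
  pitch <- 5.7 / 1000
  n <- 200L
  for (r_px in c(30, 60)) {
    r_mm <- r_px * pitch
    c_mm <- n / 2 * pitch
    xs <- (seq_len(n) - 0.5) * pitch
    inside <- outer(xs, xs, function(y, x) (x - c_mm)^2 + (y - c_mm)^2) <
      r_mm^2
    vm <- structure(list(mask = !inside, pixel_pitch_um = 5.7),
                    class = "vessel_map")
    cfz <- cfz_from_mask(vm, c(c_mm, c_mm))
    expect_lt(abs(cfz$perimeter_mm - 2 * pi * r_mm) / (2 * pi * r_mm), 0.02)
    expect_lt(abs(cfz$area_mm2 - pi * r_mm^2) / (pi * r_mm^2), 0.02)
  }
})

test_that("CFZ recovered from a synthetic vessel map matches ground truth", {
  cfg <- test_config(seed = 21, faz_area_mm2 = 0.45, faz_circularity = 0.55)
  truth <- generate_vessel_network(cfg, seed = 21)
  ang <- render_angiogram(truth, cfg, seed = 21)
  maps <- binarize_angiogram(ang)
  ext <- cfg$image_size_px * cfg$pixel_pitch_um / 1000
  cfz <- cfz_from_mask(maps$vessels, c(ext / 2, ext / 2))
  expect_lt(abs(cfz$area_mm2 - truth$faz_area_mm2) / truth$faz_area_mm2, 0.05)
  truth_c <- circularity(truth$faz_area_mm2, truth$faz_perimeter_mm)
  expect_lt(abs(cfz$circularity - truth_c), 0.05)
})

test_that("CFZ extraction rejects bad seeds and unbounded components", {
  vm <- structure(list(mask = matrix(FALSE, 32, 32), pixel_pitch_um = 5.7),
                  class = "vessel_map")
  expect_error(cfz_from_mask(vm, c(0.05, 0.05)), "unbounded")
  vm$mask[] <- TRUE
  expect_error(cfz_from_mask(vm, c(0.05, 0.05)), "vessel pixel")
})
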