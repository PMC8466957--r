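test_that("section subtraction follows the loss-positive sign convention", {
  b <- list(patient_id = "P1", section_id = 1L, gap_area_mm2 = 0.10)
  f <- list(patient_id = "P1", section_id = 1L, gap_area_mm2 = 0.14)
  expect_equal(as.numeric(section_tissue_loss(b, f)), 0.04)
  expect_equal(as.numeric(section_tissue_loss(b, b)), 0)

  shrink <- section_tissue_loss(b, list(patient_id = "P1", section_id = 1L,
                                        gap_area_mm2 = 0.09))
  expect_equal(as.numeric(shrink), -0.01)
  expect_true(attr(shrink, "shrinkage"))

  expect_error(section_tissue_loss(b, list(patient_id = "P2",
                                           section_id = 1L,
                                           gap_area_mm2 = 0.2)), "match")

  # polygon-valued gaps are measured through the shoelace area
  sq <- rbind(c(0, 0), c(0.2, 0), c(0.2, 0.2), c(0, 0.2))
  fpoly <- list(patient_id = "P1", section_id = 1L, gap_area_mm2 = NA,
                gap_polygon = sq)
  expect_equal(as.numeric(section_tissue_loss(b, fpoly)), 0.04 - 0.10,
               tolerance = 1e-12)
})

test_that("top-3 summation, cutoff and speed follow the stated rules", {
  r <- quantify_patient_tl(c(0.04, 0.03, 0.01, 0.005), interval_years = 2.16)
  expect_equal(r$top3_sum_mm2, 0.08)
  expect_equal(r$group, "TL")
  expect_equal(r$speed_mm2_per_year, 0.08 / 2.16, tolerance = 1e-10)

  r <- quantify_patient_tl(c(0.005, 0.004), interval_years = 1)
  expect_equal(r$top3_sum_mm2, 0.009)
  expect_equal(r$group, "ST")

  # cutoff is inclusive ("at least 0.02")
  expect_equal(quantify_patient_tl(c(0.02), interval_years = 1)$group, "TL")
  expect_equal(quantify_patient_tl(c(0.0199), interval_years = 1)$group, "ST")

  expect_error(quantify_patient_tl(c(0.1), interval_years = 0), "positive")

  # exact day difference / 365.25
  r <- quantify_patient_tl(c(0.09), dates = c("2019-01-01", "2021-03-01"))
  expect_equal(r$interval_years, 790 / 365.25)
})

test_that("top-3 sum is permutation invariant and monotone in gap growth", {
  set.seed(7)
  for (i in 1:20) {
    tls <- round(rnorm(8, 0.02, 0.02), 4)
    r0 <- quantify_patient_tl(tls, interval_years = 2)
    perm <- sample(seq_along(tls))
    r1 <- quantify_patient_tl(tls[perm], interval_years = 2)
    expect_equal(r1$top3_sum_mm2, r0$top3_sum_mm2)
    expect_equal(r1$group, r0$group)

    # enlarging any one section's follow-up gap never decreases the sum
    k <- sample(length(tls), 1)
    tls2 <- tls; tls2[k] <- tls2[k] + 0.01
    expect_gte(quantify_patient_tl(tls2, 2)$top3_sum_mm2, r0$top3_sum_mm2)
  }
})

test_that("classifier reproduces generator group labels on default cohorts", {
  set.seed(31)
  agree <- replicate(10, {
    co <- simulate_cohort(test_config(), seed = sample.int(1e6, 1))
    tlt <- tissue_loss_table(attr(co, "sections"))
    mean(tlt$group[match(co$patient_id, tlt$patient_id)] == co$group)
  })
  expect_gte(mean(agree), 0.95)
})

test_that("grader agreement: identical lists give ICC 1; constant offset
           lowers absolute agreement below consistency", {
  a <- c(0.05, 0.09, 0.12, 0.2, 0.07)
  ga <- grader_agreement(a, a)
  expect_equal(ga$icc$value, 1)
  expect_equal(ga$consensus, a)

  shifted <- grader_agreement(a, a + 0.05)
  abs_icc <- shifted$icc$value
  cons_icc <- icc_two_way(cbind(a, a + 0.05), form = "consistency")$value
  expect_lt(abs_icc, cons_icc)
  expect_error(grader_agreement(0.1, 0.1), "2 measured")
})
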