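#' Recompute the cohort result tables
#'
#' Runs the full statistical battery on a cohort table: the
#' clinical/functional comparison (age, sex, comorbidities, BCVA,
#' follow-up, refraction, IOP), the OCT/OCTA comparison (PVD, EZ
#' disruption, LHEP, CFZ morphometry and sector densities per plexus),
#' the paired BCVA/IOP within-group tests, the two
#' TL-group Spearman correlations (tissue-loss amount vs SCP parafoveal
#' PD; speed of loss vs BCVA change), and the ROI-vs-remaining-quadrants
#' PD comparison. Quantitative rows are gated per group by Shapiro-Wilk;
#' descriptives match the gate (mean/SD when normal, median/IQR
#' otherwise). Raw p-values are reported row by row (no across-row
#' multiplicity correction); post hoc corrections live inside the
#' categorical tests only.
#'
#' @param cohort A cohort data frame from [simulate_cohort()] (or with the
#'   same columns).
#' @param spearman_seed Seed for Monte-Carlo permutation p-values.
#' @return List of data frames: `table1`, `table2`, `paired`,
#'   `correlations`, `roi_comparison`.
#' @export
build_results_tables <- function(cohort, spearman_seed = 1L) {
  quant1 <- c("age_years", "bcva_baseline", "bcva_followup",
              "followup_years", "se_diopters", "iop_baseline",
              "iop_followup")
  cat1 <- c("sex_male", "cv_dementia_stroke", "diabetes", "sah",
            "pseudophakia")
  cat2 <- c("ez_disruption", "lhep")
  quant2 <- c("scp_cfz_circularity", "scp_cfz_area_mm2",
              "scp_cfz_perimeter_mm", "scp_foveal_vd", "scp_foveal_pd",
              "scp_parafoveal_vd", "scp_parafoveal_pd",
              "dcp_cfz_circularity", "dcp_cfz_area_mm2",
              "dcp_cfz_perimeter_mm", "dcp_foveal_vd", "dcp_foveal_pd",
              "dcp_parafoveal_vd", "dcp_parafoveal_pd")
  need <- c("group", quant1, cat1, cat2, quant2, "pvd", "top3_sum_mm2",
            "speed_mm2_per_year")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  }
  tl <- cohort[cohort$group == "TL", ]
  st <- cohort[cohort$group == "ST", ]

  quant_row <- function(v) {
    r <- compare_groups(tl[[v]], st[[v]], variable = v)
    data.frame(variable = v, test = r$test_name,
               tl_location = r$descriptives$x$location,
               tl_spread = r$descriptives$x$spread,
               tl_style = r$descriptives$x$style,
               st_location = r$descriptives$y$location,
               st_spread = r$descriptives$y$spread,
               st_style = r$descriptives$y$style,
               p_value = r$p_value)
  }
  cat_row <- function(v, values = c(TRUE, FALSE)) {
    tab <- rbind(TL = c(sum(tl[[v]] %in% values[1L]),
                        sum(!tl[[v]] %in% values[1L])),
                 ST = c(sum(st[[v]] %in% values[1L]),
                        sum(!st[[v]] %in% values[1L])))
    r <- tryCatch(categorical_test(tab, variable = v),
                  error = function(e) {
                    # shared constant value in both groups: no contrast
                    stat_report(v, "degenerate", NA_real_, 1,
                                degenerate = TRUE)
                  })
    data.frame(variable = v, test = r$test_name,
               tl_location = tab[1L, 1L] / sum(tab[1L, ]),
               tl_spread = NA_real_, tl_style = "proportion",
               st_location = tab[2L, 1L] / sum(tab[2L, ]),
               st_spread = NA_real_, st_style = "proportion",
               p_value = r$p_value)
  }
  table1 <- rbind(
    do.call(rbind, lapply(quant1[1L], quant_row)),
    do.call(rbind, lapply(cat1, cat_row)),
    do.call(rbind, lapply(quant1[-1L], quant_row)))

  pvd_rows <- do.call(rbind, lapply(c("complete", "incomplete"), function(lv) {
    tab <- rbind(TL = c(sum(tl$pvd == lv), sum(tl$pvd != lv)),
                 ST = c(sum(st$pvd == lv), sum(st$pvd != lv)))
    r <- categorical_test(tab, variable = paste0("pvd_", lv))
    data.frame(variable = paste0("pvd_", lv), test = r$test_name,
               tl_location = tab[1L, 1L] / sum(tab[1L, ]),
               tl_spread = NA_real_, tl_style = "proportion",
               st_location = tab[2L, 1L] / sum(tab[2L, ]),
               st_spread = NA_real_, st_style = "proportion",
               p_value = r$p_value)
  }))
  table2 <- rbind(pvd_rows,
                  do.call(rbind, lapply(cat2, cat_row)),
                  do.call(rbind, lapply(quant2, quant_row)))

  paired <- do.call(rbind, lapply(c("TL", "ST"), function(g) {
    gg <- cohort[cohort$group == g, ]
    rb <- paired_test(gg$bcva_baseline, gg$bcva_followup,
                      variable = paste0("bcva_", g))
    ri <- paired_test(gg$iop_baseline, gg$iop_followup,
                      variable = paste0("iop_", g))
    data.frame(variable = c(rb$variable, ri$variable),
               test = c(rb$test_name, ri$test_name),
               p_value = c(rb$p_value, ri$p_value))
  }))

  if (nrow(tl) >= 4L) {
    s1 <- spearman_perm(tl$top3_sum_mm2, tl$scp_parafoveal_pd,
                        seed = spearman_seed)
    s2 <- spearman_perm(tl$speed_mm2_per_year,
                        tl$bcva_followup - tl$bcva_baseline,
                        seed = spearman_seed + 1L)
  } else {
    warning("fewer than 4 TL patients: correlations not estimable")
    s1 <- s2 <- list(rho = NA_real_, p_value = NA_real_, method = "none")
  }
  correlations <- data.frame(
    pair = c("tl_amount_vs_scp_parafoveal_pd", "tl_speed_vs_bcva_change"),
    group = "TL", rho = c(s1$rho, s2$rho),
    p_value = c(s1$p_value, s2$p_value),
    method = c(s1$method, s2$method))

  roi_comparison <- NULL
  if (all(c("scp_roi_pd", "scp_r1_pd", "scp_r2_pd", "scp_r3_pd") %in%
          names(cohort))) {
    others <- rowMeans(tl[, c("scp_r1_pd", "scp_r2_pd", "scp_r3_pd")])
    r <- paired_test(others, tl$scp_roi_pd,
                     variable = "scp_roi_pd_vs_other_quadrants")
    roi_comparison <- data.frame(
      variable = r$variable, test = r$test_name,
      roi_median = stats::median(tl$scp_roi_pd),
      others_median = stats::median(others), p_value = r$p_value)
  }
  list(table1 = table1, table2 = table2, paired = paired,
       correlations = correlations, roi_comparison = roi_comparison)
}
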