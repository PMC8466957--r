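#' Tissue loss of one B-scan section between visits
#'
#' TL = follow-up gap area minus baseline gap area, so that loss (an
#' enlarging retinal gap) is positive — the sign convention under which
#' every reported loss is a positive number. Negative values (gap
#' shrinkage) are retained algebraically and flagged.
#'
#' @param baseline,followup Rows/lists with `patient_id`, `section_id` and
#'   either `gap_area_mm2` or `gap_polygon` (a polygon whose area is then
#'   computed).
#' @return TL in mm^2 with attribute `shrinkage` when negative.
#' @export
section_tissue_loss <- function(baseline, followup) {
  area_of <- function(g) {
    if (!is.null(g$gap_area_mm2) && !is.na(g$gap_area_mm2)) {
      g$gap_area_mm2
    } else if (!is.null(g$gap_polygon)) {
      polygon_area(g$gap_polygon)
    } else stop("gap needs gap_area_mm2 or gap_polygon")
  }
  if (!identical(baseline$patient_id, followup$patient_id) ||
      !identical(as.integer(baseline$section_id),
                 as.integer(followup$section_id))) {
    stop("baseline and follow-up gaps must match in patient and section")
  }
  tl <- area_of(followup) - area_of(baseline)
  if (tl < 0) attr(tl, "shrinkage") <- TRUE
  tl
}

#' Quantify per-patient tissue loss and classify the eye
#'
#' The quantitative TL is the sum of the 3 largest per-section losses
#' (all sections when fewer than 3; ties at the third place broken by
#' ascending section id). An eye is classified progressive (`"TL"`) when
#' the sum reaches the enrollment cutoff of at least 0.02 mm^2, otherwise
#' stable (`"ST"`). Speed of loss is the top-3 sum divided by the interval
#' in years.
#'
#' @param section_tl Named (by section id) or plain numeric vector of
#'   per-section TL values (mm^2), length >= 1.
#' @param interval_years Interval between examinations (> 0), or computed
#'   from `dates` when supplied.
#' @param dates Optional pair of visit dates (anything `as.Date` accepts);
#'   the interval is the exact day difference / 365.25.
#' @param cutoff_mm2 Enrollment cutoff (default 0.02, inclusive).
#' @return A `tissue_loss_result` list: `per_section_tl_mm2`,
#'   `top3_sum_mm2`, `group`, `cutoff_mm2`, `interval_years`,
#'   `speed_mm2_per_year`.
#' @export
quantify_patient_tl <- function(section_tl, interval_years = NULL,
                                dates = NULL, cutoff_mm2 = 0.02) {
  if (!length(section_tl)) stop("need at least one section")
  if (!is.null(dates)) {
    dates <- as.Date(dates)
    interval_years <-
      as.numeric(difftime(dates[2L], dates[1L], units = "days")) / 365.25
  }
  if (is.null(interval_years) || interval_years <= 0) {
    stop("interval must be positive")
  }
  ids <- if (!is.null(names(section_tl))) {
    suppressWarnings(as.numeric(names(section_tl)))
  } else seq_along(section_tl)
  ord <- order(-section_tl, ids)  # largest first, ties by ascending id
  top <- ord[seq_len(min(3L, length(section_tl)))]
  top3 <- sum(section_tl[top])
  structure(list(per_section_tl_mm2 = section_tl,
                 top3_sum_mm2 = top3,
                 group = if (top3 >= cutoff_mm2) "TL" else "ST",
                 cutoff_mm2 = cutoff_mm2,
                 interval_years = interval_years,
                 speed_mm2_per_year = top3 / interval_years),
            class = "tissue_loss_result")
}

#' Per-patient tissue loss from a long gap table
#'
#' @param gaps Data frame with columns `patient_id`, `section_id`, `visit`
#'   (`"baseline"`/`"followup"`), `gap_area_mm2`, and either
#'   `interval_years` or `visit_date`.
#' @param cutoff_mm2 Enrollment cutoff.
#' @return Data frame, one row per patient: `patient_id`, `top3_sum_mm2`,
#'   `group`, `interval_years`, `speed_mm2_per_year`.
#' @export
tissue_loss_table <- function(gaps, cutoff_mm2 = 0.02) {
  need <- c("patient_id", "section_id", "visit", "gap_area_mm2")
  miss <- setdiff(need, names(gaps))
  if (length(miss)) {
    stop("gap table is missing columns: ", paste(miss, collapse = ", "))
  }
  out <- lapply(split(gaps, gaps$patient_id), function(g) {
    b <- g[g$visit == "baseline", ]
    f <- g[g$visit == "followup", ]
    b <- b[order(b$section_id), ]; f <- f[order(f$section_id), ]
    if (!identical(b$section_id, f$section_id)) {
      stop("unmatched sections for patient ", g$patient_id[1L])
    }
    tl <- stats::setNames(f$gap_area_mm2 - b$gap_area_mm2, b$section_id)
    iv <- if ("interval_years" %in% names(g)) g$interval_years[1L] else NULL
    dt <- if ("visit_date" %in% names(g)) {
      c(b$visit_date[1L], f$visit_date[1L])
    } else NULL
    r <- quantify_patient_tl(tl, interval_years = iv, dates = dt,
                             cutoff_mm2 = cutoff_mm2)
    data.frame(patient_id = g$patient_id[1L],
               top3_sum_mm2 = r$top3_sum_mm2, group = r$group,
               interval_years = r$interval_years,
               speed_mm2_per_year = r$speed_mm2_per_year)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Inter-grader agreement on tissue-loss areas
#'
#' Two-way random single-measure absolute-agreement ICC (ICC(2,1)) between
#' the two graders' area measurements, plus the per-item mean as the
#' consensus used downstream.
#'
#' @param areas_g1,areas_g2 Equal-length numeric vectors (n >= 2).
#' @return List with `icc` (an [icc_two_way()] result) and `consensus`.
#' @export
grader_agreement <- function(areas_g1, areas_g2) {
  if (length(areas_g1) != length(areas_g2)) stop("grader lists differ in length")
  if (length(areas_g1) < 2L) stop("need at least 2 measured areas")
  ratings <- cbind(g1 = areas_g1, g2 = areas_g2)
  list(icc = icc_two_way(ratings, form = "agreement"),
       consensus = rowMeans(ratings))
}
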