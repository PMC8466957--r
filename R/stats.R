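#' Shapiro-Wilk normality gate
#'
#' Drives both the descriptive style (mean/SD vs median/IQR) and the
#' between-group test choice (t test vs Mann-Whitney): a sample is
#' `"non_normal"` when the Shapiro-Wilk p-value is below `alpha`.
#'
#' @param x Numeric sample, 3 <= n <= 5000, non-constant.
#' @param alpha Gate level (default 0.05).
#' @return `"normal"` or `"non_normal"`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || length(x) > 5000L) {
    stop("normality gate needs 3 <= n <= 5000")
  }
  if (stats::var(x) == 0) stop("undefined variance: constant sample")
  if (stats::shapiro.test(x)$p.value < alpha) "non_normal" else "normal"
}

#' Gate-matched descriptives
#'
#' @param x Numeric sample.
#' @param gate `"normal"` (mean and n-1 SD) or `"non_normal"` (median and
#'   IQR from linear-interpolation, type-7 quantiles).
#' @return List with `location`, `spread`, `style`.
#' @export
descriptives <- function(x, gate = c("non_normal", "normal")) {
  gate <- match.arg(gate)
  x <- x[!is.na(x)]
  if (!length(x)) stop("empty sample")
  if (gate == "normal") {
    list(location = mean(x),
         spread = if (length(x) > 1L) stats::sd(x) else 0,
         style = "mean_sd")
  } else {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    list(location = q[2L], spread = q[3L] - q[1L], style = "median_iqr")
  }
}

stat_report <- function(variable, test_name, statistic, p_value,
                        desc_x = NULL, desc_y = NULL, paired = FALSE,
                        degenerate = FALSE) {
  structure(list(variable = variable, test_name = test_name,
                 statistic = unname(statistic), p_value = unname(p_value),
                 descriptives = list(x = desc_x, y = desc_y),
                 paired = paired, degenerate = degenerate),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("%s: %s, statistic = %.4g, p = %.4g%s\n",
              x$variable, x$test_name, x$statistic, x$p_value,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Between-group comparison with normality gating
#'
#' Both samples normal by the Shapiro-Wilk gate: two-tailed independent
#' samples t test (Welch by default). Otherwise Mann-Whitney U, with the
#' exact null distribution when `n_x + n_y <= 20` and there are no ties,
#' and the tie-corrected normal approximation beyond.
#'
#' @param x,y Numeric samples, each n >= 2.
#' @param gate_x,gate_y Optional precomputed gate results; computed when
#'   `NULL` (samples with n < 3 are treated as non-normal).
#' @param variable Label carried into the report.
#' @param welch Use Welch's unequal-variance t test (default) rather than
#'   the pooled-variance form.
#' @return A `stat_report`.
#' @export
compare_groups <- function(x, y, gate_x = NULL, gate_y = NULL,
                           variable = "x vs y", welch = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 per group")
  safe_gate <- function(v) {
    if (length(v) < 3L || stats::var(v) == 0) "non_normal" else
      normality_gate(v)
  }
  if (is.null(gate_x)) gate_x <- safe_gate(x)
  if (is.null(gate_y)) gate_y <- safe_gate(y)
  if (gate_x == "normal" && gate_y == "normal") {
    ht <- stats::t.test(x, y, var.equal = !welch, alternative = "two.sided")
    return(stat_report(variable,
                       if (welch) "welch_t" else "student_t",
                       ht$statistic, ht$p.value,
                       descriptives(x, "normal"), descriptives(y, "normal")))
  }
  if (stats::var(c(x, y)) == 0) {
    return(stat_report(variable, "mann_whitney", NA_real_, 1,
                       descriptives(x), descriptives(y), degenerate = TRUE))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 20L) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  stat_report(variable, "mann_whitney", ht$statistic, ht$p.value,
              descriptives(x), descriptives(y))
}

#' Paired within-group test (Wilcoxon signed rank)
#'
#' Zero differences are dropped (Wilcoxon convention); the exact null is
#' used for up to 25 untied nonzero pairs, the corrected normal
#' approximation beyond. All-zero differences give a degenerate p = 1.
#'
#' @param before,after Equal-length numeric samples (n >= 2).
#' @param variable Label carried into the report.
#' @return A `stat_report` with `paired = TRUE`.
#' @export
paired_test <- function(before, after, variable = "before vs after") {
  if (length(before) != length(after)) stop("paired samples differ in length")
  ok <- !(is.na(before) | is.na(after))
  before <- before[ok]; after <- after[ok]
  if (length(before) < 2L) stop("need n >= 2 pairs")
  d <- after - before
  nz <- d[d != 0]
  if (!length(nz)) {
    return(stat_report(variable, "wilcoxon_signed_rank", NA_real_, 1,
                       paired = TRUE, degenerate = TRUE))
  }
  exact <- length(nz) <= 25L && !anyDuplicated(abs(nz))
  ht <- suppressWarnings(
    stats::wilcox.test(after, before, paired = TRUE, exact = exact,
                       correct = TRUE, alternative = "two.sided"))
  stat_report(variable, "wilcoxon_signed_rank", ht$statistic, ht$p.value,
              descriptives(before), descriptives(after), paired = TRUE)
}

# all permutations of 1..n as a matrix (n! rows); n <= 8 keeps this small
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Spearman rank correlation with permutation p-value
#'
#' Rho uses average ranks for ties. The two-sided p-value is exact (full
#' enumeration of the n! rank permutations) for n <= 8, and a fixed-seed
#' Monte-Carlo estimate over `n_perm` permutations beyond — exactness
#' matters at this study's n = 14.
#'
#' @param x,y Numeric samples, n >= 4.
#' @param n_perm Monte-Carlo permutations when n > 8.
#' @param seed Seed for the Monte-Carlo branch.
#' @return List with `rho`, `p_value`, `method`.
#' @export
spearman_perm <- function(x, y, n_perm = 1e5, seed = 1L) {
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need n >= 4")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("zero variance in ranks")
  }
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    pm <- all_perms(n)
    rhos <- apply(pm, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (abs(stats::cor(rx, sample(ry))) >= abs(rho) - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_perm)
    method <- "mc_permutation"
  }
  list(rho = rho, p_value = p, method = method, n = n)
}

#' Two-way intraclass correlation coefficient
#'
#' Single-measure ICC from the two-way ANOVA mean squares of an n x k
#' ratings matrix. The default `"agreement"` form is ICC(2,1):
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`;
#' `"consistency"` is ICC(3,1) and `"oneway"` is ICC(1,1).
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns
#'   (n >= 2, k >= 2, no missing cells).
#' @param form ICC variant.
#' @return List with `value`, `form`, mean squares and an `undefined` flag
#'   (zero between-subject variance).
#' @export
icc_two_way <- function(ratings,
                        form = c("agreement", "consistency", "oneway")) {
  form <- match.arg(form)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("missing cells are not supported")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  grand <- mean(ratings)
  rm_ <- rowMeans(ratings); cm_ <- colMeans(ratings)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sse <- sum((ratings - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm_) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  msw <- (ssc + sse) / (n * (k - 1))  # one-way within mean square
  value <- switch(form,
    agreement = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    consistency = (msr - mse) / (msr + (k - 1) * mse),
    oneway = (msr - msw) / (msr + (k - 1) * msw))
  undefined <- ssr == 0
  if (undefined) value <- NA_real_
  list(value = value, form = form, msr = msr, msc = msc, mse = mse,
       undefined = undefined)
}

#' Categorical 2x2 (or r x c) comparison
#'
#' Fisher's exact test (two-sided) when any expected cell count is below 5,
#' otherwise the chi-squared test with continuity correction. For tables
#' larger than 2x2, pairwise 2x2 Fisher tests with Bonferroni correction
#' are attached as post hoc comparisons.
#'
#' @param tab Matrix of nonnegative integer counts.
#' @param variable Label carried into the report.
#' @return A `stat_report`; larger tables carry a `post_hoc` attribute.
#' @export
categorical_test <- function(tab, variable = "counts") {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be nonnegative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("empty margin in contingency table")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ht <- stats::fisher.test(tab, alternative = "two.sided")
    rep_ <- stat_report(variable, "fisher_exact", NA_real_, ht$p.value)
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    rep_ <- stat_report(variable, "chi_squared", ht$statistic, ht$p.value)
  }
  if (nrow(tab) > 2L) {
    pairs <- utils::combn(nrow(tab), 2L)
    ph <- apply(pairs, 2L, function(ij) {
      stats::fisher.test(tab[ij, , drop = FALSE])$p.value
    })
    attr(rep_, "post_hoc") <- data.frame(
      row_a = pairs[1L, ], row_b = pairs[2L, ],
      p_bonferroni = pmin(1, ph * ncol(pairs)))
  }
  rep_
}
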