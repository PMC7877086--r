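# Thin reporting statistics: group comparison, correlation, and
# repeatability measures for ECV studies.

#' Group-comparison and repeatability statistics
#'
#' Computes Welch's two-sample t-test between `group_a` and `group_b`,
#' Pearson correlation between `x` and `y`, and repeatability measures for
#' two paired measurement series (`rep_a`, `rep_b`): Bland-Altman bias and
#' 95% limits of agreement, the two-way random-effects single-measure
#' intraclass correlation ICC(2,1), and the within-subject coefficient of
#' variation (RMS within-subject SD over the grand mean).
#'
#' @param group_a,group_b numeric vectors (n >= 2 each) for the t-test
#' @param x,y optional paired vectors for the correlation
#' @param rep_a,rep_b optional paired repeat measurements
#' @return list with `welch` (t, df, p), optionally `pearson` (r, p),
#'   `bland_altman` (bias, lower, upper), `icc21`, `cov_within_pct`
#' @export
report_stats <- function(group_a, group_b, x = NULL, y = NULL,
                         rep_a = NULL, rep_b = NULL) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  out <- list()
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    out$welch <- list(t = 0, df = NA_real_, p = NA_real_,
                      note = "zero variance in both groups; p undefined")
  } else {
    tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
    out$welch <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                      p = tt$p.value)
  }
  if (!is.null(x) && !is.null(y)) {
    ct <- stats::cor.test(x, y, method = "pearson")
    out$pearson <- list(r = unname(ct$estimate), p = ct$p.value)
  }
  if (!is.null(rep_a) && !is.null(rep_b)) {
    stopifnot(length(rep_a) == length(rep_b))
    d <- rep_a - rep_b
    out$bland_altman <- list(bias = mean(d),
                             lower = mean(d) - 1.96 * stats::sd(d),
                             upper = mean(d) + 1.96 * stats::sd(d))
    out$icc21 <- icc_2_1(cbind(rep_a, rep_b))
    # within-subject SD for two repeats: sd of a pair = |d| / sqrt(2)
    wsd <- sqrt(mean(d^2) / 2)
    out$cov_within_pct <- 100 * wsd / mean(c(rep_a, rep_b))
    out$rms_within_sd <- wsd
  }
  out
}

#' Two-way random effects single-measure intraclass correlation ICC(2,1)
#'
#' @param ratings numeric matrix, rows = subjects, columns = raters/sessions
#' @return ICC(2,1) scalar
#' @export
icc_2_1 <- function(ratings) {
  n <- nrow(ratings)
  k <- ncol(ratings)
  stopifnot(n >= 2, k >= 2)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Cardiac temporal resolution of a binned reconstruction
#'
#' One cardiac period divided into `k_card` bins.
#'
#' @param heart_rate beats per minute
#' @param k_card number of cardiac bins
#' @return bin duration (ms)
#' @export
cardiac_temporal_resolution <- function(heart_rate, k_card) {
  stopifnot(heart_rate > 0, k_card >= 1)
  60000 / heart_rate / k_card
}
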