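# Method-agreement statistics: Wilcoxon signed-rank, Bland-Altman limits of
# agreement, two-way random-effects ICC with interpretation bands, and
# Lilliefors-corrected Kolmogorov-Smirnov normality.

#' Wilcoxon signed-rank test for paired measurements
#'
#' Two-sided test of symmetric zero-median paired differences. Zero differences
#' are dropped (classical handling). The exact signed-rank null is used when
#' the effective sample size is at most 25 and the absolute differences are
#' untied; otherwise the normal approximation with continuity and tie
#' correction is used.
#'
#' @param x Paired differences, or the first member of each pair if `y` given.
#' @param y Optional second member of each pair (differences are `x - y`).
#' @param exact_max Largest effective n for which the exact null is used.
#' @return List with `statistic` (V, sum of positive ranks), `p_value`,
#'   `n_effective` and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  if (!length(d)) {
    stop("all paired differences are zero; signed-rank test undefined",
         call. = FALSE)
  }
  ties <- anyDuplicated(abs(d)) > 0
  use_exact <- length(d) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = use_exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_effective = length(d),
       method = if (use_exact) "exact" else "normal approximation")
}

#' Bland-Altman agreement analysis
#'
#' Mean difference, limits of agreement (mean +/- 1.96 sd of the differences),
#' observed range of differences, and the per-pair (mean, difference) points
#' for plotting.
#'
#' @param single,multi Paired measurements (cm); alternatively `single` may be
#'   a data frame with columns `value_single` and `value_multi`. Differences
#'   are oriented `single - multi`. Incomplete pairs are dropped.
#' @return Object of class `bland_altman`: `n`, `mean_difference`,
#'   `sd_difference`, `loa_low`, `loa_high`, `range_low`, `range_high`,
#'   `outside_loa`, `points` (tibble `mean`, `difference`).
#' @export
bland_altman <- function(single, multi = NULL) {
  if (is.data.frame(single)) {
    multi <- single$value_multi
    single <- single$value_single
  }
  keep <- !is.na(single) & !is.na(multi)
  single <- single[keep]; multi <- multi[keep]
  if (length(single) < 2) {
    stop("Bland-Altman analysis needs at least 2 complete pairs", call. = FALSE)
  }
  d <- single - multi
  m <- (single + multi) / 2
  mu <- mean(d)
  s <- stats::sd(d)
  loa <- mu + c(-1, 1) * 1.96 * s
  structure(list(
    n = length(d), mean_difference = mu, sd_difference = s,
    loa_low = loa[1], loa_high = loa[2],
    range_low = min(d), range_high = max(d),
    outside_loa = sum(d < loa[1] | d > loa[2]),
    points = tibble::tibble(mean = m, difference = d)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean difference %+.2f cm (range %+.2f to %+.2f)\n",
              x$n, x$mean_difference, x$range_low, x$range_high))
  cat(sprintf("  limits of agreement %+.2f to %+.2f cm; %d point(s) outside\n",
              x$loa_low, x$loa_high, x$outside_loa))
  invisible(x)
}

#' Plot a Bland-Altman analysis
#'
#' Difference plot with the mean-difference line and the limits of agreement,
#' mirroring the usual method-comparison layout. Requires ggplot2.
#'
#' @param ba A [bland_altman()] result.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(ba$points, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$mean_difference, linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        colour = "grey50", linetype = "dashed") +
    ggplot2::labs(x = "Mean of the two methods (cm)",
                  y = "Difference, single - multi (cm)")
}

#' Intraclass correlation, two-way random effects, absolute agreement, single
#' measures (ICC(2,1))
#'
#' Computed from the two-way ANOVA mean squares of a subjects x raters matrix;
#' the 95% confidence interval follows the F-distribution method of McGraw and
#' Wong. Chosen for reader studies where each of a fixed random sample of
#' readers rates every subject and absolute closeness of single measurements is
#' the question of interest.
#'
#' @param ratings Numeric matrix or data frame, one row per subject, one column
#'   per rater; at least 5 subjects and 2 raters. Rows with missing values are
#'   dropped.
#' @param conf_level Confidence level for the interval.
#' @return Object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `category`, `n`, `k`.
#' @export
icc_absolute_agreement <- function(ratings, conf_level = 0.95) {
  m <- as.matrix(ratings)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (k < 2) stop("ICC needs at least 2 raters", call. = FALSE)
  if (n < 5) stop("ICC needs at least 5 subjects", call. = FALSE)

  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (ss_rows < 1e-12 || denom <= 0) {
    warning("zero between-subject variance; ICC set to 0")
    icc <- 0
  } else {
    icc <- (msr - mse) / denom
  }

  alpha <- 1 - conf_level
  if (mse < 1e-300) {
    ci <- c(icc, icc)
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    ci_low <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    ci_high <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(ci_low, ci_high)
  }

  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2],
                 category = interpret_icc(max(min(icc, 1), -1)),
                 n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f (95%% CI %.3f-%.3f), %s agreement [n = %d, k = %d]\n",
              x$icc, x$ci_low, x$ci_high, x$category, x$n, x$k))
  invisible(x)
}

#' Interpret an intraclass correlation coefficient
#'
#' Bands: below 0.40 poor, 0.40 to below 0.60 fair, 0.60 to below 0.75 good,
#' 0.75 and above excellent.
#'
#' @param value ICC value(s) in \[-1, 1\].
#' @return Character vector of categories.
#' @export
interpret_icc <- function(value) {
  if (any(!is.na(value) & (value < -1 | value > 1))) {
    stop("ICC values must lie in [-1, 1]", call. = FALSE)
  }
  cut_pts <- c(-Inf, 0.40, 0.60, 0.75, Inf)
  labels <- c("poor", "fair", "good", "excellent")
  as.character(cut(value, breaks = cut_pts, labels = labels, right = FALSE))
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' Tests a sample against a normal distribution with mean and standard
#' deviation estimated from the data (Lilliefors correction).
#'
#' @param sample Numeric vector, at least 5 non-missing, non-constant values.
#' @return Two-sided p-value.
#' @export
ks_normality <- function(sample) {
  x <- sample[!is.na(sample)]
  if (length(x) < 5) {
    stop("normality test needs at least 5 observations", call. = FALSE)
  }
  if (stats::sd(x) < 1e-12) {
    stop("constant sample; normality test undefined", call. = FALSE)
  }
  nortest::lillie.test(x)$p.value
}
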