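#' Pearson correlation with two-sided test
#'
#' Sample Pearson correlation with the two-sided p-value from the t
#' transform on n - 2 degrees of freedom (the test that the regression
#' coefficient equals zero).
#'
#' @param x,y numeric vectors of equal length (n >= 3), non-constant.
#' @return A `stat_result` list: `statistic_name`, `estimate` (r),
#'   `p_value`, `df`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for constant input")
  r <- cor(x, y)
  df <- n - 2
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df)
  }
  structure(list(statistic_name = "pearson_r", estimate = r, p_value = p,
                 df = df, n = n), class = "stat_result")
}

#' Welch's unequal-variance two-tailed t-test
#'
#' Welch statistic with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value; significance is conventionally read at the 5%
#' level but never used to suppress output.
#'
#' @param a,b numeric vectors (each n >= 2, positive variance).
#' @return A `stat_result`: `estimate` (t), `p_value`, `df` (fractional),
#'   `group_summaries` (per-group n, mean, sd and box summary).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0)
    stop("both groups have zero variance; t statistic undefined")
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  structure(list(statistic_name = "welch_t", estimate = tstat, p_value = p,
                 df = df, n = na + nb,
                 group_summaries = list(a = box_summary(a),
                                        b = box_summary(b))),
            class = "stat_result")
}

#' Multiple correlation of volume on displacement and area
#'
#' Ordinary least squares of `dV` on `dy_max` and `area` with intercept;
#' returns the multiple correlation `R = sqrt(R^2)`. Collinear
#' predictors are flagged (attribute `collinear`), with R still
#' computed from the fitted values.
#'
#' @param dV,dy_max,area numeric vectors of equal length (n >= 4).
#' @return A `stat_result`: `estimate` (R), `p_value` (overall F test),
#'   `df` (residual), `n`.
#' @export
multiple_regression_R <- function(dV, dy_max, area) {
  n <- length(dV)
  stopifnot(length(dy_max) == n, length(area) == n)
  if (n < 4) stop("need at least 4 observations")
  fit <- lm(dV ~ dy_max + area)
  sm <- suppressWarnings(summary(fit))  # silence the perfect-fit notice
  R <- sqrt(sm$r.squared)
  collinear <- any(is.na(coef(fit))) || fit$rank < 3
  p <- if (is.null(sm$fstatistic)) NA_real_ else
    pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
       lower.tail = FALSE)
  out <- structure(list(statistic_name = "multiple_R", estimate = R,
                        p_value = unname(p), df = fit$df.residual, n = n),
                   class = "stat_result")
  attr(out, "collinear") <- isTRUE(collinear)
  out
}

#' Box-plot summary with 1.5 IQR whiskers
#'
#' Median and quartiles by linear interpolation of order statistics;
#' whiskers extend to the most extreme data points within 1.5 times the
#' inter-quartile range of the quartiles; points beyond are listed as
#' outliers.
#'
#' @param values numeric vector (n >= 1).
#' @return A list: `n`, `mean`, `sd`, `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `outliers`.
#' @export
box_summary <- function(values) {
  stopifnot(length(values) >= 1)
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(n = length(values),
       mean = mean(values),
       sd = if (length(values) > 1) sd(values) else 0,
       median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = values[!inside])
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$statistic_name, ": estimate ", format(x$estimate, digits = 4),
      ", p = ", format(x$p_value, digits = 3),
      ", df = ", format(x$df, digits = 4), ", n = ", x$n, "\n", sep = "")
  invisible(x)
}
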