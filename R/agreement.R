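# Agreement and association statistics: ordinary least squares with
# t-based confidence intervals, Pearson correlation, paired t-test,
# Bland-Altman limits of agreement, intraclass correlation (two-way,
# absolute agreement, single measurement) and the Kruskal-Wallis
# rank test. All computed from explicit closed forms so they can be checked
# against independent brute-force oracles.

#' Simple linear regression with confidence intervals
#'
#' Least-squares fit of `y ~ x` with 95% t-based confidence intervals
#' (n - 2 degrees of freedom) for slope and intercept.
#'
#' @param x,y numeric vectors, `length(x) >= 3`; `x` must not be constant.
#' @param conf confidence level.
#' @return An object of class `regression_fit`: `slope`, `intercept`,
#'   `slope_ci`, `intercept_ci`, `pcc`, `r_squared`, `p_value` (slope,
#'   two-sided), `n`.
#' @export
fit_ols <- function(x, y, conf = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) stop("at least 3 points required")
  if (sd(x) == 0) stop("degenerate-regressor error: x is constant")
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  se_slope <- sqrt(s2 / sxx)
  se_int <- sqrt(s2 * (1 / n + mean(x)^2 / sxx))
  tq <- qt(1 - (1 - conf) / 2, df = n - 2)
  r <- if (sd(y) == 0) NA_real_ else sxy / sqrt(sxx * sum((y - mean(y))^2))
  tstat <- if (se_slope > 0) slope / se_slope else Inf
  structure(list(slope = slope, intercept = intercept,
                 slope_ci = slope + c(-1, 1) * tq * se_slope,
                 intercept_ci = intercept + c(-1, 1) * tq * se_int,
                 pcc = r, r_squared = if (is.na(r)) NA_real_ else r^2,
                 p_value = 2 * pt(-abs(tstat), df = n - 2), n = n),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): slope %.3f (95%%CI %.3f-%.3f), intercept %.3f (95%%CI %.3f-%.3f)\n  PCC %.3f, R^2 %.3f, p = %s\n",
              x$n, x$slope, x$slope_ci[1], x$slope_ci[2], x$intercept,
              x$intercept_ci[1], x$intercept_ci[2], x$pcc, x$r_squared,
              format(x$p_value, digits = 3)))
  invisible(x)
}

#' Pearson correlation with two-sided t-based p-value
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) stop("at least 3 points required")
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate error: constant input to correlation")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Paired t-test on two equal-length measurement vectors
#'
#' Classical paired t on the differences `a - b`. A zero-variance difference
#' vector is degenerate, except for the exact-agreement case (all
#' differences zero), which reports t = 0, p = 1.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return list with `mean_difference`, `t`, `p`, `n`.
#' @export
paired_t <- function(a, b) {
  n <- length(a)
  stopifnot(length(b) == n, n >= 2L)
  d <- a - b
  s <- sd(d)
  if (s == 0) {
    if (all(d == 0)) return(list(mean_difference = 0, t = 0, p = 1, n = n))
    stop("degenerate error: zero-variance non-zero differences")
  }
  t <- mean(d) / (s / sqrt(n))
  list(mean_difference = mean(d), t = t, p = 2 * pt(-abs(t), df = n - 1), n = n)
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as reference minus comparison (`a - b`); limits of
#' agreement are the mean difference plus/minus 1.96 times the SD of the
#' differences.
#'
#' @param a reference measurements.
#' @param b comparison measurements (equal length >= 2).
#' @return An `agreement_report` with `mean_difference`, `sd_difference`,
#'   `loa_lower`, `loa_upper`, `n`.
#' @export
bland_altman <- function(a, b) {
  n <- length(a)
  stopifnot(length(b) == n, n >= 2L)
  d <- a - b
  m <- mean(d); s <- sd(d)
  structure(list(mean_difference = m, sd_difference = s,
                 loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s, n = n),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  if (!is.null(x$icc))
    cat(sprintf("ICC (%s) = %.3f, n = %d pairs\n", x$icc_model, x$icc, x$n))
  else
    cat(sprintf("Bland-Altman (n = %d): mean difference %.2f, limits of agreement [%.2f, %.2f]\n",
                x$n, x$mean_difference, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Intraclass correlation coefficient for two raters
#'
#' Two-way model computed from the ANOVA mean squares. The default and only
#' implemented form is absolute agreement, single measurement (ICC(A,1) of
#' McGraw & Wong; SPSS "two-way mixed, absolute agreement, single
#' measures"), the form matching a Bland-Altman absolute-difference
#' analysis with fixed raters. The model label is always carried in the
#' result because reports often omit it.
#'
#' @param a,b paired ratings, equal length >= 3.
#' @param model ICC model label; only `"A1"` is available.
#' @return An `agreement_report` with `icc`, `icc_model`, `n`.
#' @export
icc <- function(a, b, model = "A1") {
  model <- match.arg(model)
  n <- length(a)
  stopifnot(length(b) == n, n >= 3L)
  k <- 2L
  x <- cbind(a, b)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  if (var(row_m) == 0)
    stop("undefined-ICC error: zero between-subject variance")
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  val <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  structure(list(icc = val, icc_model = "two-way mixed, absolute agreement, single measures (A,1)",
                 n = n), class = "agreement_report")
}

#' Kruskal-Wallis rank test (non-parametric one-way ANOVA)
#'
#' Rank-based H statistic with tie correction and chi-square p-value.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, 1L) > 0L))
  x <- unlist(groups)
  if (length(unique(x)) == 1L)
    stop("degenerate error: all values identical")
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / corr
  list(H = H, p = pchisq(H, df = length(groups) - 1, lower.tail = FALSE),
       df = length(groups) - 1)
}
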