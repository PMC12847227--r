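#' Intraclass correlation, two-way model, absolute agreement, single measure
#'
#' ICC(A,1) in the McGraw-Wong taxonomy: a two-way (subjects x methods)
#' mean-squares decomposition where systematic offsets between methods count
#' against agreement. `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE)/n)`
#' with `MSR` the between-subject, `MSC` the between-method, and `MSE` the
#' residual mean square. The F statistic is `MSR/MSE`; the confidence interval
#' uses the McGraw-Wong closed form with Satterthwaite df.
#'
#' @param m1,m2 Paired measurements (one per subject by two methods), or a
#'   two-column matrix in `m1`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List of class `icc_result`: `icc, ci, f, df1, df2, p`, and the
#'   mean squares `msr, msc, mse`.
#' @export
icc_absolute <- function(m1, m2 = NULL, conf_level = 0.95) {
  x <- if (is.null(m2)) as.matrix(m1) else cbind(m1, m2)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop_sw("need at least 3 complete pairs")
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 0) stop_sw("zero between-subject variance")
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  f <- msr / mse
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # McGraw & Wong CI for ICC(A,1)
  alpha <- 1 - conf_level
  fj <- msc / mse
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * fj + b)^2 /
    (a^2 * fj^2 / (k - 1) + b^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(icc = icc, ci = c(lower, upper), f = f, df1 = df1,
                 df2 = df2, p = p, msr = msr, msc = msc, mse = mse),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f [%.3f, %.3f]; F(%d, %.1f) = %.2f, p = %.3g\n",
              x$icc, x$ci[1], x$ci[2], x$df1, x$df2, x$f, x$p))
  invisible(x)
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences `d = m1 - m2`; bias is their mean, limits of agreement
#' `bias +/- 1.96 * SD(d)`.
#'
#' @param m1,m2 Paired measurements.
#' @return List: `bias, loa_low, loa_high, sd_diff, differences`.
#' @export
bland_altman <- function(m1, m2) {
  ok <- !is.na(m1) & !is.na(m2)
  d <- m1[ok] - m2[ok]
  if (length(d) < 2) stop_sw("need at least 2 complete pairs")
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, differences = d)
}

#' Percentage error of a limits-of-agreement interval
#'
#' Width of the limits of agreement divided by the grand mean of the
#' reference method, times 100.
#'
#' @param loa_low,loa_high Limits of agreement.
#' @param grand_mean Mean of the reference measurements (non-zero).
#' @return Percentage.
#' @export
percentage_error <- function(loa_low, loa_high, grand_mean) {
  if (grand_mean == 0) stop_sw("grand mean must be non-zero")
  100 * (loa_high - loa_low) / grand_mean
}

#' Counts of differences beyond a substantive limit
#'
#' Partition of paired differences into `D < -limit`, `-limit <= D <= limit`
#' (inclusive bounds), and `D > limit`.
#'
#' @param differences Numeric differences.
#' @param limit Positive threshold (default 5 T-points, i.e. half an SD).
#' @return Data frame with rows `below`, `within`, `above` and columns
#'   `n`, `percent`.
#' @export
exceedance_counts <- function(differences, limit = 5) {
  if (limit <= 0) stop_sw("limit must be > 0")
  d <- differences[!is.na(differences)]
  n <- c(below = sum(d < -limit),
         within = sum(d >= -limit & d <= limit),
         above = sum(d > limit))
  data.frame(n = as.integer(n), percent = 100 * n / length(d),
             row.names = names(n))
}

#' Full agreement report between two scoring methods
#'
#' @param m1 Candidate method scores.
#' @param m2 Reference method scores (grand mean for the percentage error).
#' @param limit Substantive-difference limit (default 5).
#' @return List of class `agreement_report`: `icc`, `bias`, `loa_low`,
#'   `loa_high`, `perc_err`, `counts`, `n`.
#' @export
agreement_report <- function(m1, m2, limit = 5) {
  ok <- !is.na(m1) & !is.na(m2)
  icc <- icc_absolute(m1[ok], m2[ok])
  ba <- bland_altman(m1[ok], m2[ok])
  structure(list(
    icc = icc, bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
    perc_err = percentage_error(ba$loa_low, ba$loa_high, mean(m2[ok])),
    counts = exceedance_counts(ba$differences, limit), n = sum(ok)
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  print(x$icc)
  cat(sprintf("bias %.2f, LoA [%.2f, %.2f], percentage error %.2f%%\n",
              x$bias, x$loa_low, x$loa_high, x$perc_err))
  print(round(x$counts, 2))
  invisible(x)
}
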