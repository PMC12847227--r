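#' Raw summed scores for a response matrix
#'
#' Sums item responses per respondent. Missing-item policy:
#' `"complete-case"` (default) scores respondents with any missing item as
#' `NA` and reports how many were dropped via a message; `"person-mean"`
#' imputes the respondent's own item mean when at most `max_impute` items are
#' missing, otherwise the respondent is still scored `NA`.
#'
#' @param data Response data frame (items auto-detected as `item01...`).
#' @param policy `"complete-case"` or `"person-mean"`.
#' @param max_impute Maximum missing items tolerated under `"person-mean"`.
#' @return Numeric vector of raw scores (NA where the policy excludes).
#' @examples
#' sum_score(data.frame(item01 = 1:2, item02 = c(7, 3)))
#' @export
sum_score <- function(data, policy = c("complete-case", "person-mean"),
                      max_impute = 2L) {
  policy <- match.arg(policy)
  items <- item_columns(data)
  if (length(items) < 2) stop_sw("need at least 2 items")
  x <- as.matrix(data[, items, drop = FALSE])
  storage.mode(x) <- "double"
  n_miss <- rowSums(is.na(x))
  rs <- rowSums(x)
  if (policy == "person-mean") {
    fix <- which(n_miss > 0 & n_miss <= max_impute)
    if (length(fix)) {
      rs[fix] <- rowMeans(x[fix, , drop = FALSE], na.rm = TRUE) * length(items)
    }
    dropped <- sum(n_miss > max_impute)
  } else {
    dropped <- sum(n_miss > 0)
  }
  if (dropped > 0) {
    message(sprintf("sum_score: %d respondent(s) scored NA under '%s' policy",
                    dropped, policy))
  }
  rs
}

#' Descriptive statistics with normality check
#'
#' Mean, sample SD (n-1), skewness, and excess kurtosis using the moment
#' (biased, "g") estimators by default, or the Fisher-Pearson adjusted ("G")
#' estimators. Shapiro-Wilk W is delegated to [stats::shapiro.test()]; above
#' that routine's n = 5000 validity cap a fixed-seed subsample of 5000 is used.
#' A constant sample flags skewness/kurtosis as undefined (`NA` plus a
#' `degenerate` flag) rather than propagating NaN.
#'
#' @param values Numeric vector (NAs dropped).
#' @param type `"moment"` (g1, g2) or `"adjusted"` (G1, G2).
#' @param shapiro Compute W? Default `TRUE` when `3 <= n`.
#' @return List of class `descriptive_stats`: `n, M, SD, skew, kurt, W,
#'   degenerate`.
#' @export
descriptives <- function(values, type = c("moment", "adjusted"),
                         shapiro = TRUE) {
  type <- match.arg(type)
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 1) stop_sw("need at least one observation")
  M <- mean(x)
  SD <- if (n >= 2) stats::sd(x) else NA_real_
  degenerate <- n >= 2 && SD == 0
  skew <- kurt <- NA_real_
  if (n >= 3 && !degenerate) {
    m2 <- mean((x - M)^2)
    m3 <- mean((x - M)^3)
    m4 <- mean((x - M)^4)
    g1 <- m3 / m2^1.5
    g2 <- m4 / m2^2 - 3
    if (type == "moment") {
      skew <- g1
      kurt <- g2
    } else {
      skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
      kurt <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
    }
  }
  W <- NA_real_
  if (shapiro && n >= 3 && !degenerate) {
    xs <- x
    if (n > 5000) {
      old <- .Random.seed_save()
      set.seed(20260910)
      xs <- sample(x, 5000)
      .Random.seed_restore(old)
    }
    W <- unname(stats::shapiro.test(xs)$statistic)
  }
  structure(list(n = n, M = M, SD = SD, skew = skew, kurt = kurt, W = W,
                 degenerate = degenerate),
            class = "descriptive_stats")
}

# stash/restore the RNG state so internal subsampling does not disturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.descriptive_stats <- function(x, ...) {
  cat(sprintf("n = %d, M = %.3f, SD = %.3f, skew = %.3f, kurt = %.3f, W = %.3f\n",
              x$n, x$M, x$SD, x$skew, x$kurt, x$W))
  invisible(x)
}

#' Cronbach's alpha internal consistency
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))` over
#' complete respondents.
#'
#' @param data Response data frame with >= 2 item columns.
#' @return Alpha in `(-Inf, 1]`.
#' @export
cronbach_alpha <- function(data) {
  items <- item_columns(data)
  if (length(items) < 2) stop_sw("need at least 2 items")
  x <- as.matrix(data[, items, drop = FALSE])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 2) stop_sw("need at least 2 complete respondents")
  k <- ncol(x)
  total_var <- stats::var(rowSums(x))
  if (total_var == 0) stop_sw("total-score variance is zero")
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / total_var)
}

#' McDonald's omega from standardized loadings
#'
#' `omega = (sum lambda)^2 / ((sum lambda)^2 + sum(1 - lambda^2))` for a
#' single-factor model with standardized loadings.
#'
#' @param loadings Standardized loadings, each strictly inside (-1, 1).
#' @return Omega in `[0, 1]`.
#' @seealso [grm_loadings()] to convert GRM discriminations to loadings.
#' @export
mcdonald_omega <- function(loadings) {
  if (any(abs(loadings) >= 1)) stop_sw("loadings must satisfy |lambda| < 1")
  s <- sum(loadings)
  s^2 / (s^2 + sum(1 - loadings^2))
}

#' Standardized loadings implied by GRM discriminations
#'
#' Logistic discriminations are rescaled to the probit metric with the
#' conventional constant 1.702, then converted:
#' `lambda = (a/1.702) / sqrt(1 + (a/1.702)^2)`.
#'
#' @param a Positive discriminations on the logistic metric.
#' @return Loadings in (0, 1).
#' @export
grm_loadings <- function(a) {
  astar <- a / 1.702
  astar / sqrt(1 + astar^2)
}

#' Pooled-SD Cohen's d with Welch t-test from summary statistics
#'
#' `d = (M1 - M2) / s_p` with the pooled SD
#' `s_p^2 = ((n1-1) SD1^2 + (n2-1) SD2^2) / (n1 + n2 - 2)`; the t statistic and
#' Satterthwaite df use Welch's unequal-variance form. The d confidence
#' interval is the normal approximation
#' `d +/- 1.96 * sqrt((n1+n2)/(n1*n2) + d^2/(2(n1+n2)))`.
#'
#' @param g1,g2 `descriptive_stats` objects, or lists with `M`, `SD`, `n`.
#' @return List of class `group_contrast`: `d, d_ci, t, df, p`.
#' @examples
#' cohens_d_welch(list(M = 61.72, SD = 8.76, n = 11789),
#'                list(M = 51.14, SD = 14.20, n = 9983))
#' @export
cohens_d_welch <- function(g1, g2) {
  if (g1$n < 2 || g2$n < 2) stop_sw("both groups need n >= 2")
  n1 <- g1$n; n2 <- g2$n
  sp2 <- ((n1 - 1) * g1$SD^2 + (n2 - 1) * g2$SD^2) / (n1 + n2 - 2)
  if (sp2 == 0) stop_sw("pooled SD is zero")
  d <- (g1$M - g2$M) / sqrt(sp2)
  se_d <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  v1 <- g1$SD^2 / n1; v2 <- g2$SD^2 / n2
  t <- (g1$M - g2$M) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(d = d, d_ci = d + c(-1, 1) * stats::qnorm(0.975) * se_d,
                 t = t, df = df, p = p),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("d = %.2f [%.2f, %.2f]; Welch t(%.2f) = %.2f, p = %.3g\n",
              x$d, x$d_ci[1], x$d_ci[2], x$df, x$t, x$p))
  invisible(x)
}

#' Mid-rank percentile rank against a reference sample
#'
#' `PR = 100 * (#below + 0.5 * #equal) / n`: the percentage of the reference
#' group scoring below the value, plus half of those scoring exactly equal.
#'
#' @param score Scalar or vector of scores to rank.
#' @param reference Non-empty numeric reference sample.
#' @return Percentile rank(s) in `[0, 100]`.
#' @examples
#' percentile_rank(2, c(1, 2, 3))  # 50
#' @export
percentile_rank <- function(score, reference) {
  if (length(reference) == 0) stop_sw("reference sample is empty")
  reference <- reference[!is.na(reference)]
  if (length(reference) == 0) stop_sw("reference sample is all NA")
  n <- length(reference)
  vapply(score, function(s) {
    if (is.na(s)) return(NA_real_)
    100 * (sum(reference < s) + 0.5 * sum(reference == s)) / n
  }, numeric(1))
}
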