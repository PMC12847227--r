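#' Closed-form raw-score conversion formulas
#'
#' A `conversion_formula` stores either a polynomial (degree <= 5,
#' coefficients `c0..cd` in ascending powers) or a Weibull-type sigmoid
#' `y = L + (U - L) * (1 - exp(-exp(s * (log(rs + eps) - log(m)))))` with
#' `eps = 1e-4`, together with its domain and fit diagnostics.
#'
#' @param kind `"polynomial"` or `"weibull-sigmoid"`.
#' @param coefficients Ascending-power coefficients (polynomial) or
#'   `c(L, U, s, m)` (sigmoid, `U > L`).
#' @param domain Length-2 raw-score range.
#' @param sigma,r_squared Optional fit diagnostics.
#' @param converged Optional convergence flag for iteratively fitted forms.
#' @return An object of class `conversion_formula`.
#' @export
conversion_formula <- function(kind = c("polynomial", "weibull-sigmoid"),
                               coefficients, domain,
                               sigma = NA_real_, r_squared = NA_real_,
                               converged = NA) {
  kind <- match.arg(kind)
  if (kind == "polynomial" && length(coefficients) > 6) {
    stop_sw("polynomial degree must be <= 5")
  }
  if (kind == "weibull-sigmoid") {
    if (length(coefficients) != 4) stop_sw("sigmoid needs (L, U, s, m)")
    if (coefficients[2] <= coefficients[1]) {
      stop_sw("sigmoid upper asymptote must exceed the lower")
    }
  }
  if (length(domain) != 2 || domain[2] < domain[1]) {
    stop_sw("domain must be a non-empty [min, max]")
  }
  structure(list(kind = kind, coefficients = unname(coefficients),
                 domain = as.numeric(domain), sigma = sigma,
                 r_squared = r_squared, converged = converged),
            class = "conversion_formula")
}

#' @export
print.conversion_formula <- function(x, ...) {
  cat(sprintf("%s formula on [%g, %g]\n", x$kind, x$domain[1], x$domain[2]))
  if (x$kind == "polynomial") {
    cat("  coefficients (c0..):", signif(x$coefficients, 6), "\n")
  } else {
    cat(sprintf("  L = %g, U = %g, shape = %g, scale = %g\n",
                x$coefficients[1], x$coefficients[2],
                x$coefficients[3], x$coefficients[4]))
  }
  if (!is.na(x$r_squared)) {
    cat(sprintf("  residual SD %.4f, R-squared %.4f\n", x$sigma, x$r_squared))
  }
  invisible(x)
}

#' Fit a polynomial raw-score conversion by least squares
#'
#' Ordinary least squares over the supplied per-respondent (rs, target)
#' pairs -- not per-unique-rs means, so heavily populated scores weigh more,
#' matching how scatterplot-based nonlinear regression treats the data. Set
#' `collapse = TRUE` to fit on unique-rs means instead.
#'
#' @param rs,target Paired observations.
#' @param degree Polynomial degree (<= 5).
#' @param collapse Fit on means per unique raw score instead of raw pairs.
#' @return A [conversion_formula()] of kind `"polynomial"`.
#' @export
fit_polynomial <- function(rs, target, degree = 5L, collapse = FALSE) {
  ok <- !is.na(rs) & !is.na(target)
  rs <- rs[ok]; target <- target[ok]
  if (degree > 5) stop_sw("degree must be <= 5")
  if (length(unique(rs)) < degree + 2) {
    stop_sw("need at least degree + 2 distinct raw scores")
  }
  if (collapse) {
    target <- tapply(target, rs, mean)
    rs <- as.numeric(names(target))
    target <- as.numeric(target)
  }
  X <- outer(rs, 0:degree, `^`)
  fit <- stats::lm.fit(X, target)
  if (fit$rank < degree + 1) {
    stop_sw("rank-deficient polynomial design (rank ", fit$rank,
            " < ", degree + 1, ")")
  }
  res <- fit$residuals
  dfres <- length(target) - (degree + 1)
  conversion_formula(
    "polynomial", fit$coefficients, range(rs),
    sigma = if (dfres > 0) sqrt(sum(res^2) / dfres) else NA_real_,
    r_squared = 1 - sum(res^2) / sum((target - mean(target))^2),
    converged = TRUE
  )
}

#' Fit a Weibull-type sigmoid for raw score to percentile rank
#'
#' Nonlinear least squares for
#' `y = L + (U - L) * (1 - exp(-exp(s * (log(rs + 1e-4) - log(m)))))`,
#' the natural shape for a cumulative-percentage target. Starting values:
#' `L = min(y)`, `U = max(y)`, `m` at the raw score nearest the 63.2% level
#' of the target range, `s = 5`. Falls back from [stats::nls()] (port
#' algorithm) to Nelder-Mead least squares if necessary; non-convergence is
#' flagged, best-so-far parameters returned.
#'
#' @param rs,target Paired observations; targets in `[0, 100]`.
#' @return A [conversion_formula()] of kind `"weibull-sigmoid"`.
#' @export
fit_weibull_sigmoid <- function(rs, target) {
  ok <- !is.na(rs) & !is.na(target)
  rs <- rs[ok]; target <- target[ok]
  if (any(target < 0 | target > 100)) stop_sw("targets must be in [0, 100]")
  if (length(unique(rs)) < 5) stop_sw("need at least 5 distinct raw scores")
  eps <- 1e-4
  L0 <- min(target); U0 <- max(max(target), L0 + 1)
  lvl <- L0 + (U0 - L0) * (1 - exp(-1))
  m0 <- rs[which.min(abs(target - lvl))]
  start <- list(L = L0, U = U0, s = 5, m = max(m0, min(rs[rs > 0])))
  form <- target ~ L + (U - L) * (1 - exp(-exp(s * (log(rs + eps) - log(m)))))
  df <- data.frame(rs = rs, target = target)
  fit <- tryCatch(
    stats::nls(form, data = df, start = start, algorithm = "port",
               lower = c(L = -10, U = 10, s = 0.1, m = min(rs[rs > 0]) / 2),
               upper = c(L = 50, U = 200, s = 100, m = max(rs) * 2),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    converged <- fit$convInfo$isConv
  } else {
    sse <- function(p) {
      yhat <- p[1] + (p[2] - p[1]) *
        (1 - exp(-exp(p[3] * (log(rs + eps) - log(max(p[4], 1e-6))))))
      sum((target - yhat)^2)
    }
    opt <- stats::optim(unlist(start), sse,
                        control = list(maxit = 5000, reltol = 1e-12))
    cf <- opt$par
    converged <- opt$convergence == 0
  }
  yhat <- cf[1] + (cf[2] - cf[1]) *
    (1 - exp(-exp(cf[3] * (log(rs + eps) - log(cf[4])))))
  res <- target - yhat
  if (!converged) warning("sigmoid fit did not fully converge; ",
                          "best-so-far parameters returned")
  conversion_formula(
    "weibull-sigmoid", cf, range(rs),
    sigma = sqrt(sum(res^2) / max(length(res) - 4, 1)),
    r_squared = 1 - sum(res^2) / sum((target - mean(target))^2),
    converged = converged
  )
}

#' Evaluate a conversion formula at raw scores
#'
#' Exact arithmetic evaluation of the stored form; raw scores outside the
#' stored domain are evaluated with a warning (extrapolation).
#'
#' @param formula A [conversion_formula()].
#' @param rs Raw score(s).
#' @return Converted value(s).
#' @export
evaluate_formula <- function(formula, rs) {
  if (!inherits(formula, "conversion_formula")) {
    stop_sw("'formula' must be a conversion_formula")
  }
  outside <- rs < formula$domain[1] | rs > formula$domain[2]
  if (any(outside, na.rm = TRUE)) {
    warning("evaluating outside the fitted domain [",
            formula$domain[1], ", ", formula$domain[2], "]")
  }
  co <- formula$coefficients
  if (formula$kind == "polynomial") {
    y <- rep(co[length(co)], length(rs))
    for (i in rev(seq_len(length(co) - 1))) y <- y * rs + co[i]  # Horner
    y
  } else {
    co[1] + (co[2] - co[1]) *
      (1 - exp(-exp(co[3] * (log(rs + 1e-4) - log(co[4])))))
  }
}

#' Build a rounded crosswalk table over a raw-score range
#'
#' One row per integer raw score with the regressed IRT T-score (1 decimal,
#' half away from zero) and percentile ranks for the two reference groups
#' (integers, clipped to `[0, 100]`). PR columns come from empirical mid-rank
#' percentile ranks when reference samples are supplied (`pr_source =
#' "empirical"`, the default in that case), else from the fitted formulas.
#' Monotonicity of every column is enforced by isotonic (cumulative-maximum)
#' adjustment; any adjusted cells are reported in attribute
#' `"monotonicity_fixes"`.
#'
#' @param t_formula [conversion_formula()] for raw score to T.
#' @param pr_formulas Named list with elements `population` and `clinical`,
#'   each a [conversion_formula()] for raw score to percentile rank.
#' @param rs_range Integer raw-score range, default `c(12, 84)`.
#' @param pr_data Optional named list of reference raw-score samples
#'   (`population`, `clinical`) for empirical PR columns.
#' @param pr_source `"empirical"` or `"formula"`.
#' @return Data frame `rs, t_irt, pr_population, pr_clinical` of class
#'   `crosswalk_table`.
#' @export
build_crosswalk <- function(t_formula, pr_formulas, rs_range = c(12, 84),
                            pr_data = NULL,
                            pr_source = if (!is.null(pr_data)) "empirical"
                                        else "formula") {
  pr_source <- match.arg(pr_source, c("empirical", "formula"))
  rs <- seq.int(rs_range[1], rs_range[2])
  all_f <- c(list(t_formula), unname(pr_formulas))
  lo <- max(vapply(all_f, function(f) f$domain[1], numeric(1)))
  hi <- min(vapply(all_f, function(f) f$domain[2], numeric(1)))
  if (lo > rs_range[2] || hi < rs_range[1]) {
    stop_sw("formula domains do not overlap the requested range")
  }
  t_raw <- suppressWarnings(evaluate_formula(t_formula, rs))
  pr_raw <- lapply(c("population", "clinical"), function(gr) {
    if (pr_source == "empirical") {
      if (is.null(pr_data[[gr]])) stop_sw("no reference data for ", gr)
      percentile_rank(rs, pr_data[[gr]])
    } else {
      suppressWarnings(evaluate_formula(pr_formulas[[gr]], rs))
    }
  })
  tab <- data.frame(
    rs = rs,
    t_irt = round_half_away(t_raw, 1),
    pr_population = pmin(pmax(round_half_away(pr_raw[[1]]), 0), 100),
    pr_clinical = pmin(pmax(round_half_away(pr_raw[[2]]), 0), 100)
  )
  fixes <- list()
  for (col in c("t_irt", "pr_population", "pr_clinical")) {
    iso <- cummax(tab[[col]])
    changed <- which(iso != tab[[col]])
    if (length(changed)) {
      fixes[[col]] <- rs[changed]
      message("build_crosswalk: isotonic adjustment of ", col,
              " at rs = ", paste(rs[changed], collapse = ", "))
      tab[[col]] <- iso
    }
  }
  attr(tab, "monotonicity_fixes") <- fixes
  attr(tab, "pr_source") <- pr_source
  class(tab) <- c("crosswalk_table", "data.frame")
  tab
}

#' Write / read a crosswalk table as delimited text
#'
#' @param table A `crosswalk_table`.
#' @param path CSV path.
#' @return `write_crosswalk` returns `path` invisibly; `read_crosswalk`
#'   returns the table.
#' @export
write_crosswalk <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_crosswalk
#' @export
read_crosswalk <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("crosswalk_table", "data.frame")
  tab
}
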