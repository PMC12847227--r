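#' Default item parameters for a MANSA-like 12-item instrument
#'
#' A versioned fixture of graded-response-model parameters for twelve 7-category
#' items, calibrated by Monte Carlo so that summed scores of the reference
#' (general population) group are high and left-skewed (mean near 62, SD near 9,
#' skewness near -0.8) while the clinical group -- lower latent mean, wider
#' latent spread -- produces a flatter distribution with mean near 51 and SD
#' near 14. These are calibration targets typical of quality-of-life norms, not
#' published item parameters (none exist for this instrument).
#'
#' @return A [grm_parameters] object with 12 items, 6 thresholds each, and two
#'   groups `population` (fixed N(0,1)) and `clinical`.
#' @export
default_mansa_params <- function() {
  path <- system.file("extdata", "mansa_grm_params_synthetic.csv",
                      package = "scorewalk")
  if (!nzchar(path)) stop_sw("bundled parameter fixture not found")
  read_grm_parameters(path)
}

#' Simulation configuration for two-group graded response data
#'
#' @param n_per_group Respondents per group (>= 1). Either a single count used
#'   for every group or a named vector matching the groups in `item_params`.
#' @param item_params A [grm_parameters] object; its `groups` table supplies the
#'   per-group latent means and SDs (reference group fixed at 0/1).
#' @param seed Integer master seed; per-group substreams are derived from it
#'   deterministically.
#' @param missing_rate Proportion of item responses set missing completely at
#'   random, in `[0, 1)`. Default 0.
#' @param covariates If `TRUE`, attach synthetic `age` (uniform 18-80) and
#'   `gender` columns for stratified-norm demonstrations.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_per_group, item_params = default_mansa_params(),
                              seed = 1L, missing_rate = 0,
                              covariates = FALSE) {
  if (!inherits(item_params, "grm_parameters")) {
    stop_sw("'item_params' must be a grm_parameters object")
  }
  groups <- item_params$groups$group
  if (length(n_per_group) == 1L && is.null(names(n_per_group))) {
    n_per_group <- stats::setNames(rep(n_per_group, length(groups)), groups)
  }
  if (!all(groups %in% names(n_per_group))) {
    stop_sw("n_per_group must cover every group: ",
            paste(groups, collapse = ", "))
  }
  n_per_group <- n_per_group[groups]
  if (any(n_per_group < 1)) stop_sw("n_per_group must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_sw("missing_rate must be in [0, 1)")
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 item_params = item_params, seed = as.integer(seed),
                 missing_rate = missing_rate, covariates = isTRUE(covariates)),
            class = "sim_config")
}

#' Simulate item responses from a multigroup graded response model
#'
#' Draws latent traits per group from its normal prior, then samples each item
#' response by inverse transform over the GRM boundary curves
#' `P*(k) = logistic(a * (theta - b[k-1]))`: category `k` occurs with
#' probability `P*(k) - P*(k+1)`. Identical seeds give bit-identical output.
#'
#' @param config A [simulation_config()] object.
#' @return Data frame with columns `item01..itemNN` (integer categories
#'   `1..K`), `group`, and optional `age`/`gender`; item parameters attached as
#'   attribute `"item_params"` and latent traits as attribute `"theta"`.
#' @export
generate_grm_responses <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_sw("'config' must come from simulation_config()")
  }
  p <- config$item_params
  K <- p$n_categories
  n_items <- length(p$a)
  out <- vector("list", nrow(p$groups))
  for (g in seq_len(nrow(p$groups))) {
    n <- config$n_per_group[g]
    # deterministic substream per group, kept well inside 32-bit range
    set.seed((config$seed %% 1000003L) * 1009L + g)
    theta <- stats::rnorm(n, p$groups$mean[g], p$groups$sd[g])
    resp <- matrix(NA_integer_, n, n_items)
    for (j in seq_len(n_items)) {
      # boundary probs at each theta: n x (K-1), decreasing across k
      bound <- vapply(p$b[j, ], function(bk) stats::plogis(p$a[j] * (theta - bk)),
                      numeric(n))
      u <- stats::runif(n)
      resp[, j] <- 1L + rowSums(matrix(u < bound, nrow = n))
    }
    if (config$missing_rate > 0) {
      drop <- stats::runif(n * n_items) < config$missing_rate
      resp[matrix(drop, n, n_items)] <- NA_integer_
    }
    df <- as.data.frame(resp)
    names(df) <- p$items
    df$group <- p$groups$group[g]
    if (config$covariates) {
      df$age <- floor(stats::runif(n, 18, 81))
      df$gender <- sample(c("female", "male"), n, replace = TRUE)
    }
    attr(df, "theta") <- theta
    out[[g]] <- df
  }
  res <- do.call(rbind, lapply(out, function(d) { attr(d, "theta") <- NULL; d }))
  rownames(res) <- NULL
  attr(res, "theta") <- unlist(lapply(out, attr, "theta"), use.names = FALSE)
  attr(res, "item_params") <- p
  res
}

#' Write / read a respondent-by-item response matrix as delimited text
#'
#' Comma-separated, UTF-8, header row; items `item01..itemNN`, a `group`
#' column, optional `age`/`gender`. `write_response_matrix` also writes a
#' sidecar `<path>.meta` echoing the simulation parameters when present.
#'
#' @param data Response data frame.
#' @param path CSV path.
#' @return `write_response_matrix` returns `path` invisibly;
#'   `read_response_matrix` returns the data frame.
#' @export
write_response_matrix <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE, na = "")
  p <- attr(data, "item_params")
  if (!is.null(p)) write_grm_parameters(p, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_response_matrix
#' @export
read_response_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  items <- item_columns(df)
  for (j in items) df[[j]] <- as.integer(df[[j]])
  df
}
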