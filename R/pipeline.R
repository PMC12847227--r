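#' Pipeline configuration
#'
#' Validated settings for the end-to-end norming run.
#'
#' @param reference_group Label of the normative group (default
#'   `"population"`).
#' @param clinical_group Label of the clinical group (default `"clinical"`).
#' @param score_range Integer raw-score range of the instrument, default
#'   `c(12, 84)` (12 items, categories 1-7).
#' @param rank_offset Plotting-position offset for the Rankit transform
#'   (0.5, 0.375, or 0).
#' @param n_quad,quad_range Quadrature spec for the IRT stages.
#' @param rci_level RCI confidence level (80/90/95).
#' @param reliability Reliability for the measurement error; `"alpha"`
#'   computes Cronbach's alpha from the reference group, or supply a number.
#' @param age_bands Optional numeric cut for age stratification, e.g.
#'   `c(18, 45, Inf)` for the bands 18-44 and 45+.
#' @param pr_source `"empirical"` or `"formula"` percentile-rank columns.
#' @param seed Seed for any internal randomness (none at present; echoed into
#'   metadata for provenance).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(reference_group = "population",
                            clinical_group = "clinical",
                            score_range = c(12, 84),
                            rank_offset = 0.5,
                            n_quad = 81L, quad_range = c(-8, 8),
                            rci_level = 95,
                            reliability = "alpha",
                            age_bands = NULL,
                            pr_source = "empirical",
                            seed = 1L) {
  if (!rank_offset %in% c(0.5, 0.375, 0)) {
    stop_sw("rank_offset must be 0.5, 0.375, or 0")
  }
  if (!rci_level %in% c(80, 90, 95)) stop_sw("rci_level must be 80/90/95")
  pr_source <- match.arg(pr_source, c("empirical", "formula"))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full norming pipeline
#'
#' Executes, in order: raw scoring, per-group descriptives, multigroup GRM
#' fit, EAP scoring (T_IRT), linear and Rankit T-scores against the reference
#' group, percentile ranks against both groups, conversion-formula fits
#' (degree-5 polynomial for T, Weibull sigmoid for the reference PR,
#' degree-5 polynomial for the clinical PR), a rounded crosswalk table,
#' change thresholds on raw and T metrics, and agreement reports of
#' T_Linear and T_Rankit against T_IRT. Deterministic given (data, config).
#'
#' @param data Response data frame (items + `group`, optional covariates).
#' @param config A [pipeline_config()].
#' @return List of class `norming_pipeline` with elements `score_table`,
#'   `descriptives`, `contrast`, `grm`, `formulas`, `crosswalk`,
#'   `thresholds`, `agreement`, `config`, and (when stratified) `strata`.
#' @export
run_pipeline <- function(data, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!"group" %in% names(data)) stop_sw("stage scoring: 'group' column required")
  res <- list(config = config)

  run_once <- function(data) {
    items <- item_columns(data)
    group <- as.character(data$group)
    ref <- config$reference_group
    clin <- config$clinical_group
    if (!ref %in% group) stop_sw("stage scoring: reference group absent")

    rs <- sum_score(data)
    ref_rs <- rs[group == ref & !is.na(rs)]
    clin_rs <- rs[group == clin & !is.na(rs)]

    desc <- lapply(split(rs[!is.na(rs)], group[!is.na(rs)]), descriptives)
    contrast <- if (length(clin_rs) >= 2) {
      cohens_d_welch(desc[[ref]], desc[[clin]])
    } else NULL

    fit <- fit_grm_multigroup(data, n_quad = config$n_quad,
                              quad_range = config$quad_range,
                              reference = ref)
    eap <- eap_score(data, fit, group = group)

    z <- (rs - desc[[ref]]$M) / desc[[ref]]$SD
    t_linear <- linear_t(rs, desc[[ref]]$M, desc[[ref]]$SD)
    t_rankit <- rep(NA_real_, length(rs))
    obs <- !is.na(rs)
    t_rankit[obs] <- suppressWarnings(
      rankit_t(rs[obs], ref_rs, config$rank_offset))

    score_table <- data.frame(
      group = group, rs = rs, z = z,
      t_linear = t_linear, t_rankit = t_rankit,
      theta = eap$theta, theta_se = eap$se, t_irt = eap$t_irt,
      pr_population = percentile_rank(rs, ref_rs),
      pr_clinical = if (length(clin_rs)) percentile_rank(rs, clin_rs)
                    else NA_real_
    )

    okr <- score_table$group == ref & !is.na(rs)
    t_formula <- fit_polynomial(rs[okr], score_table$t_irt[okr], degree = 5)
    pr_formulas <- list(
      population = fit_weibull_sigmoid(rs[okr], score_table$pr_population[okr]),
      clinical = if (length(clin_rs)) {
        okc <- score_table$group == clin & !is.na(rs)
        fit_polynomial(rs[okc], score_table$pr_clinical[okc], degree = 5)
      } else NULL
    )
    xwalk <- build_crosswalk(
      t_formula, pr_formulas, rs_range = config$score_range,
      pr_data = list(population = ref_rs, clinical = clin_rs),
      pr_source = config$pr_source)

    r_xx <- if (identical(config$reliability, "alpha")) {
      cronbach_alpha(data[group == ref, items])
    } else config$reliability
    thresholds <- if (length(clin_rs) >= 2) {
      t_desc_ref <- descriptives(score_table$t_irt[okr])
      t_desc_clin <- descriptives(
        score_table$t_irt[score_table$group == clin & !is.na(rs)])
      list(
        raw = change_thresholds(desc[[ref]]$SD, r_xx, desc[[clin]], desc[[ref]]),
        t = change_thresholds(t_desc_ref$SD, r_xx, t_desc_clin, t_desc_ref)
      )
    } else NULL

    agreement <- list(
      linear_vs_irt = agreement_report(score_table$t_linear,
                                       score_table$t_irt),
      rankit_vs_irt = agreement_report(score_table$t_rankit,
                                       score_table$t_irt)
    )

    list(score_table = score_table, descriptives = desc, contrast = contrast,
         grm = fit, formulas = c(list(t_irt = t_formula), pr_formulas),
         crosswalk = xwalk, thresholds = thresholds, agreement = agreement)
  }

  res <- c(res, run_once(data))
  if (!is.null(config$age_bands)) {
    if (!"age" %in% names(data)) stop_sw("stage stratify: no 'age' column")
    band <- cut(data$age, config$age_bands, right = FALSE)
    res$strata <- lapply(split(seq_len(nrow(data)), band), function(idx) {
      run_once(data[idx, , drop = FALSE])
    })
  }
  class(res) <- "norming_pipeline"
  res
}

#' @export
print.norming_pipeline <- function(x, ...) {
  cat("Norming pipeline results\n")
  for (g in names(x$descriptives)) {
    d <- x$descriptives[[g]]
    cat(sprintf("  %s: n = %d, M = %.2f, SD = %.2f, skew = %.2f\n",
                g, d$n, d$M, d$SD, d$skew))
  }
  if (!is.null(x$contrast)) { cat("  contrast: "); print(x$contrast) }
  cat(sprintf("  GRM: logLik %.1f, %d EM cycles, converged %s\n",
              x$grm$loglik, x$grm$iterations, x$grm$converged))
  if (!is.null(x$thresholds)) { cat("  raw-score thresholds: ")
    print(x$thresholds$raw)
    cat("  T-score thresholds: ")
    print(x$thresholds$t) }
  cat(sprintf("  ICC(A,1) vs T_IRT: linear %.3f, rankit %.3f\n",
              x$agreement$linear_vs_irt$icc$icc,
              x$agreement$rankit_vs_irt$icc$icc))
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Writes `score_table.csv`, `crosswalk.csv`, `grm_parameters.csv`,
#' `thresholds.txt`, and `agreement.csv`, each with a provenance header where
#' the format allows. Existing partial outputs are removed first.
#'
#' @param result A `norming_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  stopifnot(inherits(result, "norming_pipeline") ||
              is.list(result) && !is.null(result$score_table))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- file.path(dir, c("score_table.csv", "crosswalk.csv",
                                "grm_parameters.csv", "thresholds.txt",
                                "agreement.csv"))
  unlink(artifacts)
  on.exit(unlink(artifacts), add = TRUE)   # failure leaves no partial output
  utils::write.csv(result$score_table, file.path(dir, "score_table.csv"),
                   row.names = FALSE, quote = FALSE)
  write_crosswalk(result$crosswalk, file.path(dir, "crosswalk.csv"))
  write_grm_parameters(result$grm, file.path(dir, "grm_parameters.csv"))
  th <- result$thresholds
  if (!is.null(th)) {
    lines <- unlist(lapply(names(th), function(scale) {
      t <- th[[scale]]
      c(sprintf("[%s]", scale),
        sprintf("se=%.6f", t$se),
        sprintf("rci80=%.6f", t$rci[["80"]]),
        sprintf("rci90=%.6f", t$rci[["90"]]),
        sprintf("rci95=%.6f", t$rci[["95"]]),
        sprintf("cs=%.6f", t$cs),
        sprintf("higher_is_better=%s", t$higher_is_better))
    }))
    writeLines(lines, file.path(dir, "thresholds.txt"))
  }
  agr <- do.call(rbind, lapply(names(result$agreement), function(nm) {
    a <- result$agreement[[nm]]
    data.frame(pair = nm, icc = a$icc$icc, icc_lo = a$icc$ci[1],
               icc_hi = a$icc$ci[2], f = a$icc$f, bias = a$bias,
               loa_low = a$loa_low, loa_high = a$loa_high,
               perc_err = a$perc_err,
               n_below = a$counts["below", "n"],
               n_within = a$counts["within", "n"],
               n_above = a$counts["above", "n"])
  }))
  utils::write.csv(agr, file.path(dir, "agreement.csv"), row.names = FALSE,
                   quote = FALSE)
  on.exit()   # success: keep the artifacts
  invisible(dir)
}
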