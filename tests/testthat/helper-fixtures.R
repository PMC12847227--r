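# Shared fixtures and independent oracles. Heavy objects are computed once
# per test run and cached in this environment.

.fixture_env <- new.env(parent = emptyenv())

# End-to-end synthetic run used by the pipeline, agreement-ordering, and
# acceptance tests: 2000 respondents per group from the bundled parameters.
pipeline_fixture <- function() {
  if (is.null(.fixture_env$pipeline)) {
    params <- default_mansa_params()
    cfg <- simulation_config(2000, params, seed = 20260901)
    data <- generate_grm_responses(cfg)
    result <- suppressMessages(run_pipeline(data, pipeline_config()))
    .fixture_env$pipeline <- list(params = params, data = data,
                                  result = result)
  }
  .fixture_env$pipeline
}

# small deterministic response matrix for cheap structural tests
toy_responses <- function(n = 200, n_items = 4, seed = 99) {
  p <- toy_params(n_items)
  cfg <- simulation_config(n, p, seed = seed)
  generate_grm_responses(cfg)
}

toy_params <- function(n_items = 4, K = 5, a = NULL, groups = NULL) {
  b <- t(vapply(seq_len(n_items), function(j) {
    seq(-1.5, 1.5, length.out = K - 1) + (j - n_items / 2) * 0.2
  }, numeric(K - 1)))
  grm_parameters(a %||% rep(1.5, n_items), b,
                 groups = groups %||%
                   data.frame(group = c("population", "clinical"),
                              mean = c(0, -1), sd = c(1, 1.4)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent EAP oracle: trapezoid integration on a 10,001-point grid.
eap_oracle <- function(pattern, params, group = "population",
                       grid_n = 10001L, range = c(-8, 8)) {
  theta <- seq(range[1], range[2], length.out = grid_n)
  g <- match(group, params$groups$group)
  lik <- stats::dnorm(theta, params$groups$mean[g], params$groups$sd[g])
  for (j in seq_along(pattern)) {
    if (is.na(pattern[j])) next
    P <- grm_category_probs(params$a[j], params$b[j, ], theta)
    lik <- lik * P[, pattern[j]]
  }
  trap <- function(f) sum((f[-1] + f[-grid_n]) / 2) * diff(theta[1:2])
  z <- trap(lik)
  m1 <- trap(theta * lik) / z
  m2 <- trap(theta^2 * lik) / z
  c(theta = m1, se = sqrt(m2 - m1^2))
}

# Independent ICC oracle: two-way ANOVA mean squares via stats::anova()
icc_oracle <- function(m1, m2) {
  n <- length(m1)
  d <- data.frame(y = c(m1, m2),
                  subject = factor(rep(seq_len(n), 2)),
                  method = factor(rep(1:2, each = n)))
  an <- stats::anova(stats::lm(y ~ subject + method, data = d))
  msr <- an["subject", "Mean Sq"]
  msc <- an["method", "Mean Sq"]
  mse <- an["Residuals", "Mean Sq"]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

sample_skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3

# Printed summary statistics of the two normative samples (raw-score and
# T-score metrics) used as inputs by several tests.
published_stats <- list(
  raw = list(clinical = list(M = 51.14, SD = 14.20, n = 9983),
             normative = list(M = 61.72, SD = 8.76, n = 11789)),
  t = list(clinical = list(M = 37.98, SD = 15.69, n = 9983),
           normative = list(M = 50.06, SD = 8.86, n = 11789))
)

published_crosswalk <- function() {
  utils::read.csv(system.file("extdata", "crosswalk_published.csv",
                              package = "scorewalk"))
}

published_formulas <- function() {
  list(
    t_irt = conversion_formula(
      "polynomial",
      c(-3.441e+01, 4.302, -1.297e-01, 2.152e-03, -1.705e-05, 5.793e-08),
      domain = c(12, 84)),
    pr_population = conversion_formula(
      "weibull-sigmoid", c(4.735e-01, 1.006e+02, 8.691, 6.563e+01),
      domain = c(12, 84)),
    pr_clinical = conversion_formula(
      "polynomial",
      c(-8.841, 1.916, -1.478e-01, 4.878e-03, -5.504e-05, 2.006e-07),
      domain = c(12, 84))
  )
}
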