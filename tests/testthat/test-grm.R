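test_that("theta_to_t is the exact affine map", {
  expect_equal(theta_to_t(0), 50)
  expect_equal(theta_to_t(1.5), 65)
  expect_equal(round(theta_to_t(-2.81), 1), 21.9)
})

test_that("eap_score matches the fine-grid integration oracle", {
  p <- toy_params(n_items = 6, K = 5, a = c(0.8, 1.1, 1.6, 2.0, 1.3, 0.9))
  patterns <- rbind(c(1, 1, 2, 1, 3, 1), c(3, 3, 3, 3, 3, 3),
                    c(5, 5, 4, 5, 5, 5), c(1, 5, 2, 4, 3, 2))
  for (g in c("population", "clinical")) {
    for (i in seq_len(nrow(patterns))) {
      got <- eap_score(patterns[i, ], p, group = g)
      want <- eap_oracle(patterns[i, ], p, group = g)
      expect_lt(abs(got$theta - want[["theta"]]), 1e-6)
      expect_lt(abs(got$se - want[["se"]]), 1e-6)
    }
  }
})

test_that("single dichotomous item EAP equals brute-force integration", {
  p <- grm_parameters(a = 1, b = matrix(0), items = "item01")
  got <- eap_score(2, p)
  want <- eap_oracle(2, p)
  expect_equal(got$theta, unname(want["theta"]), tolerance = 1e-6)
  # closed-form cross-check on the normalizer: E[plogis(theta)] = 1/2
  expect_gt(got$theta, 0)  # responding "yes" pulls theta up
})

test_that("zero information returns the prior; dominance orders thetas", {
  p0 <- toy_params(a = rep(1e-8, 4), K = 5)
  e <- eap_score(c(2, 3, 4, 1), p0, group = "population")
  expect_equal(e$theta, 0, tolerance = 1e-6)
  expect_equal(e$se, 1, tolerance = 1e-6)
  # the shifted prior is truncated asymmetrically by the [-6, 6] grid, so the
  # clinical zero-information limit agrees with the integration oracle (and
  # with the prior mean only to the truncation error ~1e-3)
  e_cl <- eap_score(c(2, 3, 4, 1), p0, group = "clinical")
  expect_equal(e_cl$theta, -1, tolerance = 1e-2)
  expect_lt(abs(e_cl$theta - eap_oracle(c(2, 3, 4, 1), p0, "clinical")[["theta"]]),
            1e-6)
  # category-wise dominating pattern scores strictly higher
  p <- toy_params(n_items = 4, K = 5)
  lo <- eap_score(c(2, 3, 2, 3), p)
  hi <- eap_score(c(3, 4, 2, 3), p)
  expect_gt(hi$theta, lo$theta)
  expect_error(eap_score(rep(NA_integer_, 4), p), "missing")
})

test_that("EM fit converges with monotone log-likelihood and honest flags", {
  d <- toy_responses(n = 500, n_items = 4, seed = 31)
  fit <- fit_grm_multigroup(d, tol = 1e-4)
  expect_true(fit$converged)
  tr <- attr(fit, "loglik_trace")
  expect_true(all(diff(tr) >= -1e-8))
  expect_identical(fit$groups$group[1], "population")
  expect_equal(fit$groups$mean[1], 0)
  expect_equal(fit$groups$sd[1], 1)
  expect_lt(fit$groups$mean[2], 0)   # clinical group sits lower
  # single observed category errors by item name
  bad <- d
  bad$item02 <- 3L
  expect_error(fit_grm_multigroup(bad), "item02")
})

test_that("reference relabelling re-anchors without changing separation", {
  d <- toy_responses(n = 350, n_items = 4, seed = 17)
  f1 <- fit_grm_multigroup(d, tol = 1e-6, reference = "population")
  f2 <- fit_grm_multigroup(d, tol = 1e-6, reference = "clinical")
  # population mean in the clinical anchoring equals -(mu_c)/sigma_c of the
  # population anchoring (affine invariance of the MLE)
  mu_c <- f1$groups$mean[2]; sd_c <- f1$groups$sd[2]
  expect_equal(f2$groups$mean[2], -mu_c / sd_c, tolerance = 1e-3)
  expect_equal(f2$groups$sd[2], 1 / sd_c, tolerance = 1e-3)
  # discriminations rescale by sigma_c
  expect_equal(f2$a, f1$a * sd_c, tolerance = 5e-3)
})

test_that("grm parameters round-trip through their text serialization", {
  p <- toy_params(n_items = 3, K = 4, a = c(0.77, 1.234567891234, 2.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_grm_parameters(p, path)
  p2 <- read_grm_parameters(path)
  expect_equal(p2$a, p$a, tolerance = 1e-11)
  expect_equal(p2$b, p$b, ignore_attr = TRUE, tolerance = 1e-11)
  expect_equal(p2$groups, p$groups)
})

test_that("polychoric screen separates one-factor from independent data", {
  # perfect monotone association: correlation ~1, eigenvalues ~ {2, 0}
  x <- rep(1:5, each = 20)
  d_perf <- data.frame(item01 = x, item02 = x)
  ev <- polychoric_eigen_screen(d_perf)
  expect_equal(ev[1], 2, tolerance = 0.02)
  expect_equal(ev[2], 0, tolerance = 0.02)
  # independent items: all eigenvalues near 1
  set.seed(4)
  d_ind <- as.data.frame(matrix(sample(1:5, 5000 * 4, TRUE), ncol = 4))
  names(d_ind) <- sprintf("item%02d", 1:4)
  ev_ind <- polychoric_eigen_screen(d_ind)
  expect_true(all(abs(ev_ind - 1) < 0.15))
  # strong single factor: dominant first eigenvalue
  p <- toy_params(n_items = 4, K = 5, a = rep(2.5, 4))
  d_spike <- generate_grm_responses(simulation_config(2000, p, seed = 6))
  ev_sp <- polychoric_eigen_screen(d_spike[d_spike$group == "population", 1:4])
  expect_gt(ev_sp[1], 2.5)
  expect_gt(ev_sp[1] / ev_sp[2], 5)
})

test_that("polychoric pairwise estimate is accurate against known rho", {
  # discretize a known bivariate normal and recover its correlation
  set.seed(12)
  n <- 4000
  z1 <- rnorm(n); z2 <- 0.6 * z1 + sqrt(1 - 0.36) * rnorm(n)
  cutq <- c(-1, 0, 0.8)
  d <- data.frame(item01 = findInterval(z1, cutq) + 1L,
                  item02 = findInterval(z2, cutq) + 1L)
  R <- polychoric_matrix(d)
  expect_equal(R[1, 2], 0.6, tolerance = 0.05)
})
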