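test_that("bundled default parameters meet the structural contract", {
  p <- default_mansa_params()
  expect_s3_class(p, "grm_parameters")
  expect_length(p$a, 12)
  expect_equal(dim(p$b), c(12, 6))
  expect_true(all(p$a > 0))
  expect_true(all(apply(p$b, 1, function(x) all(diff(x) > 0))))
  expect_identical(p$groups$group[1], "population")
  expect_identical(p$groups[1, c("mean", "sd")],
                   data.frame(mean = 0, sd = 1, row.names = 1L))
})

test_that("category probabilities are exact at closed-form points and sum to 1", {
  # a = 2, thresholds (-1, 0, 1), theta = 0: boundaries plogis(2), .5, plogis(-2)
  P <- grm_category_probs(2, c(-1, 0, 1), 0)
  expect_equal(as.numeric(P),
               c(1 - plogis(2), plogis(2) - 0.5, 0.5 - plogis(-2), plogis(-2)),
               tolerance = 1e-12)
  expect_equal(round(as.numeric(P), 3), c(0.119, 0.381, 0.381, 0.119))
  # rows sum to one everywhere
  theta <- seq(-5, 5, by = 0.25)
  for (a in c(0.3, 1.2, 2.5)) {
    P <- grm_category_probs(a, c(-2.1, -0.7, 0.4, 1.8), theta)
    expect_equal(rowSums(P), rep(1, length(theta)), tolerance = 1e-12)
  }
})

test_that("generation is deterministic and respects the config contract", {
  cfg <- simulation_config(50, toy_params(), seed = 123)
  d1 <- generate_grm_responses(cfg)
  d2 <- generate_grm_responses(cfg)
  expect_identical(d1, d2)
  expect_setequal(unique(d1$group), c("population", "clinical"))
  expect_true(all(as.matrix(d1[, 1:4]) %in% 1:5))
  # different seed changes the draw
  d3 <- generate_grm_responses(simulation_config(50, toy_params(), seed = 124))
  expect_false(identical(d1[, 1:4], d3[, 1:4]))
})

test_that("invalid configurations are rejected", {
  expect_error(grm_parameters(a = c(1, 1), b = rbind(c(0, -1), c(-1, 0))),
               "increasing")
  expect_error(grm_parameters(a = c(-1, 1), b = rbind(c(-1, 0), c(-1, 0))),
               "positive")
  expect_error(simulation_config(0, toy_params()), ">= 1")
  expect_error(simulation_config(10, toy_params(), missing_rate = 1), "missing_rate")
  bad_groups <- data.frame(group = c("population", "clinical"),
                           mean = c(0.2, -1), sd = c(1, 1))
  expect_error(grm_parameters(1, t(c(-1, 0, 1)), groups = bad_groups),
               "reference")
})

test_that("near-zero discrimination makes groups indistinguishable", {
  p <- toy_params(a = rep(1e-3, 4))
  d <- generate_grm_responses(simulation_config(4000, p, seed = 5))
  x <- as.matrix(d[, 1:4])
  f_pop <- tabulate(x[d$group == "population", ], nbins = 5) / (4000 * 4)
  f_cl <- tabulate(x[d$group == "clinical", ], nbins = 5) / (4000 * 4)
  expect_lt(max(abs(f_pop - f_cl)), 0.02)
  # threshold-implied marginals at a -> 0: boundary probs all 1/2
  expect_equal(unname(f_pop), c(0.5, 0, 0, 0, 0.5), tolerance = 0.02)
})

test_that("missing responses are generated MCAR at the requested rate", {
  cfg <- simulation_config(2000, toy_params(), seed = 3, missing_rate = 0.1)
  d <- generate_grm_responses(cfg)
  expect_lt(abs(mean(is.na(as.matrix(d[, 1:4]))) - 0.1), 0.015)
})

test_that("default parameters reproduce the stated two-group world", {
  p <- default_mansa_params()
  d <- generate_grm_responses(simulation_config(10000, p, seed = 42))
  rs <- rowSums(d[, 1:12])
  pop <- rs[d$group == "population"]
  cl <- rs[d$group == "clinical"]
  expect_gt(mean(pop), 58)        # Monte-Carlo calibration band
  expect_lt(mean(pop), 65)
  expect_lt(sample_skewness(pop), -0.3)
  expect_gt(sd(cl), sd(pop))      # clinical group wider
  expect_lt(mean(cl), mean(pop))  # and lower
})

test_that("empirical category frequencies match model probabilities (GOF)", {
  p <- default_mansa_params()
  d <- generate_grm_responses(simulation_config(50000, p, seed = 77))
  x <- d[d$group == "population", 1]
  # marginal model probabilities by fine-grid integration over N(0,1)
  theta <- seq(-8, 8, length.out = 4001)
  w <- dnorm(theta); w <- w / sum(w)
  probs <- colSums(grm_category_probs(p$a[1], p$b[1, ], theta) * w)
  obs <- tabulate(x, nbins = 7)
  expect_gt(chisq.test(obs, p = probs)$p.value, 0.01)
})

test_that("response matrix round-trips through delimited text", {
  d <- toy_responses(30)
  path <- withr::local_tempfile(fileext = ".csv")
  write_response_matrix(d, path)
  expect_true(file.exists(paste0(path, ".meta")))  # parameter sidecar
  d2 <- read_response_matrix(path)
  expect_equal(d2[names(d2)], as.data.frame(d)[names(d2)],
               ignore_attr = TRUE)
  p2 <- read_grm_parameters(paste0(path, ".meta"))
  expect_equal(p2$a, attr(d, "item_params")$a, tolerance = 1e-10)
})
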