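test_that("measurement error and RCI follow the closed forms", {
  expect_equal(standard_error_measurement(8.86, 1), 0)
  expect_equal(standard_error_measurement(0, 0.5), 0)
  expect_equal(round(standard_error_measurement(8.86, 0.88), 3), 3.069)
  expect_error(standard_error_measurement(5, 1.2), "r_xx")
  se <- standard_error_measurement(8.86, 0.88)
  expect_equal(round_half_away(rci(se, 95), 1), 8.5)
  expect_equal(rci(0, 80), 0)
  expect_lt(rci(se, 80), rci(se, 90))
  expect_lt(rci(se, 90), rci(se, 95))
  expect_equal(rci(2 * se, 95), 2 * rci(se, 95))   # degree-1 homogeneity
  expect_error(rci(se, 99), "level")
})

test_that("cs_cutoff reproduces printed cutoffs and stays between means", {
  s <- published_stats
  expect_equal(round(cs_cutoff(s$raw$clinical, s$raw$normative), 2), 57.68)
  expect_equal(round(cs_cutoff(s$t$clinical, s$t$normative), 1), 45.7)
  expect_equal(cs_cutoff(list(M = 40, SD = 3), list(M = 40, SD = 9)), 40)
  set.seed(2)
  for (i in 1:25) {
    m1 <- runif(1, 10, 50); m2 <- runif(1, 51, 90)
    cs <- cs_cutoff(list(M = m1, SD = runif(1, 1, 20)),
                    list(M = m2, SD = runif(1, 1, 20)))
    expect_gt(cs, m1); expect_lt(cs, m2)
  }
  expect_error(cs_cutoff(list(M = 1, SD = 0), list(M = 2, SD = 1)), "SD")
})

test_that("classify_change covers the five outcomes on the printed thresholds", {
  th <- change_thresholds(8.86, 0.88, published_stats$t$clinical,
                          published_stats$t$normative)
  expect_equal(round(th$cs, 1), 45.7)
  expect_equal(as.character(classify_change(40, 50, th)), "Recovered")
  expect_equal(as.character(classify_change(50, 50, th)), "Unchanged")
  expect_equal(as.character(classify_change(50, 41, th)), "Relapsed")
  expect_equal(as.character(classify_change(30, 40, th)), "Reliably Improved")
  expect_equal(as.character(classify_change(40, 30, th)),
               "Reliably Deteriorated")
})

test_that("classify_change truth table is exhaustive and exclusive", {
  th <- change_thresholds(10, 0.75, list(M = 40, SD = 12), list(M = 55, SD = 8))
  rc <- th$rci[["95"]]
  grid <- expand.grid(pre = seq(th$cs - 2 * rc, th$cs + 2 * rc, by = rc / 3),
                      post = seq(th$cs - 2 * rc, th$cs + 2 * rc, by = rc / 3))
  out <- classify_change(grid$pre, grid$post, th)
  expect_false(anyNA(out))                       # exactly one category per cell
  # rule-by-rule re-derivation (independent of implementation order)
  delta <- grid$post - grid$pre
  fun <- function(s) s >= th$cs
  want <- ifelse(abs(delta) < rc, "Unchanged",
          ifelse(delta >= rc & !fun(grid$pre) & fun(grid$post), "Recovered",
          ifelse(delta >= rc, "Reliably Improved",
          ifelse(fun(grid$pre) & !fun(grid$post), "Relapsed",
                 "Reliably Deteriorated"))))
  expect_equal(as.character(out), want)
  # direction reversal flips improvement and deterioration
  th_rev <- th; th_rev$higher_is_better <- FALSE
  out_rev <- classify_change(grid$post, grid$pre, th_rev)
  improved <- out %in% c("Recovered", "Reliably Improved")
  improved_rev <- out_rev %in% c("Recovered", "Reliably Improved")
  expect_equal(improved, improved_rev)
})

test_that("severity bands assign boundaries to the worse side", {
  expect_equal(as.character(severity_band(50)), "Average")
  expect_equal(as.character(severity_band(45.7)), "Below Average")
  expect_equal(as.character(severity_band(45.71)), "Average")
  expect_equal(as.character(severity_band(39)), "Poor")
  expect_equal(as.character(severity_band(61)), "Excellent")
  # lower-is-better flips the boundary rule to the upper (worse) side
  expect_equal(as.character(severity_band(45.7, higher_is_better = FALSE,
                                          labels = rev(c("Poor", "Below Average",
                                                         "Average", "Above Average",
                                                         "Excellent")))),
               "Average")
  expect_error(severity_band(50, cutpoints = c(40, 40)), "ordered")
})

test_that("change_thresholds validates and prints consistently", {
  th <- change_thresholds(8.76, 0.88, published_stats$raw$clinical,
                          published_stats$raw$normative)
  expect_equal(round(th$cs, 2), 57.68)
  expect_true(all(diff(th$rci) > 0))
  expect_output(print(th), "RCI95")
})
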