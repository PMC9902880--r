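test_that("region counting summarizes accepted spots", {
  expect_equal(count_regions(c(3, 3, 3))$mean, 3)
  expect_equal(count_regions(c(3, 3, 3))$sd, 0)
  rc <- count_regions(c(1, 2, 3, 4), label = "s")
  expect_equal(rc$mean, 2.5)
  expect_equal(rc$sd, 1.2909944, tolerance = 1e-6)
  # from spot tables
  tabs <- lapply(c(2, 5), function(n)
    data.frame(x = seq_len(n), accepted = rep(TRUE, n)))
  expect_equal(count_regions(tabs)$counts, c(2L, 5L))
  expect_error(count_regions(list()), class = "smi_config_error")
  expect_error(count_regions(c(-1, 2)), class = "smi_config_error")
})

test_that("calibration fitting matches the normal-equations oracle", {
  # exact line
  x <- c(0.1, 1, 10, 100)
  fit <- fit_calibration(x, 2 * log10(x) + 3)
  expect_equal(unname(coef(fit)), c(3, 2), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(predict(fit, newdata = 1000), 2 * 3 + 3)

  # noisy points against closed-form OLS
  set.seed(31)
  y <- 110 * log10(x) + 120 + rnorm(4, 0, 7)
  fitn <- fit_calibration(x, y)
  beta <- ols_oracle(log10(x), y)
  expect_equal(fitn$intercept, unname(beta[1]), tolerance = 1e-10)
  expect_equal(fitn$slope, unname(beta[2]), tolerance = 1e-10)
  expect_gte(fitn$r_squared, 0)
  expect_lte(fitn$r_squared, 1)
  expect_equal(sum(residuals(fitn)), 0, tolerance = 1e-9)

  expect_error(fit_calibration(c(1, 10), c(1, 2)),
               class = "smi_config_error")
  expect_error(fit_calibration(c(1, 1, 1), c(1, 2, 3)),
               class = "smi_config_error")
})

test_that("count scaling propagates through fits and folds but not R^2", {
  x <- c(0.1, 1, 10, 100)
  set.seed(5)
  y <- 100 * log10(x) + 110 + rnorm(4, 0, 4)
  f1 <- fit_calibration(x, y)
  f2 <- fit_calibration(x, y * 3)
  expect_equal(f2$slope, 3 * f1$slope)
  expect_equal(f2$intercept, 3 * f1$intercept)
  expect_equal(f2$r_squared, f1$r_squared)
  ref <- count_regions(c(200, 210, 220))
  var <- count_regions(c(95, 100, 105))
  ref3 <- count_regions(3 * c(200, 210, 220))
  var3 <- count_regions(3 * c(95, 100, 105))
  expect_equal(selectivity_ratios(ref3, list(var3))$fold,
               selectivity_ratios(ref, list(var))$fold)
})

test_that("LOD follows the blank + 3 SD crossing rule", {
  x <- c(0.1, 1, 10, 100)
  fit <- fit_calibration(x, 100 * log10(x) + 8)
  blank <- count_regions(c(5, 5, 5))
  blank$sd <- 2   # blank mean 5, SD 2 -> threshold 11
  lod <- estimate_lod(fit, blank)
  expect_equal(lod$threshold, 11)
  expect_equal(lod$lod_value, 10^0.03, tolerance = 1e-9)
  # independent numerical inversion of the same crossing
  oracle <- uniroot(function(c) 100 * log10(c) + 8 - 11, c(1e-3, 1e3),
                    tol = 1e-12)$root
  expect_equal(lod$lod_value, oracle, tolerance = 1e-8)

  # degenerate blank: zero SD and intercept equal to the blank mean -> LOD 1
  fit2 <- fit_calibration(x, 50 * log10(x) + 5)
  blank2 <- count_regions(c(5, 5, 5))
  expect_equal(estimate_lod(fit2, blank2)$lod_value, 1)

  # non-positive slope is rejected
  fitneg <- fit_calibration(x, -10 * log10(x) + 50)
  expect_error(estimate_lod(fitneg, blank), class = "smi_config_error")
  # threshold below the fitted line over the whole calibrated range
  fithigh <- fit_calibration(x, 100 * log10(x) + 500)
  expect_error(estimate_lod(fithigh, blank), class = "smi_data_error")
})

test_that("selectivity folds are reference over variant means", {
  ref <- count_regions(rep(210, 5), label = "miR-126")
  v1 <- count_regions(rep(100, 5), label = "single-mismatch")
  expect_equal(selectivity_ratios(ref, list(v1))$fold, 2.1)
  expect_equal(selectivity_ratios(ref, list(ref))$fold, 1)
  v0 <- count_regions(rep(0, 5), label = "blank")
  expect_warning(s0 <- selectivity_ratios(ref, list(v0)))
  expect_true(is.infinite(s0$fold))
})
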