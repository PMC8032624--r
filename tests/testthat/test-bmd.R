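hill_curve <- function(doses, c = 95, b = 8, d = 1.6) {
  tibble::tibble(dose_mg_kg = doses,
                 inhibition_pct = c * doses^d / (b^d + doses^d))
}

test_that("data generated from a Hill curve are recovered and AIC prefers Hill", {
  doses <- 10^seq(-1, 2.5, length.out = 12)
  curve <- hill_curve(doses)
  fits <- fit_dose_response_models(curve)
  expect_setequal(names(fits), c("exponential", "hill"))
  h <- fits$hill
  expect_equal(h$pars$c, 95, tolerance = 1e-3)
  expect_equal(h$pars$b, 8, tolerance = 1e-3)
  expect_equal(h$pars$d, 1.6, tolerance = 1e-3)
  expect_lt(h$aic, fits$exponential$aic)
})

test_that("degenerate curves are rejected", {
  flat <- tibble::tibble(dose_mg_kg = 1:6, inhibition_pct = rep(0.2, 6))
  expect_error(fit_dose_response_models(flat), "flat",
               class = "revdosim_fit_error")
  short <- hill_curve(c(1, 5, 20, 80))
  expect_error(fit_dose_response_models(short), "5 dose",
               class = "revdosim_validation_error")
})

test_that("the benchmark dose inverts the fitted curve at the benchmark response", {
  # Hill with c = 100, b = 9, d = 1 crosses 10% inhibition exactly at dose 1
  doses <- 10^seq(-1.5, 2, length.out = 10)
  curve <- tibble::tibble(dose_mg_kg = doses,
                          inhibition_pct = 100 * doses / (9 + doses))
  fit <- fit_dose_response_models(curve, families = "hill")$hill
  expect_equal(bmd_at_bmr(fit, 0.10), 1, tolerance = 1e-4)
  expect_equal(bmd_at_bmr(fit, 0), 0)
  expect_error(bmd_at_bmr(fit, 1.2), class = "revdosim_range_error")
})

test_that("doubling all doses doubles the BMD (scale equivariance)", {
  doses <- 10^seq(-1, 2.5, length.out = 12)
  f1 <- fit_dose_response_models(hill_curve(doses))
  c2 <- hill_curve(doses)
  c2$dose_mg_kg <- c2$dose_mg_kg * 2
  f2 <- fit_dose_response_models(c2)
  for (fam in names(f1)) {
    expect_equal(bmd_at_bmr(f2[[fam]], 0.10), 2 * bmd_at_bmr(f1[[fam]], 0.10),
                 tolerance = 1e-3)
  }
})

test_that("model averaging reduces to the single model and bounds BMDL by BMD", {
  doses <- 10^seq(-1, 2.5, length.out = 12)
  curve <- hill_curve(doses)
  curve$inhibition_pct <- curve$inhibition_pct *
    (1 + withr::with_seed(7, stats::rnorm(nrow(curve), 0, 0.03)))
  single <- fit_dose_response_models(curve, families = "hill")
  res1 <- model_average_bmdl(single, curve, n_boot = 80, seed = 11)
  expect_equal(res1$models$weight, 1)
  expect_equal(res1$bmd, res1$models$bmd)
  expect_lte(res1$bmdl, res1$bmd)

  both <- fit_dose_response_models(curve)
  res2 <- model_average_bmdl(both, curve, n_boot = 80, seed = 11)
  expect_equal(sum(res2$models$weight), 1)
  expect_lte(res2$bmdl, res2$bmd)
  # reproducible under a fixed seed
  res3 <- model_average_bmdl(both, curve, n_boot = 80, seed = 11)
  expect_equal(res2$bmdl, res3$bmdl)
})

test_that("a low bootstrap count is flagged in the result", {
  doses <- 10^seq(-1, 2.5, length.out = 12)
  curve <- hill_curve(doses)
  fits <- fit_dose_response_models(curve, families = "hill")
  expect_warning(res <- model_average_bmdl(fits, curve, n_boot = 20, seed = 3),
                 "below 50")
  expect_true(any(grepl("below 50", res$warnings)))
})

test_that("bmd_result supports tidy and glance", {
  doses <- 10^seq(-1, 2.5, length.out = 12)
  curve <- hill_curve(doses)
  fits <- fit_dose_response_models(curve)
  res <- model_average_bmdl(fits, curve, n_boot = 60, seed = 2)
  expect_setequal(tidy(res)$family, c("exponential", "hill"))
  gl <- glance(res)
  expect_equal(gl$bmr, 0.10)
  expect_true(gl$bmdl <= gl$bmd)
})
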