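test_that("concentration zero maps to dose zero and the inversion round-trips within 1%", {
  m <- pbk_model("rat")
  # grid density comparable to the default map (about 5 points per decade)
  map <- quick_map(m, doses = 10^seq(-2, 3, length.out = 26))
  expect_equal(concentration_to_dose(map, 0), 0)
  # round trip dose -> Cmax -> dose across the interior of the grid
  for (d in c(0.1, 5, 200)) {
    cu <- quick_sim(m, d, n_out = 250)$cmax_unbound_uM
    back <- concentration_to_dose(map, cu)
    expect_lt(abs(back - d) / d, 0.01)
  }
})

test_that("concentrations above the mapped range trigger grid extension or a range error", {
  m <- pbk_model("rat")
  map <- dose_to_cmax_map(m, doses = 10^seq(-2, 0, length.out = 6), n_out = 200)
  top <- max(map$cmax_unbound_uM)
  expect_error(concentration_to_dose(map, top * 5, extend = FALSE),
               class = "revdosim_range_error")
  d <- concentration_to_dose(map, top * 5, extend = TRUE)
  expect_gt(d, max(map$dose_mg_kg))
})

test_that("predicted dose-response curves preserve the in vitro response and are monotone", {
  m <- pbk_model("rat")
  fit <- fit_ic50(gen_inhibition_data(312, noise = noise_model("additive", sd = 0)))
  map <- quick_map(m)
  conc <- 10^seq(1, 4, by = 0.5)
  curve <- predict_dose_response(map, fit, conc_grid = conc)
  expect_s3_class(curve, "dose_response_curve")
  expect_equal(curve$inhibition_pct, inhibition_at(conc, fit))
  expect_true(all(diff(curve$dose_mg_kg) > 0))
  expect_true(all(diff(curve$inhibition_pct) >= 0))
})

test_that("the human curve lies left of the rat curve at every inhibition level", {
  ref <- profenofos_reference_ic50()
  curves <- lapply(c("rat", "human"), function(sp) {
    fit <- fit_ic50(gen_inhibition_data(
      ref$ic50_nM[ref$species == sp],
      noise = noise_model("additive", sd = 0)))
    predict_dose_response(quick_map(pbk_model(sp)), fit,
                          conc_grid = 10^seq(1, 4, by = 0.5))
  })
  rat <- curves[[1]]; hum <- curves[[2]]
  for (lev in c(10, 30, 50, 80)) {
    d_rat <- stats::approx(rat$inhibition_pct, rat$dose_mg_kg, xout = lev)$y
    d_hum <- stats::approx(hum$inhibition_pct, hum$dose_mg_kg, xout = lev)$y
    expect_lt(d_hum, d_rat)
  }
})

test_that("identical kinetics forced into both species labels give the same curve", {
  phys <- default_physiology("rat")
  met <- build_metabolism("rat")
  fit <- fit_ic50(gen_inhibition_data(302, noise = noise_model("additive", sd = 0)))
  conc <- 10^seq(1.5, 3.5, by = 0.5)
  doses <- 10^seq(-1, 3, length.out = 10)
  c1 <- predict_dose_response(
    dose_to_cmax_map(pbk_model("rat", physiology = phys, metabolism = met),
                     doses = doses, n_out = 200), fit, conc_grid = conc)
  c2 <- predict_dose_response(
    dose_to_cmax_map(pbk_model("human", physiology = phys, metabolism = met),
                     doses = doses, n_out = 200), fit, conc_grid = conc)
  expect_equal(c1$dose_mg_kg, c2$dose_mg_kg, tolerance = 1e-6)
})

test_that("an in vitro unbound-fraction correction shifts the dose axis only", {
  m <- pbk_model("rat")
  fit <- fit_ic50(gen_inhibition_data(312, noise = noise_model("additive", sd = 0)))
  map <- quick_map(m)
  conc <- 10^seq(1.5, 3.5, by = 0.5)
  full <- predict_dose_response(map, fit, conc_grid = conc, fu_invitro = 1)
  half <- predict_dose_response(map, fit, conc_grid = conc, fu_invitro = 0.5)
  expect_equal(half$inhibition_pct, full$inhibition_pct)
  expect_true(all(half$dose_mg_kg < full$dose_mg_kg))
})
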