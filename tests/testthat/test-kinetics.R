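test_that("the Michaelis-Menten rate law satisfies its identities", {
  expect_equal(michaelis_menten_rate(6.9, 6.9, 1.2), 0.6)   # S = Km -> Vmax/2
  expect_equal(michaelis_menten_rate(0, 6.9, 1.2), 0)
  expect_equal(michaelis_menten_rate(100, 6.9, 1.2), 1.2 * 100 / 106.9)
  expect_lt(michaelis_menten_rate(1e9, 6.9, 1.2), 1.2)
  expect_error(michaelis_menten_rate(-1, 6.9, 1.2),
               class = "revdosim_validation_error")
})

test_that("noiseless Michaelis-Menten data are recovered to at least 4 significant digits", {
  dat <- gen_incubation_data(Km = 6.9, Vmax = 1.2,
                             noise = noise_model("proportional", cv = 0))
  fit <- fit_michaelis_menten(dat)
  expect_equal(fit$Km, 6.9, tolerance = 1e-4)
  expect_equal(fit$Vmax, 1.2, tolerance = 1e-4)
  expect_equal(fit$catalytic_efficiency, fit$Vmax / fit$Km)
})

test_that("degenerate incubation inputs are rejected with informative errors", {
  ok <- gen_incubation_data(5, 1, noise = noise_model(cv = 0))
  few <- ok[ok$concentration_uM %in% c(1, 5, 25), ]
  expect_error(fit_michaelis_menten(few), "4 distinct",
               class = "revdosim_validation_error")
  zero <- ok
  zero$rate_nmol_min_mg <- 0
  expect_error(fit_michaelis_menten(zero), "zero",
               class = "revdosim_validation_error")
})

test_that("rat plasma Km is recovered within 15% from noisy synthetic data", {
  kin <- profenofos_invitro_kinetics()
  row <- kin[kin$species == "rat" & kin$matrix == "plasma", ]
  dat <- gen_incubation_data(row$Km_uM, row$Vmax_nmol_min_mg,
                             noise = noise_model("proportional", cv = 0.05,
                                                 replicates = 3, seed = 42))
  fit <- fit_michaelis_menten(dat)
  expect_lt(abs(fit$Km - row$Km_uM) / row$Km_uM, 0.15)
  expect_lt(abs(fit$Vmax - row$Vmax_nmol_min_mg) / row$Vmax_nmol_min_mg, 0.15)
})

test_that("parameter error vanishes as the noise level goes to zero", {
  errs <- vapply(c(0.1, 0.02, 0.002), function(cv) {
    rel <- vapply(1:4, function(s) {
      d <- gen_incubation_data(6.9, 1.2,
                               noise = noise_model(cv = cv, seed = 100 + s))
      f <- fit_michaelis_menten(d)
      abs(f$Km - 6.9) / 6.9 + abs(f$Vmax - 1.2) / 1.2
    }, numeric(1))
    mean(rel)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.01)
})

test_that("catalytic efficiency is exactly Vmax/Km with the printed reference values", {
  expect_equal(signif(catalytic_efficiency(1.2, 6.9), 2), 0.17)
  expect_equal(signif(catalytic_efficiency(0.99, 158), 2), 0.0063)
  expect_equal(catalytic_efficiency(0, 10), 0)
  f <- fit_michaelis_menten(gen_incubation_data(5, 1, noise = noise_model(cv = 0)))
  expect_identical(catalytic_efficiency(f), f$Vmax / f$Km)
})

test_that("Vmax scaling to whole-organ capacity is the documented unit conversion", {
  sf <- scaling_factors()
  expect_equal(scale_vmax_to_in_vivo(1.2, "liver microsomes", sf), 1.2 * 35 * 60)
  expect_equal(scale_vmax_to_in_vivo(1.2, "liver microsomes", sf), 2520)
  expect_equal(scale_vmax_to_in_vivo(0.99, "plasma", sf), 0.99 * 550 * 60)
  expect_equal(scale_vmax_to_in_vivo(0.99, "plasma", sf), 32670)
  expect_equal(scale_vmax_to_in_vivo(0, "liver cytosol", sf), 0)
  expect_error(scale_vmax_to_in_vivo(1, "kidney slices", sf),
               class = "revdosim_validation_error")
  # the alternative plasma-protein conversion basis is a config switch
  alt <- scaling_factors(plasma_basis_mg_per_g = 41)
  expect_equal(scale_vmax_to_in_vivo(1, "plasma", alt), 41 * 60)
})

test_that("incubation unbound fractions act through the in vivo Km", {
  met <- build_metabolism("rat", sf = scaling_factors(fupla = 0.5))
  ref <- build_metabolism("rat")
  expect_equal(met$pla$km, ref$pla$km * 0.5)
  expect_equal(met$pla$vmax, ref$pla$vmax)
})

test_that("mm_fit supports broom-style tidy and glance", {
  f <- fit_michaelis_menten(gen_incubation_data(5, 1, noise = noise_model(cv = 0.02)))
  td <- tidy(f)
  expect_setequal(td$term, c("Km", "Vmax"))
  gl <- glance(f)
  expect_true(gl$converged)
  expect_equal(gl$catalytic_efficiency, f$Vmax / f$Km)
})
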