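test_that("a zero dose leaves every state identically zero", {
  m <- pbk_model("rat")
  s <- quick_sim(m, 0, n_out = 50)
  expect_true(all(s$amounts == 0))
  expect_equal(unbound_cmax(s), 0)
})

test_that("with all elimination disabled the body plus lumen conserves the dose", {
  m <- elimination_free_model("rat")
  s <- quick_sim(m, 5, n_out = 100)
  body <- rowSums(s$amounts[, c("lumen", revdosim:::PBK_COMPARTMENTS)])
  expect_true(all(abs(body / s$dose_umol - 1) < 1e-3))
})

test_that("mass balance holds within 0.1% across six decades of dose", {
  m <- pbk_model("rat")
  for (d in c(1e-4, 1e-1, 10, 1000)) {
    s <- quick_sim(m, d, n_out = 120)
    expect_true(all(s$mass_balance > 0.999 & s$mass_balance < 1.001))
  }
})

test_that("the absorption rate constant defaults to 1 per hour", {
  expect_equal(pbk_model("rat")$ka, 1)
  expect_equal(pbk_model("human")$physiology$renal_clearance, 6.7)
  expect_error(pbk_model("rat", ka = 0), class = "revdosim_validation_error")
})

test_that("a compartment without a partition coefficient is rejected", {
  chem <- default_chemical("profenofos")
  p <- resolve_partitions(NULL, chem)
  expect_error(pbk_model("rat", partitions = p[p$tissue != "brain", ]),
               "brain", class = "revdosim_validation_error")
})

test_that("renal-only elimination matches the closed-form terminal rate CL*fup/Vss", {
  phys <- default_physiology("rat")
  m <- pbk_model("rat",
                 metabolism = build_metabolism("rat", kinetics = zero_kinetics("rat")))
  V <- phys$tissue_volumes
  kp <- m$kp
  vss <- sum(V[setdiff(names(V), c("venous_blood", "arterial_blood"))] *
               kp[setdiff(names(V), c("venous_blood", "arterial_blood"))]) +
    V[["venous_blood"]] + V[["arterial_blood"]]
  kel_expected <- phys$renal_clearance * m$chem$fup / vss
  s <- simulate_pbk(m, 1, hours = 2000, n_out = 300, rtol = 1e-8, atol = 1e-12)
  cv <- s$amounts[, "venous_blood"] / V[["venous_blood"]]
  tail_i <- s$times > 800
  slope <- -stats::coef(stats::lm(log(cv[tail_i]) ~ s$times[tail_i]))[2]
  expect_lt(abs(slope - kel_expected) / kel_expected, 0.05)
})

test_that("halving the solver tolerances changes the unbound Cmax by less than 0.1%", {
  m <- pbk_model("rat")
  a <- simulate_pbk(m, 1, n_out = 300, rtol = 1e-8, atol = 1e-10)
  b <- simulate_pbk(m, 1, n_out = 300, rtol = 5e-9, atol = 5e-11)
  expect_lt(abs(a$cmax_unbound_uM - b$cmax_unbound_uM) / b$cmax_unbound_uM,
            1e-3)
})

test_that("unbound Cmax is fup times the venous peak and never exceeds the total", {
  m <- pbk_model("rat")
  s <- quick_sim(m, 1)
  expect_equal(s$cmax_unbound_uM, m$chem$fup * s$cmax_venous_uM)
  expect_lte(s$cmax_unbound_uM, s$cmax_venous_uM)
  chem1 <- chemical_properties("free", m$chem$molecular_weight,
                               m$chem$logKow, fup = 1)
  expect_equal(unbound_cmax(s, chem1), s$cmax_venous_uM)
})

test_that("the dose to Cmax map is strictly increasing with linear low-dose kinetics", {
  m <- pbk_model("rat")
  map <- dose_to_cmax_map(m, doses = 10^seq(-4, 3, length.out = 15), n_out = 250)
  expect_true(all(diff(map$cmax_unbound_uM) > 0))
  # doubling the dose never lowers Cmax
  c1 <- quick_sim(m, 0.5)$cmax_unbound_uM
  c2 <- quick_sim(m, 1.0)$cmax_unbound_uM
  expect_gte(c2, c1)
  # low-dose regime: Cmax/dose constant within 2%
  r1 <- map$cmax_unbound_uM[1] / map$dose_mg_kg[1]
  r2 <- map$cmax_unbound_uM[2] / map$dose_mg_kg[2]
  expect_lt(abs(r1 - r2) / r1, 0.02)
  # saturable clearance makes high doses supralinear
  n <- nrow(map)
  slope_hi <- map$cmax_unbound_uM[n] / map$dose_mg_kg[n]
  expect_gt(slope_hi / r1, 2)
})

test_that("human blood concentrations run roughly twentyfold above rat at equal dose", {
  rat <- quick_sim(pbk_model("rat"), 0.1, n_out = 300)
  hum <- quick_sim(pbk_model("human"), 0.1, n_out = 300)
  ratio <- hum$cmax_unbound_uM / rat$cmax_unbound_uM
  expect_gt(ratio, 10)
  expect_lt(ratio, 30)
})

test_that("urinary metabolite excretion is cumulative, bounded, and closes the mole balance", {
  m <- pbk_model("rat", bcp = TRUE)
  expect_error(simulate_urinary_excretion(pbk_model("rat"), 1),
               class = "revdosim_validation_error")
  u0 <- simulate_urinary_excretion(m, 0, duration = 24, n_out = 50)
  expect_true(all(u0$cumulative_pct_dose == 0))

  u <- simulate_urinary_excretion(m, 35.8, duration = 120, n_out = 250)
  expect_true(all(diff(u$cumulative_pct_dose) >= -1e-9))
  expect_true(all(u$cumulative_pct_dose <= 100 + 1e-6))
  # glucuronidation is the metabolite's only elimination route, so the late
  # plateau equals the fraction of parent metabolised (mole balance)
  s <- simulate_pbk(m, 35.8, hours = 120, n_out = 250)
  frac_met <- 100 * s$amounts[nrow(s$amounts), "amet"] / s$dose_umol
  expect_equal(tail(u$cumulative_pct_dose, 1), unname(frac_met),
               tolerance = 0.02)
})

test_that("the BCP sub-model is rat-only and dose metrics survive tidying", {
  expect_error(pbk_model("human", bcp = TRUE),
               class = "revdosim_validation_error")
  s <- quick_sim(pbk_model("rat"), 1, n_out = 60)
  td <- tidy(s)
  expect_true(all(c("time_h", "compartment", "amount_umol",
                    "concentration_uM") %in% names(td)))
  expect_equal(sort(unique(td$compartment)),
               sort(revdosim:::pbk_state_names(s$model)))
})
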