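test_that("in the vanishing-lipophilicity limit Kp reduces to the tissue:plasma water ratio", {
  # with fup = 1 the binding corrections drop out and only the water terms
  # remain when logKow -> -inf
  chem <- chemical_properties("hydrophil", 100, logKow = -30, fup = 1)
  tab <- tissue_composition()
  kp <- estimate_partition_coefficients(chem, tab)
  pl <- tab[tab$tissue == "plasma", ]
  for (t in c("muscle", "liver", "brain", "fat")) {
    row <- tab[tab$tissue == t, ]
    expected <- (row$water + 0.7 * row$phospholipid) /
      (pl$water + 0.7 * pl$phospholipid)
    expect_equal(kp$kp[kp$tissue == t], expected, tolerance = 1e-6)
  }
})

test_that("fat Kp increases monotonically with logKow", {
  kps <- vapply(seq(0, 6, by = 0.5), function(lk) {
    chem <- chemical_properties("sweep", 100, logKow = lk, fup = 0.1)
    kp <- estimate_partition_coefficients(chem)
    kp$kp[kp$tissue == "fat"]
  }, numeric(1))
  expect_true(all(diff(kps) > 0))
})

test_that("profenofos partitioning is lipid-ordered and deterministic", {
  chem <- default_chemical("profenofos")
  kp1 <- estimate_partition_coefficients(chem)
  kp2 <- estimate_partition_coefficients(chem)
  expect_identical(kp1, kp2)
  k <- function(t) kp1$kp[kp1$tissue == t]
  expect_gt(k("fat"), k("muscle"))
  expect_gt(k("muscle"), 0)
  expect_true(all(kp1$kp > 0))
  # blood compartments carry the blood:plasma ratio
  expect_equal(k("venous_blood"), chem$blood_plasma_ratio)
})

test_that("ionization follows Henderson-Hasselbalch at pH 7.4", {
  # a strong acid (pKa 4.4) is 99.9% ionized: neutral fraction 1e-3
  acid <- chemical_properties("acid", 100, logKow = 3, pKa = 4.4,
                              ionization = "acid", fup = 0.5)
  base <- chemical_properties("base", 100, logKow = 3, pKa = 10.4,
                              ionization = "base", fup = 0.5)
  neut <- chemical_properties("neut", 100, logKow = 3, fup = 0.5)
  expect_equal(revdosim:::neutral_fraction(acid), 1 / (1 + 10^3))
  expect_equal(revdosim:::neutral_fraction(base), 1 / (1 + 10^3))
  expect_equal(revdosim:::neutral_fraction(neut), 1)
  # ionization suppresses lipid partitioning: ionized Kp_fat below neutral
  kpa <- estimate_partition_coefficients(acid)
  kpn <- estimate_partition_coefficients(neut)
  expect_lt(kpa$kp[kpa$tissue == "fat"], kpn$kp[kpn$tissue == "fat"])
})

test_that("doubling lipid fractions never decreases any Kp (scale consistency)", {
  chem <- chemical_properties("x", 100, logKow = 3, fup = 0.2)
  tab <- tissue_composition()
  tab2 <- tab
  grow <- tab2$tissue != "plasma"
  tab2$neutral_lipid[grow] <- pmin(tab2$neutral_lipid[grow] * 2, 1)
  tab2$phospholipid[grow] <- pmin(tab2$phospholipid[grow] * 2, 1)
  kp1 <- estimate_partition_coefficients(chem, tab)
  kp2 <- estimate_partition_coefficients(chem, tab2)
  tiss <- setdiff(kp1$tissue, c("venous_blood", "arterial_blood"))
  expect_true(all(kp2$kp[match(tiss, kp2$tissue)] >=
                    kp1$kp[match(tiss, kp1$tissue)] - 1e-12))
})

test_that("resolve_partitions honours user overrides per tissue", {
  chem <- default_chemical("profenofos")
  est <- estimate_partition_coefficients(chem)

  # supplying nothing: everything estimated
  none <- resolve_partitions(NULL, chem)
  expect_true(all(none$provenance == "estimated"))

  # supplying every compartment: identical passthrough
  all_kp <- setNames(est$kp, est$tissue)
  full <- resolve_partitions(all_kp, chem)
  expect_true(all(full$provenance == "user-supplied"))
  expect_equal(full$kp, est$kp)

  # one override: mixed provenance
  mixed <- resolve_partitions(c(liver = 2.5), chem)
  expect_equal(mixed$kp[mixed$tissue == "liver"], 2.5)
  expect_identical(sort(unique(mixed$provenance)),
                   c("estimated", "user-supplied"))

  expect_error(resolve_partitions(c(liver = -1), chem),
               class = "revdosim_validation_error")
  expect_error(resolve_partitions(c(gills = 2), chem), "gills",
               class = "revdosim_validation_error")
})

test_that("a composition table missing a model tissue is rejected by name", {
  chem <- default_chemical("profenofos")
  tab <- tissue_composition()
  expect_error(
    estimate_partition_coefficients(chem, tab[tab$tissue != "spleen", ]),
    "spleen", class = "revdosim_validation_error")
})
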