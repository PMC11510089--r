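test_that("generators are bit-reproducible for a fixed seed", {
  cfg <- sim_config(seed = 99)
  expect_identical(
    simulate_growth_curve("partial_inhibition", cfg),
    simulate_growth_curve("partial_inhibition", cfg)
  )
  expect_identical(
    simulate_plaque_counts(1e8, c(1e-5, 1e-6), 3, seed = 5),
    simulate_plaque_counts(1e8, c(1e-5, 1e-6), 3, seed = 5)
  )
  geno <- tibble::tibble(strain_id = c("g1", "g2"),
    intact_receptors = c("R1;R2", "R1;R3"))
  ph <- tibble::tibble(phage_id = c("A", "B"), main_receptors = c("R1", "R2"))
  expect_identical(
    simulate_cross_matrix(geno, ph, seed = 3),
    simulate_cross_matrix(geno, ph, seed = 3)
  )
  expect_identical(
    simulate_milk_counts(seed = 12), simulate_milk_counts(seed = 12)
  )
  # substreams for different labels differ
  expect_false(identical(
    simulate_growth_curve("no_effect", cfg, label = "a"),
    simulate_growth_curve("no_effect", cfg, label = "b")
  ))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(phenotype_mix = c(
    full_inhibition = 0.5, partial_inhibition = 0.2,
    transient_inhibition = 0.2, no_effect = 0.2
  )), "sum to 1")
  expect_error(sim_config(noise_sd_od = -0.1), ">= 0")
  expect_error(sim_config(n_phages = c(a = 0L)), "positive")
  expect_error(simulate_growth_curve("lysogenic", sim_config()), "phenotype")
})

test_that("noiseless phenotypes produce the intended endpoint differences", {
  cfg0 <- sim_config(seed = 4, noise_sd_od = 0)
  full <- simulate_growth_curve("full_inhibition", cfg0)
  expect_gt(classify_inhibition(full)$endpoint_diff, 0.1)
  expect_equal(as.character(classify_inhibition(full)$label), "strong")

  none <- simulate_growth_curve("no_effect", cfg0)
  expect_equal(classify_inhibition(none)$endpoint_diff, 0)
  expect_equal(as.character(classify_inhibition(none)$label), "none")

  # transient inhibition: suppressed early, rejoined by the endpoint
  tr <- simulate_growth_curve("transient_inhibition", cfg0)
  mid <- tr[tr$time_min == 140 & tr$replicate == 1, ]
  expect_gt(
    mid$od[mid$well_role == "positive_control"],
    mid$od[mid$well_role == "test"] + 0.1
  )
  expect_lt(classify_inhibition(tr)$endpoint_diff, 0.05)

  # partial inhibition plateaus below control
  pa <- simulate_growth_curve("partial_inhibition", cfg0)
  expect_gt(classify_inhibition(pa)$endpoint_diff, 0.1)
})

test_that("plaque counts follow the Poisson plating model", {
  # mean identity: 1e9 * 0.1 mL * 1e-6 -> expected count 100
  set.seed(2)
  sims <- simulate_plaque_counts(1e9, 1e-6, plates_per_dilution = 2000,
    volume_ml = 0.1)
  expect_equal(mean(sims$plaques), 100, tolerance = 0.02)
  expect_equal(stats::var(sims$plaques), 100, tolerance = 0.1)

  # near-sterile plate: count 0 with probability exp(-1e-4)
  lo <- simulate_plaque_counts(1e3, 1e-6, plates_per_dilution = 5000,
    volume_ml = 0.1, seed = 8)
  expect_gte(mean(lo$plaques == 0), 0.999)

  expect_error(simulate_plaque_counts(1e8, 1e-6, volume_ml = 0), "positive")
  expect_error(simulate_plaque_counts(-1, 1e-6), "positive")
})

test_that("receptor-knockout rule drives simulated cross matrices", {
  geno <- tibble::tibble(strain_id = "s1", intact_receptors = "OmpC")
  ph <- tibble::tibble(phage_id = "A", main_receptors = "OmpC")
  m <- simulate_cross_matrix(geno, ph, seed = 1)
  # knocking out the only receptor makes the variant insensitive
  expect_equal(m$response[m$phage_id == "A"], "insensitive")

  geno2 <- tibble::tibble(strain_id = "s1",
    intact_receptors = "OmpC;OmpA;LPS-core-A")
  ph2 <- tibble::tibble(phage_id = c("A", "B"),
    main_receptors = c("OmpC", "LPS-core-A;OmpA"))
  m2 <- simulate_cross_matrix(geno2, ph2, seed = 1)
  # variant induced by A lacks OmpC only; B still binds via LPS or OmpA
  byA <- m2[m2$inducing_phage == "A", ]
  expect_equal(byA$response[byA$phage_id == "A"], "insensitive")
  expect_equal(byA$response[byA$phage_id == "B"], "sensitive")

  expect_error(simulate_cross_matrix(geno, ph[0, ], seed = 1), "Empty")
  expect_error(simulate_cross_matrix(
    tibble::tibble(strain_id = "s", intact_receptors = "R1"),
    tibble::tibble(phage_id = "A", main_receptors = "R9"), seed = 1
  ), "alphabet")
})

test_that("planted universally-binding phage is recovered as core", {
  # six genotypes all carrying a conserved receptor the core phage binds;
  # the core phage never induces variants, so its receptor is never lost
  geno <- tibble::tibble(
    strain_id = sprintf("g%d", 1:6),
    intact_receptors = paste0("CoreR;X", 1:6)
  )
  phages <- tibble::tibble(
    phage_id = c("core", "p1", "p2", "p3"),
    main_receptors = c("CoreR", "X1", "X2", "X3")
  )
  m <- simulate_cross_matrix(geno, phages, seed = 7)
  m <- m[m$inducing_phage != "core", ]
  s <- analyze_cross_sensitivity(m)
  expect_true("core" %in% s$core_phages)
})

test_that("spot, biofilm, milk and stability generators have the assumed structure", {
  spots <- simulate_spot_grid(
    tibble::tibble(strain_id = c("a", "b"), threshold_pfu_ml = c(2e4, Inf)),
    seed = 3
  )
  calls <- spots |>
    dplyr::group_by(strain_id) |>
    dplyr::group_modify(~ call_sensitivity(.x)) |>
    dplyr::ungroup()
  expect_equal(as.character(calls$label[calls$strain_id == "a"]), "sensitive")
  expect_equal(as.character(calls$label[calls$strain_id == "b"]), "insensitive")

  plate <- simulate_biofilm_plate(
    tibble::tibble(strain_id = "s", capacity = 0.8, suppression = 0.99),
    n_replicates = 6, noise_sd = 0.01, seed = 4
  )
  expect_gt(compute_ebc(plate)$ebc_pct, 90)

  milk <- simulate_milk_counts("Staphylococcus aureus", reduction_pct = 43,
    seed = 5)
  rng <- sim_config()$control_endpoint_ranges[["Staphylococcus aureus"]]
  ctrl <- milk$cfu_per_ml[milk$arm == "control"]
  expect_true(all(ctrl > rng[1] / 10 & ctrl < rng[2] * 10))

  stab <- simulate_stability_series(seed = 6)
  expect_equal(nrow(stab), 18)
  expect_true(all(stab$titer_pfu_ml > 0))
  sp <- stability_percent(stab)
  expect_equal(sp$stability_pct[1], 100)
})
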