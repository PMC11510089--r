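test_that("singleton optimum and planted two-phage cover are recovered", {
  # one phage covering everything
  lytic <- tibble::tibble(phage_id = "P1", strain_id = sprintf("s%d", 1:6),
    label = "strong")
  d <- design_cocktail(lytic, toy_phage_records("P1"))
  expect_equal(d$selected, "P1")
  expect_equal(d$coverage, 1)
  expect_true(all(d$strains$redundancy_depth == 1))

  # planted receptor-distinct pair among decoys; brute force confirms optimal
  strains <- sprintf("s%d", 1:6)
  covers <- list(P1 = strains[1:3], P2 = strains[4:6],
    P3 = strains[c(1, 4)], P4 = strains[2])
  lytic2 <- purrr::imap_dfr(covers, function(ss, p) {
    tibble::tibble(phage_id = p, strain_id = strains,
      label = ifelse(strains %in% ss, "strong", "none"))
  })
  phages2 <- toy_phage_records(c("P1", "P2", "P3", "P4"),
    c("R1", "R2", "R1", "R2"))
  d2 <- design_cocktail(lytic2, phages2)
  expect_equal(sort(d2$selected), c("P1", "P2"))
  bf <- brute_force_coverage(lytic2)
  expect_equal(d2$coverage, bf$coverage)
  expect_true(list(c("P1", "P2")) %in% bf$sets)
})

test_that("tie-breaking prefers receptor-distinct then strongly lytic phages", {
  strains <- sprintf("s%d", 1:4)
  # P1 selected first (covers 3). P2 and P3 both add 1 new strain; P3 shares
  # P1's receptor class, P2 does not -> P2 wins the tie.
  lytic <- dplyr::bind_rows(
    tibble::tibble(phage_id = "P1", strain_id = strains,
      label = c("strong", "strong", "strong", "none")),
    tibble::tibble(phage_id = "P2", strain_id = strains,
      label = c("none", "none", "none", "weak")),
    tibble::tibble(phage_id = "P3", strain_id = strains,
      label = c("none", "none", "none", "strong"))
  )
  phages <- toy_phage_records(c("P1", "P2", "P3"), c("R1", "R2", "R1"))
  d <- design_cocktail(lytic, phages)
  expect_equal(d$selected, c("P1", "P2"))

  # with identical receptors the stronger phage wins instead
  phages_same <- toy_phage_records(c("P1", "P2", "P3"), c("R1", "R1", "R1"))
  d2 <- design_cocktail(lytic, phages_same)
  expect_equal(d2$selected, c("P1", "P3"))
})

test_that("coverage mode, monotonicity and redundancy-depth invariants", {
  set.seed(11)
  for (i in 1:10) {
    lytic <- random_panel(5, 10)
    phages <- toy_phage_records(sprintf("P%02d", 1:5))
    d_any <- design_cocktail(lytic, phages, coverage = "any")
    d_strong <- design_cocktail(lytic, phages, coverage = "strong")
    expect_gte(d_any$coverage, d_strong$coverage)

    # coverage never decreases as max_size grows
    covs <- purrr::map_dbl(1:5, function(k) {
      design_cocktail(lytic, phages, max_size = k)$coverage
    })
    expect_true(all(diff(covs) >= 0))

    # selecting all candidates matches the panel overlap row
    d_all <- design_cocktail(lytic, phages, max_size = Inf)
    s <- summarize_panel(lytic)
    ov <- s[s$phage_id == "all", ]
    expect_equal(100 * d_all$coverage, ov$strong_pct + ov$weak_pct,
      tolerance = 0.01)
  }
})

test_that("resilience and core phages use the cross matrix when available", {
  # sA covered by both phages, sB only by P2, sC only by P1, so greedy keeps
  # both components and sA gains receptor-distinct redundancy
  lytic <- dplyr::bind_rows(
    tibble::tibble(phage_id = "P1", strain_id = c("sA", "sB", "sC"),
      label = c("strong", "none", "strong")),
    tibble::tibble(phage_id = "P2", strain_id = c("sA", "sB", "sC"),
      label = c("strong", "strong", "none"))
  )
  phages <- toy_phage_records(c("P1", "P2"), c("R1", "R2"))
  cross <- tibble::tibble(
    variant_id = c("vA1", "vA1", "vB1", "vB1"),
    parent_strain = c("sA", "sA", "sB", "sB"),
    phage_id = c("P1", "P2", "P1", "P2"),
    response = c("insensitive", "sensitive", "insensitive", "insensitive")
  )
  d <- design_cocktail(lytic, phages, cross = cross)
  expect_setequal(d$selected, c("P1", "P2"))
  res <- setNames(d$strains$resilient, d$strains$strain_id)
  # sA's variant is rescued by P2; sB has a single covering phage and a
  # variant resisting both components
  expect_true(res[["sA"]])
  expect_false(res[["sB"]])
  # P2 fails on vB1 -> not core; on a matrix where it always rescues -> core
  expect_equal(d$core_phages, character(0))
  d2 <- design_cocktail(lytic, phages, cross = cross[1:2, ])
  expect_equal(d2$core_phages, "P2")

  # without a cross matrix, receptor-class distinctness drives resilience
  d3 <- design_cocktail(lytic, phages)
  res3 <- setNames(d3$strains$resilient, d3$strains$strain_id)
  expect_true(res3[["sA"]])
  expect_false(res3[["sB"]])
  d4 <- design_cocktail(lytic, toy_phage_records(c("P1", "P2"), c("R1", "R1")))
  expect_false(any(d4$strains$resilient))
})

test_that("equal-split formulation with one-significant-digit rounding", {
  expect_equal(unique(formulate(5, 1e8)$titer_pfu_ml), 2e7)
  expect_equal(unique(formulate(3, 1e8)$titer_pfu_ml), 3e7)
  expect_equal(formulate(3, 1e8)$titer_exact[1], 1e8 / 3)
  expect_equal(formulate("only_phage", 5e7)$titer_pfu_ml, 5e7)
  expect_error(formulate(character(), 1e8), "Empty")
  expect_error(formulate(3, -1), "positive")
})

test_that("stability percent log is 100 at the reference point", {
  two_pt <- tibble::tibble(month = c(0, 3), titer_pfu_ml = c(2e8, 2e8))
  s <- stability_percent(two_pt)
  expect_equal(s$stability_pct, c(100, 100))

  series <- tibble::tibble(
    month = rep(c(0, 3, 6), each = 2),
    species = rep(c("a", "b"), 3),
    titer_pfu_ml = c(2e8, 1e8, 1.5e8, 0.8e8, 1e8, 0.5e8)
  )
  s2 <- stability_percent(series)
  expect_equal(s2$final_titer, c(3e8, 2.3e8, 1.5e8))
  expect_equal(s2$stability_raw[1], 100)
  expect_error(stability_percent(
    tibble::tibble(month = 0, titer_pfu_ml = -1)), "positive")
})
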