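test_that("cross-sensitivity summary counts, rescue and core phages", {
  # minimal matrix: one sensitive cell among not_tested
  minimal <- tibble::tibble(
    variant_id = c("v1", "v1", "v2"),
    phage_id = c("A", "B", "A"),
    response = c("sensitive", "not_tested", "insensitive")
  )
  s <- analyze_cross_sensitivity(minimal)
  expect_equal(s$variants$n_sensitive[s$variants$variant_id == "v1"], 1)
  expect_equal(s$phages$rescue_count[s$phages$phage_id == "A"], 1)
  # A is tested on v2 and fails there, so it is not core
  expect_false("A" %in% s$core_phages)

  expect_error(analyze_cross_sensitivity(
    tibble::tibble(variant_id = "v", phage_id = "A", response = "?")
  ), "Malformed")
  expect_error(analyze_cross_sensitivity(
    tibble::tibble(variant_id = "v", phage_id = "A", response = "not_tested")
  ))
})

test_that("distribution categories partition the variants", {
  set.seed(7)
  for (i in 1:10) {
    n_v <- sample(3:10, 1)
    n_p <- sample(2:5, 1)
    cross <- expand.grid(
      variant_id = sprintf("v%d", 1:n_v),
      phage_id = sprintf("P%d", 1:n_p), stringsAsFactors = FALSE
    )
    cross$response <- sample(c("sensitive", "insensitive", "not_tested"),
      nrow(cross), replace = TRUE, prob = c(0.5, 0.4, 0.1))
    # guarantee every row has a tested cell
    cross$response[match(unique(cross$variant_id), cross$variant_id)] <-
      "insensitive"
    s <- analyze_cross_sensitivity(cross)
    d <- s$distribution
    expect_equal(d$n_ge2 + d$n_eq1 + d$n_eq0, d$n_variants)
    # a core phage's rescue count equals its tested row count
    core_rows <- s$phages[s$phages$is_core, ]
    expect_equal(core_rows$rescue_count, core_rows$n_tested_rows)
  }
})

test_that("packaged cross matrix reproduces the published resistance pattern", {
  cs <- load_fixture("cross_sensitivity")
  expect_equal(dplyr::n_distinct(cs$variant_id), 28)

  ec <- analyze_cross_sensitivity(
    dplyr::filter(cs, species == "Escherichia coli"))
  expect_equal(ec$distribution$n_variants, 20)
  expect_equal(ec$distribution$n_ge2, 14)
  expect_equal(ec$distribution$n_eq1, 5)
  expect_equal(ec$distribution$n_eq0, 1)

  sa <- analyze_cross_sensitivity(
    dplyr::filter(cs, species == "Staphylococcus aureus"))
  expect_equal(sa$distribution$n_variants, 8)
  expect_equal(sa$core_phages, "357Saur119PP")
  expect_equal(
    sa$phages$rescue_count[sa$phages$phage_id == "357Saur119PP"], 8)
})

test_that("receptor confirmation statuses follow the mutated-gene rule", {
  cs <- load_fixture("cross_sensitivity")
  conf <- confirm_receptors(
    load_fixture("receptor_predictions"), load_fixture("mutations"), cs
  )
  status <- setNames(conf$status, conf$phage_id)
  # tarS mutants (variants 119-121) confirm the WTA beta-GlcNAc prediction
  expect_equal(status[["351Saur083PP"]], "confirmed")
  expect_equal(status[["355Saur083PP"]], "confirmed")
  expect_true(all(c("119PP2018", "120PP2018", "121PP2018") %in%
    conf$supporting_variants[conf$phage_id == "351Saur083PP"][[1]]))
  # phages with no sequenced resistant variant
  expect_equal(status[["241Ecol014PP"]], "no_data")
  expect_equal(status[["357Saur119PP"]], "no_data")
  expect_equal(
    conf$supporting_variants[conf$phage_id == "241Ecol014PP"][[1]],
    character(0)
  )
  # ompC-only mutant fully inside the prediction
  expect_equal(status[["308Ecol101PP"]], "confirmed")
  # ompA/wbbD mutant outside the porin prediction
  expect_equal(status[["348Ecol098PP"]], "not_confirmed")
})

test_that("silent records are ignored and unmapped genes warn", {
  preds <- tibble::tibble(phage_id = "PX", predicted_receptors = "OmpC")
  cross <- tibble::tibble(variant_id = "v1", phage_id = "PX",
    response = "insensitive")
  # intergenic-only record: no informative mutation, so no sequencing signal
  silent_only <- tibble::tibble(variant_id = "v1", gene = "5SrRNA",
    effect = "intergenic")
  expect_equal(confirm_receptors(preds, silent_only, cross)$status, "no_data")

  # unmapped gene: warned, treated as non-matching
  unk <- tibble::tibble(variant_id = "v1", gene = "mysteryX",
    effect = "missense")
  expect_warning(
    res <- confirm_receptors(preds, unk, cross),
    "mysteryX"
  )
  expect_equal(res$status, "not_confirmed")

  # matching gene confirms
  omp <- tibble::tibble(variant_id = "v1", gene = "ompC", effect = "frameshift")
  expect_equal(confirm_receptors(preds, omp, cross)$status, "confirmed")
  # mixed mapped/unmapped-to-prediction genes -> partial
  mixed <- dplyr::bind_rows(omp,
    tibble::tibble(variant_id = "v1", gene = "tarS", effect = "missense"))
  expect_equal(confirm_receptors(preds, mixed, cross)$status,
    "partially_confirmed")
})
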