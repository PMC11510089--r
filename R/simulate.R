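#' Simulation configuration for synthetic assay data
#'
#' Bundles the parameters shared by the synthetic assay generators: the global
#' seed (fanned out to per-assay substreams by a deterministic hash of the
#' assay label, so each assay is independently reproducible), the panel shape,
#' plate-reader noise, plating geometry and the phenotype mix of the
#' cocktail-response classes observed in 24 h growth kinetics. Default
#' phenotype proportions follow the observed split of classified strains
#' (22 fully inhibited, 6 partially, 4 transiently, 4 unaffected). Default
#' control endpoint densities in the milk model are the observed 24 h control
#' ranges: 4e7--2e8 CFU/mL for E. coli, 3e8--3e9 CFU/mL for S. aureus.
#'
#' @param seed Integer global seed.
#' @param n_strains_per_species Named counts of strains per species.
#' @param n_phages Named counts of phages per species.
#' @param noise_sd_od Gaussian noise sd on OD readings (absorbance units).
#' @param plate_volume Inoculated volume per plate in mL.
#' @param dilution_step Fold-change between successive dilutions.
#' @param phenotype_mix Named proportions over the four growth-response
#'   phenotypes; must sum to 1.
#' @param control_endpoint_ranges Named list of CFU/mL intervals per species.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_strains_per_species = c(
                         "Escherichia coli" = 18L,
                         "Staphylococcus aureus" = 15L
                       ),
                       n_phages = c(
                         "Escherichia coli" = 5L,
                         "Staphylococcus aureus" = 3L
                       ),
                       noise_sd_od = 0.02,
                       plate_volume = 0.1,
                       dilution_step = 10,
                       phenotype_mix = c(
                         full_inhibition = 22 / 36,
                         partial_inhibition = 6 / 36,
                         transient_inhibition = 4 / 36,
                         no_effect = 4 / 36
                       ),
                       control_endpoint_ranges = list(
                         "Escherichia coli" = c(4e7, 2e8),
                         "Staphylococcus aureus" = c(3e8, 3e9)
                       )) {
  if (abs(sum(phenotype_mix) - 1) > 1e-8) {
    abort("`phenotype_mix` proportions must sum to 1.")
  }
  if (!setequal(names(phenotype_mix), growth_phenotypes())) {
    abort(sprintf(
      "`phenotype_mix` must be named over: %s",
      paste(growth_phenotypes(), collapse = ", ")
    ))
  }
  if (any(n_strains_per_species <= 0) || any(n_phages <= 0)) {
    abort("Strain and phage counts must be positive.")
  }
  if (noise_sd_od < 0) abort("`noise_sd_od` must be >= 0.")
  if (plate_volume <= 0) abort("`plate_volume` must be positive.")
  structure(
    list(
      seed = as.integer(seed),
      n_strains_per_species = n_strains_per_species,
      n_phages = n_phages,
      noise_sd_od = noise_sd_od,
      plate_volume = plate_volume,
      dilution_step = dilution_step,
      phenotype_mix = phenotype_mix,
      control_endpoint_ranges = control_endpoint_ranges
    ),
    class = "sim_config"
  )
}

#' The four growth-response phenotypes
#'
#' Phenotype labels for a bacterial culture challenged with a phage cocktail:
#' complete suppression over the assay window (`full_inhibition`), growth to a
#' reduced plateau (`partial_inhibition`), early suppression with later
#' regrowth to the control kinetics (`transient_inhibition`), and growth
#' indistinguishable from control (`no_effect`).
#'
#' @return Character vector of the four labels.
#' @export
growth_phenotypes <- function() {
  c("full_inhibition", "partial_inhibition", "transient_inhibition", "no_effect")
}

#' Simulate a control/treated pair of bacterial growth curves
#'
#' The untreated control follows four-parameter logistic growth in OD units
#' (baseline 0.05, plateau drawn in 0.9--1.3, rate and midpoint fixed per
#' assay window). The treated curve follows the phenotype: `full_inhibition`
#' stays near baseline, `partial_inhibition` grows to a reduced plateau
#' (30--60% of control), `transient_inhibition` is delayed early but rejoins
#' the control kinetics, and `no_effect` matches the control within noise.
#' Independent Gaussian noise of sd `noise_sd_od` is added to every reading
#' and floored at 0.
#'
#' @param phenotype One of [growth_phenotypes()].
#' @param config A [sim_config()].
#' @param assay `"lytic"` (0--280 min every 20 min, OD620) or `"biofilm"`
#'   (0--24 h every 20 min, OD600).
#' @param n_replicates Wells per arm (default 2, duplicate wells).
#' @param label Substream label so different strains/phages get independent
#'   noise under one global seed.
#' @return A tibble with `time_min`, `od`, `well_role` (`positive_control` /
#'   `test`) and `replicate`, directly consumable by [classify_inhibition()].
#' @export
simulate_growth_curve <- function(phenotype, config = sim_config(),
                                  assay = c("lytic", "biofilm"),
                                  n_replicates = 2, label = "growth") {
  assay <- match.arg(assay)
  if (!phenotype %in% growth_phenotypes()) {
    abort(sprintf("Unknown phenotype '%s'.", phenotype))
  }
  times <- if (assay == "lytic") seq(0, 280, by = 20) else seq(0, 1440, by = 20)
  with_substream(config$seed, paste(label, assay, phenotype), {
    baseline <- 0.05
    plateau <- runif(1, 0.9, 1.3)
    rate <- if (assay == "lytic") runif(1, 0.035, 0.05) else runif(1, 0.008, 0.012)
    midpoint <- if (assay == "lytic") runif(1, 120, 160) else runif(1, 260, 340)
    logistic <- function(t, K, r, m) baseline + (K - baseline) / (1 + exp(-r * (t - m)))

    control_mu <- logistic(times, plateau, rate, midpoint)
    treated_mu <- switch(phenotype,
      full_inhibition = rep(baseline, length(times)),
      partial_inhibition = logistic(times, baseline +
        runif(1, 0.3, 0.6) * (plateau - baseline), rate, midpoint),
      transient_inhibition = logistic(times, plateau, rate * 1.6,
        midpoint + 0.35 * (max(times) - midpoint)),
      no_effect = control_mu
    )

    one_arm <- function(mu, role) {
      purrr::map_dfr(seq_len(n_replicates), function(r) {
        tibble::tibble(
          time_min = times,
          od = pmax(0, mu + rnorm(length(times), 0, config$noise_sd_od)),
          well_role = role,
          replicate = r
        )
      })
    }
    dplyr::bind_rows(
      one_arm(control_mu, "positive_control"),
      one_arm(treated_mu, "test")
    )
  })
}

#' Simulate plaque counts over a dilution series
#'
#' Each plate's plaque count is drawn Poisson with mean
#' `true_titer * volume_ml * dilution` -- the counting statistics of a
#' double-agar overlay assay.
#'
#' @param true_titer True titer in PFU/mL (> 0).
#' @param dilutions Dilution factors in (0, 1].
#' @param plates_per_dilution Plates per dilution level.
#' @param volume_ml Inoculated volume per plate in mL.
#' @param seed Optional seed (integer) for reproducibility.
#' @return A tibble with `dilution`, `plate_id`, `plaques`, `volume_ml`,
#'   directly consumable by [estimate_titer()].
#' @export
simulate_plaque_counts <- function(true_titer, dilutions,
                                   plates_per_dilution = 1, volume_ml = 0.1,
                                   seed = NULL) {
  if (true_titer <= 0) abort("`true_titer` must be positive.")
  if (volume_ml <= 0) abort("`volume_ml` must be positive.")
  if (any(dilutions <= 0 | dilutions > 1)) abort("Dilutions must lie in (0, 1].")
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(dilutions, function(d) {
    tibble::tibble(
      dilution = d,
      plate_id = seq_len(plates_per_dilution),
      plaques = rpois(plates_per_dilution, true_titer * volume_ml * d),
      volume_ml = volume_ml
    )
  })
}

#' Simulate a resistant-variant cross-sensitivity matrix from receptor genotypes
#'
#' Generative receptor-knockout model behind cross-sensitivity grids: for each
#' parent strain and each inducing phage, a resistant variant is derived by
#' knocking out one receptor class targeted by that phage (chosen at random
#' among the phage's main receptors present in the strain's genotype). A
#' variant is sensitive to a phage iff at least one of that phage's main
#' receptor classes remains intact. Deterministic given `seed`.
#'
#' @param genotypes Tibble with `strain_id` and `intact_receptors`
#'   (semicolon-separated receptor-class labels; non-empty for wild types).
#' @param phages Tibble with `phage_id` and `main_receptors`
#'   (semicolon-separated).
#' @param seed Integer seed.
#' @return A long tibble: `variant_id`, `parent_strain`, `inducing_phage`,
#'   `phage_id`, `response` (`sensitive` / `insensitive`).
#' @export
simulate_cross_matrix <- function(genotypes, phages, seed = 1L) {
  assert_columns(genotypes, c("strain_id", "intact_receptors"), "genotypes")
  assert_columns(phages, c("phage_id", "main_receptors"), "phages")
  if (nrow(phages) == 0) abort("Empty phage list.")
  split_set <- function(x) trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  geno <- lapply(setNames(as.character(genotypes$intact_receptors),
    genotypes$strain_id), split_set)
  if (any(lengths(geno) == 0)) abort("Wild-type genotypes must be non-empty.")
  mains <- lapply(setNames(as.character(phages$main_receptors),
    phages$phage_id), split_set)
  alphabet <- unique(unlist(geno))
  off <- setdiff(unique(unlist(mains)), alphabet)
  if (length(off) > 0) {
    abort(sprintf(
      "Phage main receptor(s) outside the genotype alphabet: %s",
      paste(off, collapse = ", ")
    ))
  }

  with_substream(seed, "cross_matrix", {
    rows <- list()
    for (s in names(geno)) {
      for (ind in names(mains)) {
        hit <- intersect(mains[[ind]], geno[[s]])
        if (length(hit) == 0) next # phage cannot infect: no variant induced
        knocked <- if (length(hit) == 1) hit else sample(hit, 1)
        intact <- setdiff(geno[[s]], knocked)
        rows[[length(rows) + 1]] <- tibble::tibble(
          variant_id = paste0(s, "_r", ind),
          parent_strain = s,
          inducing_phage = ind,
          phage_id = names(mains),
          response = unname(ifelse(
            vapply(mains, function(m) length(intersect(m, intact)) > 0, logical(1)),
            "sensitive", "insensitive"
          ))
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Simulate a serial-dilution spot-test grid
#'
#' Each strain has a detection threshold: spots at or above it show a positive
#' sign (clearance, turbidity or plaques, drawn at random among the positive
#' codes), spots below it show no clearance.
#'
#' @param strains Tibble with `strain_id` and `threshold_pfu_ml` (the lowest
#'   spotted titer giving a positive sign; `Inf` for an insensitive strain).
#' @param ladder Spotted titers (PFU/mL), default the ten-fold ladder
#'   `2e8 ... 2e3`.
#' @param n_replicates Independent replicate series (default 3).
#' @param seed Integer seed.
#' @return A tibble with `strain_id`, `replicate`, `spotted_titer_pfu_ml`,
#'   `observation`, consumable by [call_sensitivity()].
#' @export
simulate_spot_grid <- function(strains, ladder = 2 * 10^(8:3),
                               n_replicates = 3, seed = 1L) {
  assert_columns(strains, c("strain_id", "threshold_pfu_ml"), "strains")
  with_substream(seed, "spot_grid", {
    purrr::map_dfr(seq_len(nrow(strains)), function(i) {
      purrr::map_dfr(seq_len(n_replicates), function(r) {
        positive <- ladder >= strains$threshold_pfu_ml[i]
        tibble::tibble(
          strain_id = strains$strain_id[i],
          replicate = r,
          spotted_titer_pfu_ml = ladder,
          observation = ifelse(positive,
            sample(c("CL", "T", "P"), length(ladder), replace = TRUE,
              prob = c(0.6, 0.25, 0.15)),
            "NL"
          )
        )
      })
    })
  })
}

#' Simulate a biofilm MTT plate
#'
#' Untreated control wells read the strain's biofilm capacity (OD570);
#' phage-treated wells read the capacity scaled by `1 - suppression`.
#' Gaussian noise, floored at zero.
#'
#' @param strains Tibble with `strain_id`, `capacity` (control OD570) and
#'   `suppression` (fraction of biofilm suppressed by the cocktail, in
#'   \[0, 1\]; values yield `EBC ~ 100 * suppression`).
#' @param n_replicates Wells per arm (default 3).
#' @param noise_sd OD570 noise sd (default 0.03).
#' @param seed Integer seed.
#' @return A tibble with `strain_id`, `arm` (`test`/`control`), `od570`,
#'   `replicate`, consumable by [compute_ebc()].
#' @export
simulate_biofilm_plate <- function(strains, n_replicates = 3, noise_sd = 0.03,
                                   seed = 1L) {
  assert_columns(strains, c("strain_id", "capacity", "suppression"), "strains")
  if (any(strains$capacity < 0)) abort("Capacities must be >= 0.")
  with_substream(seed, "biofilm_plate", {
    purrr::map_dfr(seq_len(nrow(strains)), function(i) {
      mu <- c(
        control = strains$capacity[i],
        test = strains$capacity[i] * (1 - strains$suppression[i])
      )
      purrr::map_dfr(names(mu), function(arm) {
        tibble::tibble(
          strain_id = strains$strain_id[i],
          arm = arm,
          od570 = pmax(0, mu[[arm]] + rnorm(n_replicates, 0, noise_sd)),
          replicate = seq_len(n_replicates)
        )
      })
    })
  })
}

#' Simulate endpoint bacterial counts in the milk model
#'
#' Control-arm 24 h endpoint densities are lognormal with the log10 mean at
#' the midpoint of the species' observed control range and sd `sdlog10`;
#' phage-arm log10 counts are reduced by `reduction_pct` percent of the
#' control log10 mean, so the percent-log-reduction estimator recovers
#' `reduction_pct` in expectation.
#'
#' @param species Species name (must be a name of
#'   `config$control_endpoint_ranges`).
#' @param reduction_pct Planted percent log reduction (default 43).
#' @param n_replicates Replicates per arm (default 4).
#' @param sdlog10 Replicate sd on the log10 scale (default 0.15).
#' @param config A [sim_config()].
#' @param seed Optional seed overriding the config substream.
#' @return A tibble with `arm` (`phage`/`control`), `cfu_per_ml`, `replicate`,
#'   consumable by [log_reduction()].
#' @export
simulate_milk_counts <- function(species = "Staphylococcus aureus",
                                 reduction_pct = 43, n_replicates = 4,
                                 sdlog10 = 0.15, config = sim_config(),
                                 seed = NULL) {
  rng <- config$control_endpoint_ranges[[species]]
  if (is.null(rng)) abort(sprintf("No control range for species '%s'.", species))
  seed <- seed %||% config$seed
  with_substream(seed, paste("milk", species), {
    mu_c <- mean(log10(rng))
    mu_p <- mu_c * (1 - reduction_pct / 100)
    tibble::tibble(
      arm = rep(c("control", "phage"), each = n_replicates),
      cfu_per_ml = 10^c(
        rnorm(n_replicates, mu_c, sdlog10),
        rnorm(n_replicates, mu_p, sdlog10)
      ),
      replicate = rep(seq_len(n_replicates), 2)
    )
  })
}

#' Simulate a storage-stability titer series
#'
#' Component titers decay exponentially at `monthly_decay` per month with
#' multiplicative lognormal measurement noise.
#'
#' @param initial_titers Named vector of initial component titers (PFU/mL),
#'   one per species/component.
#' @param months Measurement months (default every 3 months to 24).
#' @param monthly_decay Exponential decay rate per month (default 0.02).
#' @param sdlog Lognormal measurement noise sd (default 0.1).
#' @param seed Integer seed.
#' @return A tibble with `month`, `species`, `titer_pfu_ml`, consumable by
#'   [stability_percent()].
#' @export
simulate_stability_series <- function(initial_titers = c(
                                        "Escherichia coli" = 2.16e8,
                                        "Staphylococcus aureus" = 1.28e8
                                      ),
                                      months = seq(0, 24, by = 3),
                                      monthly_decay = 0.02, sdlog = 0.1,
                                      seed = 1L) {
  if (any(initial_titers <= 0)) abort("Initial titers must be positive.")
  with_substream(seed, "stability_series", {
    purrr::map_dfr(names(initial_titers), function(sp) {
      tibble::tibble(
        month = months,
        species = sp,
        titer_pfu_ml = initial_titers[[sp]] * exp(-monthly_decay * months) *
          rlnorm(length(months), 0, sdlog)
      )
    })
  })
}
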