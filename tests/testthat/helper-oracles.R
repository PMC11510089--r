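# Independent oracles and small fixture builders used across tests.

# Exhaustive subset-enumeration oracle for the cocktail set-cover objective:
# best achievable strain coverage over all phage subsets of size <= max_size.
brute_force_coverage <- function(lytic, max_size = Inf,
                                 qualifying = c("strong", "weak")) {
  strains <- unique(as.character(lytic$strain_id))
  phages <- unique(as.character(lytic$phage_id))
  covers <- lapply(setNames(phages, phages), function(p) {
    unique(lytic$strain_id[lytic$phage_id == p & lytic$label %in% qualifying])
  })
  best <- 0
  best_sets <- list()
  for (k in seq_len(min(max_size, length(phages)))) {
    for (comb in utils::combn(phages, k, simplify = FALSE)) {
      cov <- length(unique(unlist(covers[comb]))) / length(strains)
      if (cov > best + 1e-12) {
        best <- cov
        best_sets <- list(sort(comb))
      } else if (abs(cov - best) < 1e-12) {
        best_sets <- c(best_sets, list(sort(comb)))
      }
    }
  }
  list(coverage = best, sets = best_sets)
}

# Random lytic-call panel: each phage covers each strain independently.
random_panel <- function(n_phages, n_strains, p_strong = 0.25, p_weak = 0.15) {
  phages <- sprintf("P%02d", seq_len(n_phages))
  strains <- sprintf("s%02d", seq_len(n_strains))
  grid <- expand.grid(phage_id = phages, strain_id = strains,
    stringsAsFactors = FALSE)
  grid$label <- sample(c("strong", "weak", "none"), nrow(grid), replace = TRUE,
    prob = c(p_strong, p_weak, 1 - p_strong - p_weak))
  tibble::as_tibble(grid)
}

# Receptor records for a toy panel: each phage gets one main receptor class
# from a small alphabet (distinct classes cycle through the alphabet).
toy_phage_records <- function(phage_ids, receptors = NULL) {
  if (is.null(receptors)) {
    receptors <- paste0("R", ((seq_along(phage_ids) - 1) %% 4) + 1)
  }
  tibble::tibble(phage_id = phage_ids, main_receptors = receptors)
}

# Noiseless kinetic pair with a prescribed endpoint difference.
flat_pair <- function(diff, endpoint_od = 1) {
  tibble::tibble(
    time_min = rep(c(0, 140, 280), 2),
    od = c(0.05, 0.5, endpoint_od, 0.05, 0.5, endpoint_od - diff),
    well_role = rep(c("positive_control", "test"), each = 3),
    replicate = 1L
  )
}

# Spot series on the standard ladder with positives at/above a threshold.
spot_series <- function(threshold, replicate = 1L, ladder = 2 * 10^(8:3)) {
  tibble::tibble(
    replicate = replicate,
    spotted_titer_pfu_ml = ladder,
    observation = ifelse(ladder >= threshold, "CL", "NL")
  )
}
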