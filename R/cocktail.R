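#' Design a phage cocktail by receptor-diverse greedy set cover
#'
#' Formalizes the rational cocktail-composition principle: maximize strain
#' coverage while combining phages that recognize distinct conserved surface
#' receptors, so that resistance arising against one component leaves the
#' strain covered by another. Selection is greedy: at each step the phage
#' adding the most newly covered strains is chosen, ties broken by (1) fewest
#' main-receptor classes shared with already-selected phages, (2) most strains
#' strongly inhibited, (3) lexicographic phage id. Selection stops when
#' coverage stops improving or `max_size` is reached.
#'
#' A strain counts as covered when its inhibition call is strong or weak
#' (`coverage = "any"`, the default) or strong only (`coverage = "strong"`).
#' After selection the design reports, per covered strain, its redundancy
#' depth (covering phages counted once per distinct main-receptor class
#' signature) and resilience: whether the strain stays covered after the loss
#' of any single covering phage, judged by receptor-class distinctness and --
#' where a resistant-variant cross matrix is supplied -- by each of the
#' strain's variants remaining sensitive to at least one other selected phage.
#' Core phages (components lytic against every resistant variant they were
#' tested on) are identified from the cross matrix via
#' [analyze_cross_sensitivity()].
#'
#' Anti-E. coli and anti-S. aureus components are designed independently:
#' call this once per species panel.
#'
#' @param lytic Inhibition calls: tibble with `phage_id`, `strain_id`, `label`
#'   (`strong`/`weak`/`none`), one row per pair.
#' @param phages Phage panel records: tibble with `phage_id` and
#'   `main_receptors` (semicolon-separated receptor-class labels); an optional
#'   `support_receptors` column is carried along.
#' @param cross Optional resistant-variant cross matrix (long format as in
#'   [analyze_cross_sensitivity()]), ideally with a `parent_strain` column
#'   linking variants to panel strains.
#' @param max_size Maximum number of phages to select. Default unlimited.
#' @param coverage `"any"` (strong or weak call covers) or `"strong"`.
#' @return An object of class `cocktail_design`: list with `selected`,
#'   `coverage` (fraction in \[0, 1\]), `covered_strains`, `strains`
#'   (per-strain tibble: `covered`, `redundancy_depth`, `resilient`),
#'   `core_phages`, `steps` (greedy trace) and `params`. Supports `tidy()`,
#'   `glance()`, `autoplot()` and `print()`.
#' @export
design_cocktail <- function(lytic, phages, cross = NULL, max_size = Inf,
                            coverage = c("any", "strong")) {
  coverage <- match.arg(coverage)
  assert_columns(lytic, c("phage_id", "strain_id", "label"), "lytic")
  assert_columns(phages, c("phage_id", "main_receptors"), "phages")
  if (nrow(phages) == 0) abort("Empty phage panel.")
  panel <- as.character(phages$phage_id)
  extra <- setdiff(unique(as.character(lytic$phage_id)), panel)
  if (length(extra) > 0) {
    abort(sprintf(
      "Phage id(s) in `lytic` missing from `phages`: %s",
      paste(extra, collapse = ", ")
    ))
  }

  strains <- sort(unique(as.character(lytic$strain_id)))
  qualifying <- if (coverage == "strong") "strong" else c("strong", "weak")
  covers <- lapply(setNames(panel, panel), function(p) {
    unique(as.character(lytic$strain_id[
      as.character(lytic$phage_id) == p &
        as.character(lytic$label) %in% qualifying
    ]))
  })
  strong_n <- vapply(setNames(panel, panel), function(p) {
    sum(as.character(lytic$phage_id) == p & as.character(lytic$label) == "strong")
  }, numeric(1))
  mains <- lapply(setNames(as.character(phages$main_receptors), panel), function(m) {
    trimws(strsplit(m, ";", fixed = TRUE)[[1]])
  })
  sig <- vapply(mains, function(m) paste(sort(m), collapse = "|"), character(1))

  selected <- character()
  covered <- character()
  steps <- list()
  while (length(selected) < max_size) {
    candidates <- setdiff(panel, selected)
    if (length(candidates) == 0) break
    gain <- vapply(candidates, function(p) {
      length(setdiff(covers[[p]], covered))
    }, numeric(1))
    if (max(gain) == 0) break
    best <- candidates[gain == max(gain)]
    if (length(best) > 1) {
      shared <- vapply(best, function(p) {
        length(intersect(mains[[p]], unlist(mains[selected])))
      }, numeric(1))
      best <- best[shared == min(shared)]
    }
    if (length(best) > 1) best <- best[strong_n[best] == max(strong_n[best])]
    pick <- sort(best)[1]
    selected <- c(selected, pick)
    covered <- union(covered, covers[[pick]])
    steps[[length(steps) + 1]] <- tibble::tibble(
      step = length(selected), phage_id = pick,
      new_strains = max(gain), coverage = length(covered) / length(strains)
    )
  }

  covering <- lapply(setNames(strains, strains), function(s) {
    selected[vapply(selected, function(p) s %in% covers[[p]], logical(1))]
  })
  depth <- vapply(covering, function(ps) length(unique(sig[ps])), numeric(1))

  cross_norm <- if (!is.null(cross)) normalize_cross(cross)
  resilient <- vapply(strains, function(s) {
    ps <- covering[[s]]
    if (length(ps) == 0) return(NA)
    recept_ok <- all(vapply(ps, function(p) {
      any(sig[setdiff(ps, p)] != sig[p])
    }, logical(1)))
    if (!recept_ok) return(FALSE)
    if (!is.null(cross_norm) && "parent_strain" %in% names(cross_norm)) {
      vs <- unique(cross_norm$variant_id[cross_norm$parent_strain == s])
      for (v in vs) {
        cells <- cross_norm[cross_norm$variant_id == v &
          cross_norm$phage_id %in% selected &
          cross_norm$response != "not_tested", , drop = FALSE]
        if (nrow(cells) > 0 && !any(cells$response == "sensitive")) return(FALSE)
      }
    }
    TRUE
  }, logical(1))

  core <- character()
  if (!is.null(cross_norm)) {
    sel_cells <- cross_norm[cross_norm$phage_id %in% selected, , drop = FALSE]
    sel_cells <- sel_cells[sel_cells$response != "not_tested", , drop = FALSE]
    if (nrow(sel_cells) > 0) {
      acs <- analyze_cross_sensitivity(sel_cells)
      core <- intersect(acs$core_phages, selected)
    }
  }

  structure(
    list(
      selected = selected,
      coverage = length(covered) / length(strains),
      covered_strains = sort(covered),
      strains = tibble::tibble(
        strain_id = strains,
        covered = strains %in% covered,
        redundancy_depth = unname(depth),
        resilient = unname(resilient)
      ),
      core_phages = core,
      steps = if (length(steps)) dplyr::bind_rows(steps) else tibble::tibble(),
      params = list(coverage = coverage, max_size = max_size,
        receptor_signatures = sig)
    ),
    class = "cocktail_design"
  )
}

#' @export
print.cocktail_design <- function(x, ...) {
  cat(sprintf(
    "Cocktail design: %d phage(s) [%s]\n  coverage %.1f%% of %d strains; core phage(s): %s\n  resilient strains: %d of %d covered\n",
    length(x$selected), paste(x$selected, collapse = ", "),
    100 * x$coverage, nrow(x$strains),
    if (length(x$core_phages)) paste(x$core_phages, collapse = ", ") else "(none)",
    sum(x$strains$resilient, na.rm = TRUE), sum(x$strains$covered)
  ))
  invisible(x)
}

#' @rdname design_cocktail
#' @param x A `cocktail_design` object.
#' @param ... Unused.
#' @export
tidy.cocktail_design <- function(x, ...) x$strains

#' @rdname design_cocktail
#' @export
glance.cocktail_design <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected),
    coverage = x$coverage,
    mean_redundancy_depth = mean(x$strains$redundancy_depth[x$strains$covered]),
    frac_resilient = mean(x$strains$resilient[x$strains$covered]),
    n_core_phages = length(x$core_phages)
  )
}

#' Split a component titer equally across selected phages
#'
#' A cocktail component formulated at `component_titer` PFU/mL is an
#' equal-titer mixture of its phages: each phage contributes
#' `component_titer / n`. The nominal per-phage titer is reported rounded to
#' one significant digit (as on a product label); the exact value is kept for
#' audit.
#'
#' @param selected Character vector of phage ids (or a single integer count).
#' @param component_titer Total component titer in PFU/mL.
#' @return A tibble with `phage_id`, `titer_pfu_ml` (1-significant-digit
#'   nominal) and `titer_exact`.
#' @examples
#' formulate(5, 1e8) # 2e7 each
#' formulate(3, 1e8) # 3e7 each
#' @export
formulate <- function(selected, component_titer) {
  if (length(selected) == 1 && is.numeric(selected)) {
    if (selected < 1 || selected != round(selected)) {
      abort("`selected` count must be a positive integer.")
    }
    selected <- paste0("phage_", seq_len(selected))
  }
  if (length(selected) == 0) abort("Empty phage selection.")
  if (!is.numeric(component_titer) || component_titer <= 0) {
    abort("`component_titer` must be positive.")
  }
  per <- component_titer / length(selected)
  tibble::tibble(
    phage_id = as.character(selected),
    titer_pfu_ml = signif(per, 1),
    titer_exact = per
  )
}

#' Storage stability as percent of log titer
#'
#' Summarizes a cocktail storage-stability series: at each timepoint the
#' component titers are summed to the final cocktail titer and stability is
#' expressed as the percentage of the log10 titer relative to the initial
#' (first) timepoint: `100 * log10(titer_t) / log10(titer_0)`. Reported
#' stability is rounded to the nearest integer; the raw value is retained.
#' The statistic is 100 at the reference point and invariant to a common
#' change of titer units as long as titers stay well above 1 PFU/mL.
#'
#' @param series Tibble with columns `month` and `titer_pfu_ml`, plus an
#'   optional `species` column identifying the components summed per month.
#' @return A tibble with one row per month: `month`, `final_titer`,
#'   `stability_raw`, `stability_pct`.
#' @export
stability_percent <- function(series) {
  assert_columns(series, c("month", "titer_pfu_ml"), "series")
  if (any(series$titer_pfu_ml <= 0)) abort("Titers must be positive.")
  if (any(series$month < 0)) abort("Months must be non-negative.")
  out <- series |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(final_titer = sum(.data$titer_pfu_ml), .groups = "drop") |>
    dplyr::arrange(.data$month)
  if (out$final_titer[1] <= 1) {
    abort("Initial titer must exceed 1 PFU/mL for a positive log reference.")
  }
  ref <- log10(out$final_titer[1])
  out |>
    dplyr::mutate(
      stability_raw = 100 * log10(.data$final_titer) / ref,
      stability_pct = round(.data$stability_raw)
    )
}
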