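#' Effectiveness of biofilm control (EBC)
#'
#' Percentage reduction in biofilm relative to the untreated control, from
#' MTT-assay absorbances (OD570):
#' `EBC = 100 - mean(A_test) * 100 / mean(A_control)`.
#' Replicate means enter both numerator and denominator. The value may be
#' negative (biofilm stimulated beyond control) and is never clamped.
#'
#' @param a_test Absorbance replicates of the phage-treated sample.
#' @param a_control Absorbance replicates of the 100% biofilm control.
#' @return EBC in percent.
#' @examples
#' ebc(0.30, 0.60) # 50
#' @export
ebc <- function(a_test, a_control) {
  if (any(a_test < 0) || any(a_control < 0)) abort("Absorbances must be >= 0.")
  if (mean(a_control) == 0) abort("Control absorbance mean is zero.")
  100 - mean(a_test) * 100 / mean(a_control)
}

#' Compute per-strain EBC from a long biofilm plate table
#'
#' @param data Tibble with columns `strain_id`, `arm` (`test` or `control`),
#'   `od570`, and optionally `assay` (e.g. `prevention` / `eradication`).
#' @return A tibble with one EBC per strain (per assay if present):
#'   `strain_id`, (`assay`,) `ebc_pct`.
#' @export
compute_ebc <- function(data) {
  assert_columns(data, c("strain_id", "arm", "od570"), "data")
  if (!all(data$arm %in% c("test", "control"))) {
    abort("`arm` must be 'test' or 'control'.")
  }
  grouping <- intersect(c("strain_id", "assay"), names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      ebc_pct = ebc(.data$od570[.data$arm == "test"],
        .data$od570[.data$arm == "control"]),
      .groups = "drop"
    )
}

#' Fraction of strains at or above an EBC threshold
#'
#' @param results Tibble with one EBC per strain: columns `strain_id`,
#'   `ebc_pct` (grouped by `assay` if present).
#' @param threshold EBC threshold in percent (default 50).
#' @return A tibble with `n_above`, `n_strains` and `pct_strains`
#'   (integer-rounded percentage of strains with EBC >= threshold).
#' @examples
#' res <- tibble::tibble(strain_id = 1:22, ebc_pct = c(rep(80, 13), rep(10, 9)))
#' summarize_ebc(res) # 13 of 22 -> 59%
#' @export
summarize_ebc <- function(results, threshold = 50) {
  assert_columns(results, c("strain_id", "ebc_pct"), "results")
  if (nrow(results) == 0) abort("No EBC results supplied.")
  grouping <- intersect("assay", names(results))
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      n_above = sum(.data$ebc_pct >= threshold),
      n_strains = dplyr::n(),
      pct_strains = round(100 * .data$n_above / .data$n_strains),
      .groups = "drop"
    )
}

#' Percent log reduction of bacteria in the milk model
#'
#' Efficacy of a phage cocktail in milk is expressed as the percentage
#' reduction of the log bacterial count relative to the untreated control:
#' `100 * (1 - mean(log10 N_phage) / mean(log10 N_control))`, with the control
#' log count taken as 100%. Significance of the difference in log10 counts is
#' assessed with a two-sided two-sample Student t-test (pooled variance by
#' default; set `var_equal = FALSE` for the Welch form), with the usual star
#' coding: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' With a single replicate in either arm the reduction is still computed but
#' the p-value is withheld (`p_value = NA`, `p_withheld = TRUE`).
#'
#' @param data Tibble with columns `arm` (`phage` or `control`) and
#'   `cfu_per_ml` (> 0).
#' @param var_equal Pooled-variance Student test (default) or Welch.
#' @return A one-row tibble: `reduction_pct`, `p_value`, `stars`,
#'   `n_phage`, `n_control`, `p_withheld`.
#' @examples
#' d <- tibble::tibble(
#'   arm = rep(c("control", "phage"), each = 4),
#'   cfu_per_ml = c(rep(1e8, 4), rep(1e4, 4))
#' )
#' log_reduction(d) # 50% reduction
#' @export
log_reduction <- function(data, var_equal = TRUE) {
  assert_columns(data, c("arm", "cfu_per_ml"), "data")
  if (!all(data$arm %in% c("phage", "control"))) {
    abort("`arm` must be 'phage' or 'control'.")
  }
  if (any(data$cfu_per_ml <= 0)) abort("Counts must be positive.")
  lp <- log10(data$cfu_per_ml[data$arm == "phage"])
  lc <- log10(data$cfu_per_ml[data$arm == "control"])
  if (length(lp) == 0 || length(lc) == 0) abort("Both arms must be non-empty.")
  reduction <- 100 * (1 - mean(lp) / mean(lc))

  withheld <- length(lp) < 2 || length(lc) < 2
  p <- if (withheld) {
    NA_real_
  } else if (stats::var(lp) == 0 && stats::var(lc) == 0) {
    # Degenerate zero-variance arms: identical means give no evidence of a
    # difference; distinct means are separated with certainty.
    if (mean(lp) == mean(lc)) 1 else 0
  } else {
    t.test(lp, lc, var.equal = var_equal)$p.value
  }

  tibble::tibble(
    reduction_pct = reduction,
    p_value = p,
    stars = significance_stars(p),
    n_phage = length(lp),
    n_control = length(lc),
    p_withheld = withheld
  )
}

#' Significance stars for p-values
#'
#' Step function with breakpoints exactly at 0.05, 0.01 and 0.001:
#' `***` below 0.001, `**` below 0.01, `*` below 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values (NA allowed).
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}
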