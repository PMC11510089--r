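#' Call strain sensitivity from a serial-dilution spot test
#'
#' In a spot test, ten-fold dilutions of a phage preparation are spotted on a
#' bacterial lawn and each spot is scored `CL` (clearance), `T` (turbidity),
#' `P` (discrete plaques) or `NL` (no clearance). A strain's sensitivity is
#' read off the lowest spotted titer still giving a positive sign (CL, T or P):
#' titers are banded by order of magnitude (floor of log10 PFU/mL), bands 3--5
#' are called sensitive, bands 6--8 intermediate, and a strain with no positive
#' spot up to the top of the ladder is insensitive. Replicate series are
#' combined by majority vote, ties resolved toward the less sensitive label.
#'
#' @param spots A tibble with columns `spotted_titer_pfu_ml`, `observation`
#'   (one of `CL`, `T`, `P`, `NL`) and optionally `replicate` (defaults to a
#'   single replicate). All replicates must share the same dilution ladder.
#' @return A one-row tibble: `label` (factor `sensitive` < `intermediate` <
#'   `insensitive`), `lowest_positive_titer` (PFU/mL, `NA` when insensitive)
#'   and `n_replicates`.
#' @examples
#' s <- tibble::tibble(
#'   spotted_titer_pfu_ml = 2 * 10^(8:3),
#'   observation = c("CL", "CL", "CL", "CL", "CL", "NL")
#' )
#' call_sensitivity(s) # positive down to 2e4 -> sensitive
#' @export
call_sensitivity <- function(spots) {
  assert_columns(spots, c("spotted_titer_pfu_ml", "observation"), "spots")
  if (nrow(spots) == 0) abort("Empty spot series.")
  codes <- c("CL", "T", "P", "NL")
  if (!all(spots$observation %in% codes)) {
    abort("`observation` must be one of CL, T, P, NL.")
  }
  if (!("replicate" %in% names(spots))) spots$replicate <- 1L

  ladders <- spots |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(
      ladder = paste(sort(unique(.data$spotted_titer_pfu_ml)), collapse = ","),
      .groups = "drop"
    )
  if (length(unique(ladders$ladder)) != 1) {
    abort("Replicates must share the same dilution ladder.")
  }

  per_rep <- spots |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(
      lowest_positive = if (any(.data$observation != "NL")) {
        min(.data$spotted_titer_pfu_ml[.data$observation != "NL"])
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(label = band_sensitivity(.data$lowest_positive))

  # Majority consensus; ties resolved toward the less sensitive label.
  lv <- c("sensitive", "intermediate", "insensitive")
  counts <- table(factor(per_rep$label, levels = lv))
  winners <- names(counts)[counts == max(counts)]
  label <- winners[length(winners)] # lv order: last winner is least sensitive

  lpt <- per_rep$lowest_positive[per_rep$label == label]
  tibble::tibble(
    label = factor(label, levels = lv),
    lowest_positive_titer = if (label == "insensitive") NA_real_ else min(lpt),
    n_replicates = nrow(per_rep)
  )
}

# Order-of-magnitude banding of the lowest positive titer.
band_sensitivity <- function(lowest_positive_titer) {
  band <- floor(log10(lowest_positive_titer))
  label <- ifelse(is.na(band), "insensitive",
    ifelse(band <= 5, "sensitive", "intermediate")
  )
  factor(label, levels = c("sensitive", "intermediate", "insensitive"))
}

#' Summarize cocktail host range per species
#'
#' Percentages of strains called sensitive, intermediate and insensitive within
#' each species, from one sensitivity call per strain.
#'
#' @param calls A tibble with columns `strain_id`, `label` and optionally
#'   `species` (without it a single overall row is returned).
#' @return A tibble with `species` (if supplied), `sensitive_pct`,
#'   `intermediate_pct`, `insensitive_pct` (rounded to one decimal) and
#'   `n_strains`.
#' @export
summarize_host_range <- function(calls) {
  assert_columns(calls, c("strain_id", "label"), "calls")
  if (nrow(calls) == 0) abort("No sensitivity calls supplied.")
  lv <- c("sensitive", "intermediate", "insensitive")
  if (!all(as.character(calls$label) %in% lv)) {
    abort("`label` must be one of sensitive/intermediate/insensitive.")
  }
  grouping <- if ("species" %in% names(calls)) "species" else character()
  calls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      sensitive_pct = pct1(mean(.data$label == "sensitive")),
      intermediate_pct = pct1(mean(.data$label == "intermediate")),
      insensitive_pct = pct1(mean(.data$label == "insensitive")),
      n_strains = dplyr::n(),
      .groups = "drop"
    )
}
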