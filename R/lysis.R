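#' Classify phage-induced growth inhibition from plate-reader kinetics
#'
#' Compares the endpoint optical density of untreated (positive-control) wells
#' against phage-treated test wells and labels the effect on bacterial growth.
#' The endpoint difference is `mean(control OD) - mean(test OD)` at the final
#' shared timepoint, replicates averaged. Labels follow the absorbance-difference
#' rule used for 280-min OD620 lytic assays: a difference above 0.1 is strong
#' inhibition, a difference in the closed interval \[0.05, 0.1\] is weak
#' inhibition, and below 0.05 the phage is considered to have no influence.
#'
#' Duplicate wells are averaged before differencing; blanks are not subtracted
#' (the control and test arms are differenced directly). If negative-control
#' wells are present and their endpoint OD exceeds `neg_control_max`, a
#' contamination flag is raised in the output.
#'
#' @param data Long-format kinetic data for a single phage-strain assay:
#'   columns `time_min`, `od`, `well_role` (one of `"test"`,
#'   `"positive_control"`, `"negative_control"`, `"blank"`) and optionally
#'   `replicate`.
#' @param thresholds Length-2 numeric `c(weak, strong)` OD-difference
#'   thresholds; default `c(0.05, 0.1)`.
#' @param neg_control_max Endpoint OD above which a negative control flags
#'   possible contamination. Default 0.2.
#' @return A one-row tibble with `endpoint_diff`, `label` (factor with levels
#'   `strong`, `weak`, `none`), `endpoint_min` (the shared final timepoint) and
#'   `neg_control_flag`.
#' @examples
#' kc <- tibble::tibble(
#'   time_min = rep(c(0, 280), 2),
#'   od = c(0.05, 1.0, 0.05, 0.2),
#'   well_role = rep(c("positive_control", "test"), each = 2)
#' )
#' classify_inhibition(kc)
#' @export
classify_inhibition <- function(data, thresholds = c(0.05, 0.1),
                                neg_control_max = 0.2) {
  assert_columns(data, c("time_min", "od", "well_role"), "data")
  stopifnot(length(thresholds) == 2, thresholds[1] <= thresholds[2])
  roles <- c("test", "positive_control", "negative_control", "blank")
  if (!all(data$well_role %in% roles)) {
    abort(sprintf("`well_role` must be one of: %s", paste(roles, collapse = ", ")))
  }
  if (any(data$od < 0)) abort("`od` must be non-negative.")
  ctrl <- data[data$well_role == "positive_control", , drop = FALSE]
  test <- data[data$well_role == "test", , drop = FALSE]
  if (nrow(ctrl) == 0 || nrow(test) == 0) {
    abort("Need at least one positive_control and one test well.")
  }
  tc <- sort(unique(ctrl$time_min))
  tt <- sort(unique(test$time_min))
  if (!identical(tc, tt)) {
    abort("Control and test wells must share the same timepoint grid.")
  }
  endpoint <- max(tc)
  diff <- mean(ctrl$od[ctrl$time_min == endpoint]) -
    mean(test$od[test$time_min == endpoint])

  neg <- data[data$well_role == "negative_control", , drop = FALSE]
  neg_flag <- nrow(neg) > 0 &&
    mean(neg$od[neg$time_min == max(neg$time_min)]) > neg_control_max

  tibble::tibble(
    endpoint_diff = diff,
    label = inhibition_label(diff, thresholds),
    endpoint_min = endpoint,
    neg_control_flag = neg_flag
  )
}

# Pure threshold rule: strong strictly above the upper threshold, weak on the
# closed interval between the two, none below.
inhibition_label <- function(diff, thresholds = c(0.05, 0.1)) {
  label <- ifelse(diff > thresholds[2], "strong",
    ifelse(diff >= thresholds[1], "weak", "none")
  )
  factor(label, levels = c("strong", "weak", "none"))
}

#' Classify every phage-strain assay in a kinetic panel
#'
#' Convenience wrapper applying [classify_inhibition()] to each
#' `phage_id` x `strain_id` group of a long kinetic table.
#'
#' @param data Long kinetic data with columns `phage_id`, `strain_id`,
#'   `time_min`, `od`, `well_role`.
#' @inheritParams classify_inhibition
#' @return A tibble with one row per phage-strain pair: `phage_id`,
#'   `strain_id`, `endpoint_diff`, `label`.
#' @export
classify_panel <- function(data, thresholds = c(0.05, 0.1)) {
  assert_columns(data, c("phage_id", "strain_id", "time_min", "od", "well_role"),
    "data")
  data |>
    dplyr::group_by(.data$phage_id, .data$strain_id) |>
    dplyr::group_modify(~ classify_inhibition(.x, thresholds = thresholds)) |>
    dplyr::ungroup() |>
    dplyr::select("phage_id", "strain_id", "endpoint_diff", "label")
}

#' Summarize panel-level lytic coverage
#'
#' From a complete phage x strain matrix of inhibition calls, reports for each
#' phage the percentage of the strain collection with strong, weak and no
#' inhibition, plus an "overlap" row giving the best call per strain across all
#' phages (strong beats weak beats none) -- the combined coverage a cocktail of
#' all panel phages would achieve.
#'
#' @param calls A tibble with columns `phage_id`, `strain_id` and `label`
#'   (values `strong`/`weak`/`none`), one row per pair.
#' @return A tibble with columns `phage_id` (the overlap row has id `"all"`),
#'   `strong_pct`, `weak_pct`, `none_pct` (percentages rounded to one decimal)
#'   and `n_strains`.
#' @export
summarize_panel <- function(calls) {
  assert_columns(calls, c("phage_id", "strain_id", "label"), "calls")
  if (nrow(calls) == 0) abort("`calls` is empty.")
  lv <- c("strong", "weak", "none")
  if (!all(as.character(calls$label) %in% lv)) {
    abort("`label` must be one of strong/weak/none.")
  }
  strains <- unique(calls$strain_id)
  n <- length(strains)

  frac_row <- function(labels) {
    counts <- table(factor(labels, levels = lv))
    tibble::tibble(
      strong_pct = pct1(counts[["strong"]] / n),
      weak_pct = pct1(counts[["weak"]] / n),
      none_pct = pct1(counts[["none"]] / n)
    )
  }

  per_phage <- calls |>
    dplyr::group_by(phage_id = as.character(.data$phage_id)) |>
    dplyr::group_modify(~ frac_row(.x$label)) |>
    dplyr::ungroup()

  # Best call per strain across the panel, ranked strong > weak > none.
  best <- calls |>
    dplyr::mutate(rank = match(as.character(.data$label), lv)) |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::summarise(best = lv[min(.data$rank)], .groups = "drop")

  overlap <- dplyr::bind_cols(tibble::tibble(phage_id = "all"), frac_row(best$best))

  dplyr::bind_rows(per_phage, overlap) |>
    dplyr::mutate(n_strains = n)
}
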