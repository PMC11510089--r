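#' Analyze a resistant-variant cross-sensitivity matrix
#'
#' Phage-resistant variants (bacteria surviving an overdose of one "inducing"
#' phage) are spot-tested against the full phage panel. This summarizes the
#' resulting variant x phage grid: for each variant, how many tested phages it
#' remains sensitive to; the distribution of variants over the classes
#' "sensitive to >= 2", "exactly 1", "none"; per-phage rescue counts (how many
#' variants each phage still lyses); and the core phages -- phages that remain
#' lytic against every variant they were tested on.
#'
#' Not-tested cells are excluded from all denominators, never imputed.
#'
#' @param cross Long-format matrix: a tibble with columns `variant_id`,
#'   `phage_id` and `response`. Responses may be the symbols `+` / `-` / `x`
#'   or the words `sensitive` / `insensitive` / `not_tested`.
#' @return An object of class `cross_summary`: a list with `variants`
#'   (per-variant tibble: `n_sensitive`, `n_tested`, `category`),
#'   `distribution` (one row: `n_ge2`, `n_eq1`, `n_eq0`, `n_variants`),
#'   `phages` (per-phage tibble: `rescue_count`, `n_tested_rows`, `is_core`)
#'   and `core_phages`. Supports `tidy()` and `glance()`.
#' @export
analyze_cross_sensitivity <- function(cross) {
  cross <- normalize_cross(cross)
  tested <- cross[cross$response != "not_tested", , drop = FALSE]
  if (nrow(tested) == 0) abort("Every cell of the matrix is not_tested.")
  untested_rows <- setdiff(unique(cross$variant_id), unique(tested$variant_id))
  if (length(untested_rows) > 0) {
    abort(sprintf(
      "Variant row(s) with no tested cell: %s",
      paste(untested_rows, collapse = ", ")
    ))
  }

  variants <- tested |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(
      n_sensitive = sum(.data$response == "sensitive"),
      n_tested = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(category = dplyr::case_when(
      .data$n_sensitive >= 2 ~ ">=2",
      .data$n_sensitive == 1 ~ "=1",
      TRUE ~ "=0"
    ))

  distribution <- tibble::tibble(
    n_ge2 = sum(variants$category == ">=2"),
    n_eq1 = sum(variants$category == "=1"),
    n_eq0 = sum(variants$category == "=0"),
    n_variants = nrow(variants)
  )

  phages <- tested |>
    dplyr::group_by(.data$phage_id) |>
    dplyr::summarise(
      rescue_count = sum(.data$response == "sensitive"),
      n_tested_rows = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(is_core = .data$rescue_count == .data$n_tested_rows)

  structure(
    list(
      variants = variants, distribution = distribution, phages = phages,
      core_phages = phages$phage_id[phages$is_core]
    ),
    class = "cross_summary"
  )
}

normalize_cross <- function(cross) {
  assert_columns(cross, c("variant_id", "phage_id", "response"), "cross")
  map <- c(
    "+" = "sensitive", "-" = "insensitive", "x" = "not_tested",
    sensitive = "sensitive", insensitive = "insensitive",
    not_tested = "not_tested"
  )
  resp <- map[as.character(cross$response)]
  if (anyNA(resp)) {
    bad <- unique(cross$response[is.na(resp)])
    abort(sprintf("Malformed response code(s): %s", paste(bad, collapse = ", ")))
  }
  cross$response <- unname(resp)
  tibble::as_tibble(cross)
}

#' @export
print.cross_summary <- function(x, ...) {
  d <- x$distribution
  cat(sprintf(
    "Cross-sensitivity of %d resistant variants:\n  sensitive to >=2 phages: %d; exactly 1: %d; none: %d\n  core phage(s): %s\n",
    d$n_variants, d$n_ge2, d$n_eq1, d$n_eq0,
    if (length(x$core_phages)) paste(x$core_phages, collapse = ", ") else "(none)"
  ))
  invisible(x)
}

#' @rdname analyze_cross_sensitivity
#' @param x A `cross_summary` object.
#' @param ... Unused.
#' @export
tidy.cross_summary <- function(x, ...) x$variants

#' @rdname analyze_cross_sensitivity
#' @export
glance.cross_summary <- function(x, ...) {
  dplyr::mutate(x$distribution, n_core_phages = length(x$core_phages))
}

#' Default gene-to-receptor-class map
#'
#' The curated mapping from mutated bacterial genes (as found in
#' phage-resistant variants) to the receptor class they disable: `ompC` and
#' `ompA` to their outer-membrane porins, `wzzB`/`wbbD` to LPS O-antigen
#' synthesis, `tarS` to the wall teichoic acid beta-GlcNAc decoration. Shipped
#' as an editable table so other species can extend it.
#'
#' @return A tibble with columns `gene`, `receptor_class`, `product`.
#' @export
default_gene_map <- function() {
  readr::read_csv(
    system.file("extdata", "gene_receptor_map.csv", package = "phagemix"),
    show_col_types = FALSE
  )
}

#' Confirm receptor predictions from resistant-variant mutations
#'
#' Checks genome-based receptor predictions against the genes mutated in
#' phage-resistant variants. For each phage, the variants resistant to it
#' (insensitive in the cross matrix) that have sequencing data are examined:
#' each non-silent mutated gene is mapped to a receptor class via `gene_map`.
#' A phage is `confirmed` when some resistant variant has all of its non-silent
#' mutated genes mapping into the phage's predicted receptor set,
#' `partially_confirmed` when only a subset of a variant's genes maps,
#' `not_confirmed` when sequenced resistant variants exist but none of their
#' genes intersect the prediction, and `no_data` when no sequenced resistant
#' variant exists. Intergenic records are silent and ignored throughout; genes
#' absent from `gene_map` trigger a warning and are treated as non-matching.
#'
#' @param predictions Tibble with `phage_id` and `predicted_receptors`
#'   (semicolon-separated receptor-class labels, or a list-column).
#' @param mutations Tibble of mutation records: `variant_id`, `gene`, `effect`
#'   (one of `stop_gained`, `frameshift`, `missense`, `intergenic`).
#' @param cross Cross-sensitivity matrix in the format accepted by
#'   [analyze_cross_sensitivity()], used to identify which variants are
#'   resistant to which phage.
#' @param gene_map Gene-to-receptor-class table, see [default_gene_map()].
#' @return A tibble with one row per phage: `phage_id`, `status`,
#'   `supporting_variants` (list-column of variants with at least one mapping
#'   gene) and `n_resistant_sequenced`.
#' @export
confirm_receptors <- function(predictions, mutations, cross,
                              gene_map = default_gene_map()) {
  assert_columns(predictions, c("phage_id", "predicted_receptors"), "predictions")
  assert_columns(mutations, c("variant_id", "gene", "effect"), "mutations")
  assert_columns(gene_map, c("gene", "receptor_class"), "gene_map")
  if (any(!nzchar(mutations$gene))) abort("Empty gene symbol in `mutations`.")
  cross <- normalize_cross(cross)

  silent <- c("intergenic")
  informative <- mutations[!(mutations$effect %in% silent), , drop = FALSE]
  unmapped <- setdiff(unique(informative$gene), gene_map$gene)
  if (length(unmapped) > 0) {
    warn(sprintf(
      "Gene(s) not in gene_map, treated as non-matching: %s",
      paste(unmapped, collapse = ", ")
    ))
  }

  pred_sets <- lapply(predictions$predicted_receptors, function(p) {
    if (is.character(p)) trimws(strsplit(p, ";", fixed = TRUE)[[1]]) else p
  })
  names(pred_sets) <- predictions$phage_id

  purrr::map_dfr(predictions$phage_id, function(ph) {
    pred <- pred_sets[[ph]]
    resistant <- unique(cross$variant_id[
      cross$phage_id == ph & cross$response == "insensitive"
    ])
    sequenced <- intersect(resistant, unique(informative$variant_id))
    support <- character()
    full <- FALSE
    partial <- FALSE
    for (v in sequenced) {
      genes <- unique(informative$gene[informative$variant_id == v])
      classes <- gene_map$receptor_class[match(genes, gene_map$gene)]
      hit <- !is.na(classes) & classes %in% pred
      if (any(hit)) support <- c(support, v)
      if (length(genes) > 0 && all(hit)) full <- TRUE else if (any(hit)) partial <- TRUE
    }
    status <- if (length(sequenced) == 0) {
      "no_data"
    } else if (full) {
      "confirmed"
    } else if (partial) {
      "partially_confirmed"
    } else {
      "not_confirmed"
    }
    tibble::tibble(
      phage_id = ph, status = status,
      supporting_variants = list(support),
      n_resistant_sequenced = length(sequenced)
    )
  })
}
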