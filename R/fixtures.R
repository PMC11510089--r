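#' Load a packaged fixture table
#'
#' The package ships the published study tables as plain CSV fixtures:
#' \describe{
#'   \item{`strains`}{The mastitis isolate collection (18 E. coli + 15
#'     S. aureus strains).}
#'   \item{`phages`}{The eight phages with taxonomy and main/support
#'     receptor-class assignments.}
#'   \item{`cross_sensitivity`}{The resistant-variant x phage grid (28
#'     variants: 20 E. coli + 8 S. aureus), returned in long format with
#'     responses `sensitive` / `insensitive` / `not_tested`.}
#'   \item{`mutations`}{Mutated genes detected in sequenced resistant
#'     variants.}
#'   \item{`receptor_predictions`}{Genome-based receptor predictions per
#'     phage.}
#'   \item{`gene_receptor_map`}{The curated gene-to-receptor-class map.}
#'   \item{`stability`}{24-month storage-stability component titers.}
#'   \item{`lytic_summary`}{Published panel-level lytic-activity percentages
#'     (for cross-checking [summarize_panel()] arithmetic).}
#' }
#'
#' @param name One of the fixture names above.
#' @return A tibble.
#' @examples
#' nrow(dplyr::distinct(load_fixture("cross_sensitivity"),
#'   variant_id)) # 28 variants
#' @export
load_fixture <- function(name = c(
                           "strains", "phages", "cross_sensitivity",
                           "mutations", "receptor_predictions",
                           "gene_receptor_map", "stability", "lytic_summary"
                         )) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "phagemix")
  if (!nzchar(path)) abort(sprintf("Unknown fixture '%s'.", name))
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (name == "cross_sensitivity") {
    x <- x |>
      tidyr::pivot_longer(
        -dplyr::all_of(c("variant_id", "species", "parent_strain",
          "inducing_phage")),
        names_to = "phage_id", values_to = "response"
      )
    x <- normalize_cross(x)
  }
  x
}

#' Validate referential integrity across fixture tables
#'
#' Checks that every identifier in the relational fixtures resolves: phage ids
#' in the cross matrix, receptor predictions and lytic summary against the
#' phage table; variant ids in the mutation table against the cross matrix;
#' genes in the mutation table against the gene map; and the structural
#' invariants of the cross matrix (each variant insensitive to its inducing
#' phage whenever tested, every row tested at least once).
#'
#' @param fixtures Optional named list of tables (defaults to the packaged
#'   fixtures), so user-supplied datasets of the same shape can be validated.
#' @return A tibble of violations (`table`, `row`, `problem`); zero rows when
#'   everything resolves.
#' @export
validate_fixtures <- function(fixtures = NULL) {
  f <- fixtures %||% list(
    phages = load_fixture("phages"),
    cross_sensitivity = load_fixture("cross_sensitivity"),
    mutations = load_fixture("mutations"),
    receptor_predictions = load_fixture("receptor_predictions"),
    gene_receptor_map = load_fixture("gene_receptor_map")
  )
  out <- list()
  note <- function(table, row, problem) {
    out[[length(out) + 1]] <<- tibble::tibble(
      table = table, row = row, problem = problem
    )
  }

  phage_ids <- f$phages$phage_id
  cs <- f$cross_sensitivity
  bad <- which(!(cs$phage_id %in% phage_ids))
  for (i in bad) note("cross_sensitivity", i,
    sprintf("unknown phage_id '%s'", cs$phage_id[i]))
  bad <- which(!(cs$inducing_phage %in% phage_ids))
  for (i in bad) note("cross_sensitivity", i,
    sprintf("unknown inducing_phage '%s'", cs$inducing_phage[i]))

  # Invariant: the inducing cell is insensitive whenever tested.
  self <- cs[cs$phage_id == cs$inducing_phage & cs$response == "sensitive", ]
  for (v in self$variant_id) note("cross_sensitivity", NA_integer_,
    sprintf("variant '%s' sensitive to its inducing phage", v))
  by_var <- split(cs$response, cs$variant_id)
  for (v in names(by_var)) {
    if (all(by_var[[v]] == "not_tested")) {
      note("cross_sensitivity", NA_integer_,
        sprintf("variant '%s' has no tested cell", v))
    }
  }

  if (!is.null(f$receptor_predictions)) {
    bad <- which(!(f$receptor_predictions$phage_id %in% phage_ids))
    for (i in bad) note("receptor_predictions", i,
      sprintf("unknown phage_id '%s'", f$receptor_predictions$phage_id[i]))
  }
  if (!is.null(f$mutations)) {
    bad <- which(!(f$mutations$variant_id %in% cs$variant_id))
    for (i in bad) note("mutations", i,
      sprintf("variant_id '%s' absent from cross matrix", f$mutations$variant_id[i]))
  }
  if (length(out) == 0) {
    tibble::tibble(table = character(), row = integer(), problem = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Write an analysis result as a JSON + markdown report
#'
#' Emits a machine-readable JSON file and a human-readable markdown table for
#' a result object: a `cocktail_design`, a `cross_summary`, or any data frame
#' (e.g. the output of [stability_percent()] or [summarize_panel()]).
#'
#' @param x The result object.
#' @param path Output path without extension; `<path>.json` and `<path>.md`
#'   are written.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(x, path) {
  UseMethod("write_report")
}

#' @export
write_report.data.frame <- function(x, path) {
  jsonlite::write_json(x, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  writeLines(md_table(x), paste0(path, ".md"))
  invisible(paste0(path, c(".json", ".md")))
}

#' @export
write_report.cocktail_design <- function(x, path) {
  obj <- list(
    selected = x$selected,
    coverage = x$coverage,
    core_phages = x$core_phages,
    strains = x$strains,
    steps = x$steps
  )
  jsonlite::write_json(obj, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  md <- c(
    "# Cocktail design",
    "",
    sprintf("Selected phages: %s", paste(x$selected, collapse = ", ")),
    sprintf("Coverage: %.1f%%", 100 * x$coverage),
    sprintf("Core phages: %s",
      if (length(x$core_phages)) paste(x$core_phages, collapse = ", ") else "none"),
    "",
    md_table(x$strains)
  )
  writeLines(md, paste0(path, ".md"))
  invisible(paste0(path, c(".json", ".md")))
}

#' @export
write_report.cross_summary <- function(x, path) {
  obj <- list(
    distribution = x$distribution,
    variants = x$variants,
    phages = x$phages,
    core_phages = x$core_phages
  )
  jsonlite::write_json(obj, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  writeLines(
    c("# Resistant-variant cross-sensitivity", "", md_table(x$variants)),
    paste0(path, ".md")
  )
  invisible(paste0(path, c(".json", ".md")))
}

# Minimal pipe-table formatter for reports.
md_table <- function(df) {
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}
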