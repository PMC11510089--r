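#' Estimate phage titer from a dilution-series plaque count
#'
#' Computes the phage titer Mf (PFU/mL) from plaque counts collected over a
#' ten-fold (or other) dilution series by the weighted plate-count formula
#'
#' \deqn{M_f = \frac{\sum c}{V \cdot d \cdot (N_1 + 0.5 N_2 + 0.25 N_3 + \dots)}}
#'
#' where \eqn{\sum c} sums the plaques on every countable plate, \eqn{V} is the
#' inoculated volume (mL), \eqn{d} is the dilution factor of the least-dilute
#' counted level, and \eqn{N_k} is the number of counted plates at the k-th
#' counted dilution, weighted by successive halving. With a single counted
#' dilution this reduces to the classical \eqn{c / (V d N)} estimator.
#'
#' Plates outside the countability window (default 3--300 plaques) are excluded
#' before the formula is applied; only plates inside the window contribute to
#' \eqn{\sum c} and the \eqn{N_k}.
#'
#' @param counts A data frame with one row per plate and columns `dilution`
#'   (unitless factor in (0, 1], e.g. `1e-6`), `plaques` (non-negative integer
#'   count) and either a `volume_ml` column or the `volume_ml` argument.
#' @param volume_ml Inoculated volume per plate in mL (default 0.1). Ignored
#'   when `counts` carries a `volume_ml` column (which must be constant).
#' @param countable Length-2 numeric window of plaque counts considered
#'   countable, inclusive. Default `c(3, 300)`.
#' @return An object of class `titer_estimate`: a list with elements `mf`
#'   (PFU/mL), `sum_c`, `volume_ml`, `d` (least-dilute counted factor),
#'   `weighted_plate_count`, `n_plates_used`, `n_plates_total` and the per-plate
#'   audit table `plates`. Supports `tidy()`, `glance()` and `print()`.
#' @examples
#' plates <- tibble::tibble(dilution = 1e-6, plaques = 50)
#' estimate_titer(plates, volume_ml = 0.1)$mf # 5e8
#' @export
estimate_titer <- function(counts, volume_ml = NULL, countable = c(3, 300)) {
  assert_columns(counts, c("dilution", "plaques"), "counts")
  if (nrow(counts) == 0) abort("`counts` has zero plates.")
  if ("volume_ml" %in% names(counts)) {
    v <- unique(counts$volume_ml)
    if (length(v) != 1) abort("`volume_ml` must be constant across plates.")
    volume_ml <- v
  }
  volume_ml <- volume_ml %||% 0.1
  if (!is.numeric(volume_ml) || volume_ml <= 0) {
    abort("`volume_ml` must be a positive number.")
  }
  if (any(counts$dilution <= 0 | counts$dilution > 1)) {
    abort("`dilution` factors must lie in (0, 1].")
  }
  if (any(counts$plaques < 0) || any(counts$plaques != round(counts$plaques))) {
    abort("`plaques` must be non-negative integers.")
  }

  plates <- tibble::as_tibble(counts[c("dilution", "plaques")])
  plates$countable <- plates$plaques >= countable[1] & plates$plaques <= countable[2]
  used <- plates[plates$countable, , drop = FALSE]
  if (nrow(used) == 0) {
    abort("No plate falls inside the countable window; titer cannot be estimated.")
  }

  # Counted dilutions ordered from least dilute (largest factor) downwards;
  # the k-th counted level gets weight 1 / 2^(k - 1).
  levels <- sort(unique(used$dilution), decreasing = TRUE)
  n_k <- vapply(levels, function(d) sum(used$dilution == d), integer(1))
  weights <- 0.5^(seq_along(levels) - 1)
  weighted_n <- sum(weights * n_k)
  d <- levels[1]
  sum_c <- sum(used$plaques)
  mf <- sum_c / (volume_ml * d * weighted_n)

  structure(
    list(
      mf = mf, sum_c = sum_c, volume_ml = volume_ml, d = d,
      weighted_plate_count = weighted_n,
      n_plates_used = nrow(used), n_plates_total = nrow(plates),
      countable = countable, plates = plates
    ),
    class = "titer_estimate"
  )
}

#' @export
print.titer_estimate <- function(x, ...) {
  cat(sprintf(
    "Phage titer estimate: %.3g PFU/mL\n  sum of plaques %d over %d/%d plates, V = %g mL, d = %g, weighted plate count %.3g\n",
    x$mf, x$sum_c, x$n_plates_used, x$n_plates_total, x$volume_ml, x$d,
    x$weighted_plate_count
  ))
  invisible(x)
}

#' @rdname estimate_titer
#' @param x A `titer_estimate` object.
#' @param ... Unused.
#' @export
tidy.titer_estimate <- function(x, ...) {
  tibble::tibble(
    dilution = x$plates$dilution,
    plaques = x$plates$plaques,
    countable = x$plates$countable
  )
}

#' @rdname estimate_titer
#' @export
glance.titer_estimate <- function(x, ...) {
  tibble::tibble(
    mf_pfu_ml = x$mf, sum_c = x$sum_c, volume_ml = x$volume_ml, d = x$d,
    weighted_plate_count = x$weighted_plate_count,
    n_plates_used = x$n_plates_used, n_plates_total = x$n_plates_total
  )
}
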