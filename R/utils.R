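# Internal helpers shared across modules.

# Deterministic substream seed derived from a global seed and an assay label.
# Horner hash of the label bytes folded with the seed, kept below 2^31 so it
# is always a valid R RNG seed. Documented derivation rule: substreams for
# distinct labels are independent streams of the same global experiment.
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(as.character(label))) h <- (h * 31 + b) %% m
  as.integer((as.numeric(seed) %% m * 48271 + h) %% m)
}

with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, label))
  force(expr)
}

assert_columns <- function(data, cols, arg = deparse(substitute(data))) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s",
      arg, paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

# Percentage rounded to one decimal, as printed in panel summaries.
pct1 <- function(x) round(100 * x, 1)
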