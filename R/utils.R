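#' @keywords internal
"_PACKAGE"

# Child seeds are derived from the master seed by fixed offsets so that every
# stage is independently reproducible.  Offsets are documented in
# `seed_offsets`.  All derived seeds stay below .Machine$integer.max.
seed_offsets <- c(
  indicators = 1L,
  bacteria   = 2L,
  fungi      = 3L,
  yield      = 4L,
  network    = 5L,
  drivers    = 6L,
  plspm      = 7L
)

child_seed <- function(seed, stage) {
  stopifnot(stage %in% names(seed_offsets))
  (as.integer(seed) + seed_offsets[[stage]]) %% .Machine$integer.max
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

#' Percent change relative to a reference mean
#'
#' Signed percent change `100 * (treated - reference) / reference`, the
#' arithmetic used throughout treatment-vs-control reporting (yield, SQI,
#' network topology deltas).
#'
#' @param reference_mean numeric, reference (e.g. control) mean; must be
#'   nonzero.
#' @param treated_mean numeric, treated mean. Vectorised over both arguments.
#' @return numeric percent change(s), sign preserved.
#' @examples
#' percent_change(5089.53, 6492.69) # +27.57 % yield under modified biochar
#' @export
percent_change <- function(reference_mean, treated_mean) {
  if (!is.numeric(reference_mean) || !is.numeric(treated_mean))
    stop("inputs must be numeric", call. = FALSE)
  if (any(!is.finite(reference_mean)) || any(!is.finite(treated_mean)))
    stop("inputs must be finite", call. = FALSE)
  if (any(reference_mean == 0))
    stop("`reference_mean` must be nonzero", call. = FALSE)
  100 * (treated_mean - reference_mean) / reference_mean
}

read_tsv_file <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
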