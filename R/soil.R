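#' EC-to-TDS calibration line
#'
#' Linear calibration converting the electrical conductivity of a 5:1
#' water:soil extract (uS/cm at 25 C) into total dissolved solids (g/kg),
#' obtained gravimetrically for the trial soil: `TDS = 0.0032 EC - 1.7739`.
#'
#' @param slope g/kg per uS/cm, > 0.
#' @param intercept g/kg.
#' @param temperature_reference reference temperature, C.
#' @return object of class `calibration_line`.
#' @export
calibration_line <- function(slope = 0.0032, intercept = -1.7739,
                             temperature_reference = 25) {
  assert_scalar_number(slope, "slope", positive = TRUE)
  assert_scalar_number(intercept, "intercept")
  structure(list(slope = slope, intercept = intercept,
                 temperature_reference = temperature_reference),
            class = "calibration_line")
}

#' Total dissolved solids from extract conductivity
#'
#' Evaluates the calibration line and clips negative predictions to zero:
#' the line crosses zero near EC = 554 uS/cm, so low-salinity extracts would
#' otherwise yield physically impossible negative solids. A clip triggers a
#' warning.
#'
#' @param ec electrical conductivity, uS/cm, >= 0 (vectorised).
#' @param cal a [calibration_line()].
#' @return TDS in g/kg, >= 0.
#' @examples
#' tds_from_ec(3050) # 7.9861 g/kg
#' @export
tds_from_ec <- function(ec, cal = calibration_line()) {
  if (!is.numeric(ec) || any(!is.finite(ec)))
    stop("`ec` must be finite numeric", call. = FALSE)
  if (any(ec < 0)) stop("negative conductivity rejected", call. = FALSE)
  y <- cal$slope * ec + cal$intercept
  if (any(y < 0)) {
    warning(sprintf(
      "%d EC value(s) below the calibration zero-crossing (%.2f uS/cm); TDS clipped to 0",
      sum(y < 0), -cal$intercept / cal$slope))
    y <- pmax(y, 0)
  }
  y
}

#' Per-treatment summary of one indicator at one stage
#'
#' @param table an `indicator_table` (long form, see
#'   [generate_indicators()]).
#' @param indicator indicator name.
#' @param stage growth-stage label; `NULL` averages over stages per sample
#'   first.
#' @return data.frame with `treatment`, `mean`, `sd` (sample sd, n-1
#'   denominator), `n`, ordered as in the table's treatment levels.
#' @export
treatment_summary <- function(table, indicator, stage = NULL) {
  stopifnot(is.data.frame(table))
  d <- table[table$indicator == indicator, , drop = FALSE]
  if (nrow(d) == 0L) stop("indicator absent: ", indicator)
  if (!is.null(stage)) {
    d <- d[d$stage == stage, , drop = FALSE]
    if (nrow(d) == 0L) stop("no records for stage: ", stage)
  } else {
    d <- stats::aggregate(value ~ sample_id + treatment, d, mean)
  }
  trt_levels <- unique(table$treatment)
  agg <- do.call(rbind, lapply(split(d$value, factor(d$treatment, trt_levels)),
                               function(v) {
                                 data.frame(mean = mean(v),
                                            sd = stats::sd(v),
                                            n = length(v))
                               }))
  out <- data.frame(treatment = rownames(agg), agg, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[!is.na(out$mean), , drop = FALSE]
}

#' Compact-letter display for treatment differences
#'
#' One-way ANOVA followed by Tukey's HSD; treatments that share a letter are
#' not significantly different at `alpha`. Letters are assigned in
#' descending-mean order starting at "a".
#'
#' @param table an `indicator_table`.
#' @param indicator indicator name.
#' @param stage stage label (or `NULL` to average over stages).
#' @param alpha significance level.
#' @return data.frame with `treatment`, `mean`, `letters`, sorted by
#'   descending mean.
#' @export
anova_letters <- function(table, indicator, stage = NULL, alpha = 0.05) {
  d <- table[table$indicator == indicator, , drop = FALSE]
  if (nrow(d) == 0L) stop("indicator absent: ", indicator)
  if (!is.null(stage)) d <- d[d$stage == stage, , drop = FALSE]
  d$treatment <- factor(d$treatment, unique(d$treatment))
  if (nlevels(d$treatment) < 2L) stop("need at least two treatments")
  if (any(table(d$treatment) < 2L)) stop("need >= 2 replicates per treatment")
  wss <- sum(tapply(d$value, d$treatment, function(v) sum((v - mean(v))^2)))
  if (wss < .Machine$double.eps * sum(d$value^2))
    stop("zero within-group variance in all groups: ANOVA is degenerate")
  fit <- stats::aov(value ~ treatment, data = d)
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(treatment = "Tukey"))
  cld <- multcomp::cld(glht_fit, level = alpha, decreasing = TRUE)
  means <- tapply(d$value, d$treatment, mean)
  out <- data.frame(treatment = names(means), mean = as.numeric(means),
                    letters = unname(cld$mcletters$Letters[names(means)]),
                    stringsAsFactors = FALSE)
  out[order(-out$mean), , drop = FALSE]
}
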