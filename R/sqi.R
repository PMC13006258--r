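#' Default scoring directions for the 12 soil indicators
#'
#' Total dissolved solids is the single "less is better" indicator; all
#' other indicators (moisture, carbon and nitrogen pools, the five enzyme
#' activities, and the two microbial richness proxies) score "more is
#' better".
#'
#' @return named character vector, values `"more_is_better"` or
#'   `"less_is_better"`.
#' @export
default_directions <- function() {
  d <- rep("more_is_better", length(sqi_indicators))
  names(d) <- sqi_indicators
  d["TDS"] <- "less_is_better"
  d
}

#' Min-max linear indicator score
#'
#' Maps a raw indicator value onto \[0, 1\] using the population extremes:
#' `(x - xmin) / (xmax - xmin)` for "more is better" indicators and
#' `(xmax - x) / (xmax - xmin)` for "less is better" ones. Values outside
#' the extremes are clipped with a warning; a zero-range indicator scores
#' 0.5 with a warning.
#'
#' @param x raw value(s).
#' @param x_min,x_max scoring extremes (x_max >= x_min).
#' @param direction `"more_is_better"` or `"less_is_better"`.
#' @return score(s) in \[0, 1\].
#' @export
minmax_score <- function(x, x_min, x_max,
                         direction = c("more_is_better", "less_is_better")) {
  direction <- match.arg(direction)
  if (any(!is.finite(x))) stop("non-finite input", call. = FALSE)
  if (x_max < x_min) stop("x_max must be >= x_min", call. = FALSE)
  if (x_max == x_min) {
    warning("zero indicator range; returning 0.5")
    return(rep(0.5, length(x)))
  }
  if (any(x < x_min) || any(x > x_max)) {
    warning("value(s) outside [x_min, x_max]; clipped")
    x <- pmin(pmax(x, x_min), x_max)
  }
  s <- (x - x_min) / (x_max - x_min)
  if (direction == "less_is_better") s <- 1 - s
  s
}

#' Score a wide indicator matrix
#'
#' Applies [minmax_score()] column-wise with extremes taken over the whole
#' scoring population (all samples entering the SQI).
#'
#' @param x numeric matrix or data.frame, samples x indicators.
#' @param directions named direction vector (see [default_directions()]).
#' @return list of class `score_table`: `scores` (matrix in \[0,1\]),
#'   `extremes` (per-indicator min/max used).
#' @export
score_table <- function(x, directions = default_directions()) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("indicator columns must be named")
  miss <- setdiff(colnames(x), names(directions))
  if (length(miss))
    stop("no scoring direction for: ", paste(miss, collapse = ", "))
  ext <- data.frame(indicator = colnames(x),
                    x_min = apply(x, 2, min), x_max = apply(x, 2, max),
                    row.names = NULL)
  scores <- vapply(seq_len(ncol(x)), function(j)
    minmax_score(x[, j], ext$x_min[j], ext$x_max[j],
                 directions[[colnames(x)[j]]]),
    numeric(nrow(x)))
  dimnames(scores) <- dimnames(x)
  structure(list(scores = scores, extremes = ext), class = "score_table")
}

#' PCA communalities of soil indicators
#'
#' Standardizes the indicator matrix to zero mean and unit variance,
#' eigendecomposes its correlation matrix, and returns per-indicator
#' communalities: the sum over retained components of squared loadings,
#' where loading_(i,k) = eigenvector_(i,k) * sqrt(eigenvalue_k). Retaining
#' all components gives communality 1 for every indicator.
#'
#' @param x numeric matrix/data.frame, samples x indicators (>= 3 samples).
#' @param retain `"kaiser"` (eigenvalue > 1, the default) or an integer
#'   number of components.
#' @return named numeric vector of communalities in \[0, 1\], with the
#'   number of retained components as attribute `"n_components"`.
#' @export
pca_communalities <- function(x, retain = "kaiser") {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need >= 3 samples")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant indicator column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  R <- stats::cor(x)
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  k <- if (identical(retain, "kaiser")) sum(vals > 1) else as.integer(retain)
  if (k < 1L) stop("retention rule keeps no components")
  if (k > ncol(x)) stop("cannot retain more components than indicators")
  if (k >= nrow(x))
    warning("retaining as many or more components than samples; ",
            "communalities may be unstable")
  load2 <- sweep(e$vectors[, seq_len(k), drop = FALSE]^2, 2,
                 vals[seq_len(k)], "*")
  comm <- rowSums(load2)
  names(comm) <- colnames(x)
  comm <- pmin(comm, 1)
  attr(comm, "n_components") <- k
  comm
}

#' Communality-ratio indicator weights
#'
#' Each indicator's weight is its communality divided by the sum of all
#' communalities, so weights are nonnegative and sum to one.
#'
#' @param communalities named nonnegative numeric vector, sum > 0.
#' @return named numeric weight vector summing to 1.
#' @examples
#' communality_weights(c(a = 0.9, b = 0.9, c = 0.9)) # all 1/3
#' @export
communality_weights <- function(communalities) {
  if (any(!is.finite(communalities)) || any(communalities < 0))
    stop("communalities must be finite and >= 0")
  s <- sum(communalities)
  if (s <= 0) stop("all-zero communalities")
  communalities / s
}

#' Soil quality index from scores and weights
#'
#' Per-sample weighted sum of linear indicator scores, `SQI = sum_i W_i S_i`,
#' on \[0, 1\] (higher is better), plus per-treatment mean and sample sd
#' when treatment labels are supplied.
#'
#' @param scores a `score_table` (or a samples x indicators score matrix).
#' @param weights named weight vector over the same indicators.
#' @param treatment optional treatment label per sample (same order as
#'   score rows).
#' @return list of class `sqi_result`: `sqi` (named per-sample values),
#'   `weights`, `by_treatment` (data.frame or NULL).
#' @export
compute_sqi <- function(scores, weights, treatment = NULL) {
  s <- if (inherits(scores, "score_table")) scores$scores else as.matrix(scores)
  if (!setequal(colnames(s), names(weights)))
    stop("scores and weights cover different indicator sets")
  w <- weights[colnames(s)]
  sqi <- as.numeric(s %*% w)
  names(sqi) <- rownames(s)
  by_trt <- NULL
  if (!is.null(treatment)) {
    trt <- factor(treatment, unique(treatment))
    by_trt <- data.frame(
      treatment = levels(trt),
      mean = as.numeric(tapply(sqi, trt, mean)),
      sd   = as.numeric(tapply(sqi, trt, stats::sd)),
      n    = as.integer(table(trt)),
      stringsAsFactors = FALSE
    )
  }
  structure(list(sqi = sqi, weights = w, by_treatment = by_trt),
            class = "sqi_result")
}

#' @export
print.sqi_result <- function(x, ...) {
  cat("Soil quality index (", length(x$sqi), " samples)\n", sep = "")
  if (!is.null(x$by_treatment)) print(x$by_treatment, ...)
  invisible(x)
}

#' Ordinary least squares fit of yield on SQI
#'
#' @param sqi per-sample soil quality index.
#' @param yield per-sample yield (kg/ha), same length and order.
#' @return list of class `yield_fit`: `slope`, `intercept`, `r_squared`,
#'   `p_value` (two-sided, slope), `n`, and the underlying `lm` fit.
#' @export
fit_yield_sqi <- function(sqi, yield) {
  if (length(sqi) != length(yield)) stop("length mismatch")
  if (length(sqi) < 3L) stop("need >= 3 paired observations")
  if (stats::sd(sqi) == 0) stop("zero variance in SQI")
  if (stats::sd(yield) == 0) {
    # a flat response carries no signal: slope 0, nothing explained
    return(structure(
      list(slope = 0, intercept = mean(yield), r_squared = 0,
           p_value = NA_real_, n = length(sqi), fit = NULL),
      class = "yield_fit"))
  }
  fit <- stats::lm(yield ~ sqi)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) >= 2L) sm$coefficients[2L, 4L] else NA_real_
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = sm$r.squared, p_value = p,
         n = length(sqi), fit = fit),
    class = "yield_fit"
  )
}

#' @export
print.yield_fit <- function(x, ...) {
  cat(sprintf("Y = %.1f x + %.1f   (R^2 = %.4f, p = %.3g, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Reference numbers from the motivating field trial
#'
#' Published summary numbers from the saline-soil amendment trial this
#' package emulates, usable as inputs for reanalysis: per-indicator PCA
#' communalities of the 12-indicator soil dataset, per-treatment yield and
#' SQI means (n = 3 pits), and the co-occurrence network topology table per
#' kingdom and treatment.
#'
#' @format A list with elements `communalities` (named numeric, 12
#'   indicators), `yield` and `sqi` (named means per treatment), and
#'   `topology` (data.frame: kingdom, treatment, nodes, links, avg_degree,
#'   avg_clustering, avg_path_length, modularity).
#' @export
field_reference <- list(
  communalities = c(
    SMC = 0.938, TDS = 0.912, TC = 0.927, TN = 0.977, TOC = 0.907,
    RUE = 0.952, SUC = 0.967, AKP = 0.752, CAT = 0.601, SCL = 0.914,
    Bacteria = 0.639, Fungi = 0.779
  ),
  yield = c(CK = 5089.53, BC = 5762.47, RBC = 6492.69),
  sqi   = c(CK = 0.23, BC = 0.48, RBC = 0.87),
  topology = data.frame(
    kingdom   = rep(c("bacteria", "fungi"), each = 3),
    treatment = rep(c("CK", "BC", "RBC"), 2),
    nodes     = c(167, 155, 170, 60, 61, 64),
    links     = c(1711, 561, 1692, 294, 295, 332),
    avg_degree = c(20.491, 7.239, 19.906, 9.046, 9.672, 10.375),
    avg_clustering = c(0.554, 0.546, 0.521, 0.568, 0.611, 0.562),
    avg_path_length = c(2.759, 4.846, 2.809, 2.955, 3.308, 3.087),
    modularity = c(0.483, 0.692, 0.404, 0.473, 0.405, 0.484),
    stringsAsFactors = FALSE
  )
)
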