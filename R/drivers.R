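#' Spearman screen of taxa against environmental factors
#'
#' Spearman rank correlation with a two-sided p-value for every (taxon
#' group, environmental factor) pair, flagged at p < 0.05 (`"*"`) and
#' p < 0.01 (`"**"`). Constant columns are excluded with a warning. No
#' multiple-testing correction is applied by default; `adjust = "BH"`
#' applies Benjamini-Hochberg across the whole screen.
#'
#' @param abundances groups x samples relative-abundance matrix (e.g. from
#'   [aggregate_rank()]).
#' @param env samples x factors numeric data.frame/matrix, same sample
#'   order.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with `taxon`, `factor`, `rho`, `p_value`, `flag`.
#' @export
taxon_env_correlation <- function(abundances, env, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  abundances <- as.matrix(abundances)
  env <- as.data.frame(env)
  if (ncol(abundances) != nrow(env))
    stop("sample mismatch between abundances and environment table")
  if (ncol(abundances) < 4L) stop("need >= 4 samples")
  const_env <- vapply(env, function(v) stats::var(v) == 0, logical(1))
  if (any(const_env)) {
    warning("constant environmental column(s) excluded: ",
            paste(names(env)[const_env], collapse = ", "))
    env <- env[, !const_env, drop = FALSE]
  }
  const_tax <- apply(abundances, 1, function(v) stats::var(v) == 0)
  if (any(const_tax)) {
    warning("constant taxon row(s) excluded: ",
            paste(rownames(abundances)[const_tax], collapse = ", "))
    abundances <- abundances[!const_tax, , drop = FALSE]
  }
  rows <- expand.grid(taxon = rownames(abundances), factor = names(env),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- t(mapply(function(tx, fc) {
    ct <- suppressWarnings(stats::cor.test(abundances[tx, ], env[[fc]],
                                           method = "spearman",
                                           exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  }, rows$taxon, rows$factor))
  rows$rho <- res[, 1L]
  rows$p_value <- if (adjust == "BH") stats::p.adjust(res[, 2L], "BH") else
    res[, 2L]
  rows$flag <- ifelse(rows$p_value < 0.01, "**",
                      ifelse(rows$p_value < 0.05, "*", "ns"))
  rows
}

#' Community principal-component scores
#'
#' PCA of transformed relative abundances (Hellinger transform by default,
#' which square-roots relative abundances to blunt compositional
#' artifacts). Scores are centred; the sign of each axis is fixed by
#' forcing the loading of the most abundant group to be nonnegative, so
#' results are deterministic across platforms.
#'
#' @param abundances groups x samples relative-abundance matrix, or an
#'   `abundance_matrix` (aggregated internally at phylum rank).
#' @param transform `"hellinger"` (default) or `"identity"`.
#' @param k number of axes (default 2).
#' @return list of class `pc_scores`: `scores` (samples x k), `proportion`
#'   (variance fraction per axis), `loadings`.
#' @export
community_pc_scores <- function(abundances,
                                transform = c("hellinger", "identity"),
                                k = 2) {
  transform <- match.arg(transform)
  if (inherits(abundances, "abundance_matrix"))
    abundances <- aggregate_rank(abundances, "phylum", top_n = Inf)
  x <- t(as.matrix(abundances))     # samples x groups
  if (nrow(x) < 3L) stop("need >= 3 samples")
  if (transform == "hellinger") x <- sqrt(x)
  sds <- apply(x, 2, stats::sd)
  pc <- stats::prcomp(x[, sds > 0, drop = FALSE], center = TRUE,
                      scale. = FALSE)
  if (ncol(pc$rotation) < 2L) stop("fewer than 2 non-degenerate dimensions")
  k <- min(k, ncol(pc$rotation))
  dominant <- names(which.max(colMeans(x)))
  for (j in seq_len(k)) {
    if (pc$rotation[dominant, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  vars <- pc$sdev^2
  structure(
    list(scores = pc$x[, seq_len(k), drop = FALSE],
         proportion = vars[seq_len(k)] / sum(vars),
         loadings = pc$rotation[, seq_len(k), drop = FALSE]),
    class = "pc_scores"
  )
}

#' Random-forest variance explained per environmental factor
#'
#' Fits a seeded random-forest regression per single factor against the
#' response (a community PC score) and reports the out-of-bag R-squared of
#' that single-factor model, floored at 0 and scaled to 0-100. Values need
#' not sum to 100. `method = "joint"` instead fits one forest on all
#' factors and reports permutation importance (%IncMSE), rescaled to the
#' 0-100 range of the largest.
#'
#' @param env samples x factors data.frame.
#' @param response numeric response per sample (e.g. PC1 scores).
#' @param method `"single"` (default) or `"joint"`.
#' @param n_tree trees per forest.
#' @param seed integer seed; results are exactly reproducible under a
#'   fixed seed.
#' @return data.frame with `factor` and `variance_explained` (percent).
#' @export
rf_variance_explained <- function(env, response,
                                  method = c("single", "joint"),
                                  n_tree = 500, seed = 1L) {
  method <- match.arg(method)
  env <- as.data.frame(env)
  if (nrow(env) != length(response)) stop("sample mismatch")
  if (nrow(env) < 6L) stop("need >= 6 samples")
  if (ncol(env) < 2L) stop("need >= 2 factors")
  if (stats::var(response) == 0) stop("constant response")
  if (method == "single") {
    ve <- vapply(names(env), function(fc) {
      with_seed(seed, {
        rf <- randomForest::randomForest(x = env[, fc, drop = FALSE],
                                         y = response, ntree = n_tree)
        max(0, utils::tail(rf$rsq, 1L)) * 100
      })
    }, numeric(1))
  } else {
    ve <- with_seed(seed, {
      rf <- randomForest::randomForest(x = env, y = response,
                                       ntree = n_tree, importance = TRUE)
      imp <- pmax(randomForest::importance(rf, type = 1L)[, 1L], 0)
      if (max(imp) > 0) imp / max(imp) * 100 else imp
    })
  }
  data.frame(factor = names(env), variance_explained = unname(ve),
             stringsAsFactors = FALSE)
}
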