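#' Aggregate counts to a taxonomic rank with a pooled "Others" group
#'
#' Sums counts per phylum or genus, converts to per-sample relative
#' abundances, ranks groups by overall mean abundance and pools everything
#' beyond the `top_n` most abundant into `"Others"`.
#'
#' @param matrix an `abundance_matrix`.
#' @param rank `"phylum"` or `"genus"`.
#' @param top_n groups to keep before pooling (default 10).
#' @return groups x samples matrix of relative abundances; rows ordered by
#'   decreasing overall mean, `"Others"` last. Columns sum to 1.
#' @export
aggregate_rank <- function(matrix, rank = c("phylum", "genus"), top_n = 10) {
  rank <- match.arg(rank)
  stopifnot(inherits(matrix, "abundance_matrix"))
  totals <- colSums(matrix$counts)
  if (any(totals == 0))
    stop("empty sample(s): ",
         paste(colnames(matrix$counts)[totals == 0], collapse = ", "))
  groups <- matrix$taxonomy[[rank]][match(rownames(matrix$counts),
                                          matrix$taxonomy$taxon_id)]
  if (anyNA(groups)) stop("taxonomy does not cover every taxon at rank ", rank)
  agg <- rowsum(matrix$counts, groups)
  rel <- sweep(agg, 2, totals, "/")
  ord <- order(rowMeans(rel), decreasing = TRUE)
  rel <- rel[ord, , drop = FALSE]
  # the generator's own minor-taxon pool folds into the pooled group too
  keep_n <- min(top_n, nrow(rel))
  keep <- setdiff(rownames(rel)[seq_len(keep_n)], "Others")
  others <- colSums(rel[!rownames(rel) %in% keep, , drop = FALSE])
  out <- rbind(rel[keep, , drop = FALSE], Others = others)
  out
}

#' Observed species richness
#'
#' @param counts nonnegative integer count vector (one sample).
#' @return number of taxa with count > 0.
#' @export
observed_species <- function(counts) {
  if (any(counts < 0)) stop("counts must be >= 0")
  sum(counts > 0)
}

#' Chao1 richness estimator
#'
#' Extrapolates unseen richness from singletons (F1) and doubletons (F2).
#' The bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` is the
#' default and is defined for F2 = 0; the classic form
#' `S_obs + F1^2 / (2 F2)` is available when F2 > 0.
#'
#' @param counts nonnegative integer count vector, some count > 0.
#' @param bias_corrected use the bias-corrected form (default TRUE).
#' @return the richness estimate (>= observed species).
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (any(counts < 0)) stop("counts must be >= 0")
  if (all(counts == 0)) stop("empty sample")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    if (f2 == 0) stop("classic Chao1 undefined when no doubletons; use bias_corrected = TRUE")
    s_obs + f1^2 / (2 * f2)
  }
}

#' ACE richness estimator
#'
#' Abundance-based coverage estimator. Taxa with counts at or below
#' `rare_threshold` form the rare group; with `N_rare` the rare individuals,
#' `F1` the singletons and `C_ace = 1 - F1 / N_rare` the sample coverage,
#' `ACE = S_abund + S_rare / C_ace + (F1 / C_ace) * gamma^2`, where
#' `gamma^2` is the rare-taxa squared coefficient of variation estimate,
#' floored at 0. When every rare taxon is a singleton the coverage is zero
#' and the estimator falls back to Chao1 with a warning.
#'
#' @param counts nonnegative integer count vector, some count > 0.
#' @param rare_threshold rare/abundant cut-off (default 10).
#' @return the richness estimate.
#' @export
ace <- function(counts, rare_threshold = 10) {
  if (any(counts < 0)) stop("counts must be >= 0")
  if (all(counts == 0)) stop("empty sample")
  counts <- counts[counts > 0]
  rare <- counts[counts <= rare_threshold]
  s_abund <- sum(counts > rare_threshold)
  s_rare <- length(rare)
  if (s_rare == 0L) return(s_abund)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warning("all rare taxa are singletons (zero coverage); falling back to Chao1")
    return(chao1(counts))
  }
  f_i <- tabulate(rare, nbins = rare_threshold)
  gamma2 <- max(
    s_rare / c_ace * sum(seq_len(rare_threshold) *
                           (seq_len(rare_threshold) - 1) * f_i) /
      (n_rare * (n_rare - 1)) - 1,
    0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Per-sample alpha diversity table
#'
#' @param matrix an `abundance_matrix`.
#' @param rare_threshold passed to [ace()].
#' @return data.frame with `sample_id`, `treatment`, `replicate`,
#'   `observed`, `ace`, `chao1`.
#' @export
alpha_diversity <- function(matrix, rare_threshold = 10) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  cnt <- matrix$counts
  out <- matrix$metadata
  out$observed <- apply(cnt, 2, observed_species)
  out$ace <- apply(cnt, 2, ace, rare_threshold = rare_threshold)
  out$chao1 <- apply(cnt, 2, chao1)
  out
}

#' Beta-diversity ordination (principal coordinates)
#'
#' Classical PCoA: samples are converted to relative abundances, a
#' dissimilarity matrix is computed (Bray-Curtis by default, via
#' \pkg{vegan}), and the double-centred squared-distance matrix is
#' eigendecomposed. Negative eigenvalues are reported; axis variance
#' proportions are computed over the positive eigenvalues.
#'
#' @param matrix an `abundance_matrix`, or a samples x features numeric
#'   matrix.
#' @param distance `"bray"`, `"jaccard"` or `"euclidean"`.
#' @param k number of axes to return (default 2).
#' @return list of class `ordination_result`: `coordinates` (samples x
#'   axes, centred), `eigenvalues` (all, decreasing), `proportion` (per
#'   returned axis, over positive eigenvalues), `distances` (the `dist`
#'   object that was embedded).
#' @export
beta_ordination <- function(matrix, distance = c("bray", "jaccard",
                                                 "euclidean"), k = 2) {
  distance <- match.arg(distance)
  x <- if (inherits(matrix, "abundance_matrix")) {
    totals <- colSums(matrix$counts)
    if (any(totals == 0)) stop("empty sample(s) in abundance matrix")
    t(sweep(matrix$counts, 2, totals, "/"))
  } else as.matrix(matrix)
  if (nrow(x) < 3L) stop("need >= 3 samples")
  d <- vegan::vegdist(x, method = distance)
  if (all(d == 0))
    stop("all samples identical: zero distance matrix, ordination undefined")
  pco <- stats::cmdscale(d, k = min(k, nrow(x) - 1L), eig = TRUE)
  eig <- pco$eig
  pos <- sum(eig[eig > 0])
  coords <- pco$points
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(
    list(coordinates = coords,
         eigenvalues = eig,
         proportion = pmax(eig[seq_len(ncol(coords))], 0) / pos,
         distances = d),
    class = "ordination_result"
  )
}

#' Compare alpha diversity between treatments
#'
#' Percent change of each index's treatment mean against the reference
#' treatment, with a two-sided pairwise test per comparison (Welch t by
#' default) flagged `"*"` below `alpha` and `"ns"` otherwise.
#'
#' @param alpha_table output of [alpha_diversity()].
#' @param reference reference treatment label (default `"CK"`).
#' @param indices which index columns to compare.
#' @param test `"welch"` or `"wilcoxon"`.
#' @param alpha significance level for the flag.
#' @return data.frame with `index`, `treatment`, `reference_mean`,
#'   `treatment_mean`, `percent_change`, `p_value`, `flag`.
#' @export
alpha_compare <- function(alpha_table, reference = "CK",
                          indices = c("observed", "ace", "chao1"),
                          test = c("welch", "wilcoxon"), alpha = 0.05) {
  test <- match.arg(test)
  if (!reference %in% alpha_table$treatment)
    stop("missing reference treatment: ", reference)
  others <- setdiff(unique(alpha_table$treatment), reference)
  rows <- list()
  for (idx in indices) {
    ref_v <- alpha_table[[idx]][alpha_table$treatment == reference]
    for (tr in others) {
      trt_v <- alpha_table[[idx]][alpha_table$treatment == tr]
      if (length(ref_v) < 2L || length(trt_v) < 2L)
        stop("need >= 2 replicates per treatment")
      p <- if (test == "welch") {
        stats::t.test(trt_v, ref_v)$p.value
      } else {
        suppressWarnings(stats::wilcox.test(trt_v, ref_v)$p.value)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        index = idx, treatment = tr,
        reference_mean = mean(ref_v), treatment_mean = mean(trt_v),
        percent_change = percent_change(mean(ref_v), mean(trt_v)),
        p_value = p, flag = if (p < alpha) "*" else "ns",
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
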