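#' Edge rule for co-occurrence inference
#'
#' @param method correlation method (default `"spearman"`).
#' @param r_threshold keep edges with `|r|` strictly above this (default
#'   0.7).
#' @param p_threshold keep edges with p strictly below this (default 0.05).
#' @param adjust multiple-testing adjustment: `"none"` (default, raw
#'   cut-offs) or `"BH"`.
#' @return object of class `edge_rule`.
#' @export
edge_rule <- function(method = c("spearman", "pearson"),
                      r_threshold = 0.7, p_threshold = 0.05,
                      adjust = c("none", "BH")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  if (r_threshold <= 0 || r_threshold > 1) stop("r_threshold must be in (0, 1]")
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0, 1)")
  structure(list(method = method, r_threshold = r_threshold,
                 p_threshold = p_threshold, adjust = adjust),
            class = "edge_rule")
}

#' Pairwise correlation edges between taxa
#'
#' Computes all pairwise correlations between taxon abundance vectors
#' (after a prevalence filter) and keeps edges satisfying the rule:
#' `|r| > r_threshold` and `p < p_threshold`. Constant vectors have
#' undefined correlation and are excluded with a warning.
#'
#' @param matrix an `abundance_matrix`, or a taxa x samples numeric matrix.
#' @param rule an [edge_rule()].
#' @param min_prevalence minimum fraction of samples in which a taxon must
#'   be present (count > 0) to enter the network (default 1/3).
#' @return data.frame of class `edge_set` with columns `taxon_a`,
#'   `taxon_b`, `r`, `p`, `sign`; attribute `"nodes"` holds the filtered
#'   taxon universe (including taxa that end up with no edge).
#' @export
correlation_edges <- function(matrix, rule = edge_rule(),
                              min_prevalence = 1 / 3) {
  x <- if (inherits(matrix, "abundance_matrix")) matrix$counts else
    as.matrix(matrix)
  if (ncol(x) < 4L) stop("need >= 4 samples")
  if (is.null(rownames(x))) rownames(x) <- paste0("t", seq_len(nrow(x)))
  prev <- rowMeans(x > 0)
  x <- x[prev >= min_prevalence, , drop = FALSE]
  const <- apply(x, 1, function(v) stats::var(v) == 0)
  if (any(const)) {
    warning(sum(const), " constant taxon vector(s) excluded (undefined correlation)")
    x <- x[!const, , drop = FALSE]
  }
  taxa <- rownames(x)
  n <- length(taxa)
  res <- list()
  if (n >= 2L) {
    idx <- utils::combn(n, 2L)
    r <- numeric(ncol(idx)); p <- numeric(ncol(idx))
    for (k in seq_len(ncol(idx))) {
      ct <- suppressWarnings(stats::cor.test(
        x[idx[1L, k], ], x[idx[2L, k], ],
        method = rule$method, exact = FALSE))
      r[k] <- unname(ct$estimate); p[k] <- ct$p.value
    }
    if (rule$adjust == "BH") p <- stats::p.adjust(p, "BH")
    keep <- abs(r) > rule$r_threshold & p < rule$p_threshold
    res <- data.frame(
      taxon_a = taxa[idx[1L, keep]], taxon_b = taxa[idx[2L, keep]],
      r = r[keep], p = p[keep],
      sign = ifelse(r[keep] >= 0, "positive", "negative"),
      stringsAsFactors = FALSE
    )
  } else {
    res <- data.frame(taxon_a = character(), taxon_b = character(),
                      r = numeric(), p = numeric(), sign = character(),
                      stringsAsFactors = FALSE)
  }
  attr(res, "nodes") <- taxa
  attr(res, "rule") <- rule
  class(res) <- c("edge_set", "data.frame")
  res
}

#' Build a co-occurrence graph from an edge set
#'
#' Undirected signed graph; by default taxa left without any retained edge
#' are dropped, matching the convention that node counts vary with the
#' treatment.
#'
#' @param edges an `edge_set` from [correlation_edges()].
#' @param taxonomy optional data.frame (`taxon_id`, `phylum`, `genus`) used
#'   to annotate nodes.
#' @param keep_isolates keep edge-less taxa as isolated nodes (default
#'   FALSE).
#' @param treatment optional label stored on the graph.
#' @return an \pkg{igraph} graph with edge attributes `r`, `p`, `sign` and
#'   node attributes `phylum`, `genus` when taxonomy is given.
#' @export
cooccurrence_graph <- function(edges, taxonomy = NULL,
                               keep_isolates = FALSE, treatment = NULL) {
  stopifnot(inherits(edges, "edge_set") || is.data.frame(edges))
  universe <- attr(edges, "nodes")
  nodes <- if (keep_isolates && !is.null(universe)) universe else
    unique(c(edges$taxon_a, edges$taxon_b))
  g <- igraph::graph_from_data_frame(
    edges[, c("taxon_a", "taxon_b", "r", "p", "sign")],
    directed = FALSE, vertices = data.frame(name = nodes))
  if (!is.null(taxonomy)) {
    m <- match(igraph::V(g)$name, taxonomy$taxon_id)
    igraph::V(g)$phylum <- taxonomy$phylum[m]
    igraph::V(g)$genus <- taxonomy$genus[m]
  }
  if (!is.null(treatment)) g <- igraph::set_graph_attr(g, "treatment", treatment)
  g
}

#' Topology report for a co-occurrence graph
#'
#' Total nodes and links, average degree (2L/N), average local clustering
#' coefficient (nodes of degree < 2 contribute 0), average shortest-path
#' length over connected pairs inside the largest connected component, and
#' the modularity of a greedy modularity-maximising partition of the
#' unsigned graph (deterministic agglomeration, so reports are
#' reproducible).
#'
#' @param graph an \pkg{igraph} graph (e.g. from [cooccurrence_graph()]).
#' @return data.frame (one row) with `nodes`, `links`, `avg_degree`,
#'   `avg_clustering`, `avg_path_length`, `modularity`.
#' @export
topology <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 1L) stop("empty graph")
  l <- igraph::ecount(graph)
  local_cc <- igraph::transitivity(graph, type = "local", isolates = "zero")
  comp <- igraph::components(graph)
  giant <- igraph::induced_subgraph(
    graph, which(comp$membership == which.max(comp$csize)))
  apl <- if (igraph::vcount(giant) > 1L)
    igraph::mean_distance(giant, directed = FALSE) else NA_real_
  mod <- if (l > 0L) {
    gu <- igraph::simplify(graph)
    igraph::modularity(igraph::cluster_fast_greedy(gu))
  } else 0
  data.frame(
    nodes = n, links = l,
    avg_degree = 2 * l / n,
    avg_clustering = mean(local_cc),
    avg_path_length = apl,
    modularity = mod
  )
}

#' Percent change between two topology reports
#'
#' @param report_a reference report (one-row data.frame from [topology()],
#'   or any named numeric row such as a published topology table row).
#' @param report_b comparison report.
#' @return named numeric vector of percent changes per shared numeric
#'   metric (reference = `report_a`).
#' @export
compare_networks <- function(report_a, report_b) {
  a <- unlist(report_a[sapply(report_a, is.numeric)])
  b <- unlist(report_b[sapply(report_b, is.numeric)])
  shared <- intersect(names(a), names(b))
  if (!length(shared)) stop("reports share no numeric metrics")
  if (any(a[shared] == 0)) stop("zero reference metric")
  percent_change(a[shared], b[shared])
}

#' Per-treatment co-occurrence analysis
#'
#' Splits the samples by treatment, infers one network per treatment with
#' the same edge rule, and reports edge sets, graphs, and topology.
#'
#' @param matrix an `abundance_matrix`.
#' @param rule an [edge_rule()].
#' @param min_prevalence prevalence filter per treatment subnetwork.
#' @return list of class `network_set`: `graphs` (named list), `topology`
#'   (data.frame, one row per treatment), `edges` (named list).
#' @export
networks_by_treatment <- function(matrix, rule = edge_rule(),
                                  min_prevalence = 1 / 3) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  treatments <- unique(matrix$metadata$treatment)
  graphs <- list(); edges <- list(); reports <- list()
  for (tr in treatments) {
    cols <- matrix$metadata$sample_id[matrix$metadata$treatment == tr]
    sub <- matrix$counts[, cols, drop = FALSE]
    es <- correlation_edges(sub, rule, min_prevalence)
    g <- cooccurrence_graph(es, matrix$taxonomy, treatment = tr)
    graphs[[tr]] <- g; edges[[tr]] <- es
    rep_row <- if (igraph::vcount(g) > 0) topology(g) else
      data.frame(nodes = 0L, links = 0L, avg_degree = NA_real_,
                 avg_clustering = NA_real_, avg_path_length = NA_real_,
                 modularity = NA_real_)
    reports[[tr]] <- cbind(treatment = tr, rep_row)
  }
  structure(list(graphs = graphs,
                 topology = do.call(rbind, reports),
                 edges = edges, kingdom = matrix$kingdom),
            class = "network_set")
}
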