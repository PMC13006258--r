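# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and igraph/vegan) so that agreement is
# meaningful.

# Bray-Curtis dissimilarity, elementwise formula sum|x-y| / sum(x+y)
bc_brute <- function(x, y) sum(abs(x - y)) / sum(x + y)

# adjacency matrix from an igraph-free edge list over node names
adj_from_edges <- function(nodes, a, b) {
  A <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (k in seq_along(a)) {
    A[a[k], b[k]] <- 1L
    A[b[k], a[k]] <- 1L
  }
  A
}

# local clustering coefficient per node; degree < 2 contributes 0
clustering_brute <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    links / choose(length(nb), 2)
  }, numeric(1))
}

# all-pairs shortest paths by BFS (unweighted); Inf if disconnected
shortest_paths_brute <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ] > 0))))
      nxt <- nxt[D[s, nxt] == Inf]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# mean shortest-path length over connected pairs within the largest
# connected component
apl_brute <- function(A) {
  D <- shortest_paths_brute(A)
  comp <- ifelse(is.infinite(D), 0L, 1L)
  # connected components from reachability
  memb <- rep(NA_integer_, nrow(A))
  cid <- 0L
  for (i in seq_len(nrow(A))) {
    if (is.na(memb[i])) {
      cid <- cid + 1L
      memb[which(comp[i, ] == 1L)] <- cid
    }
  }
  big <- which(memb == which.max(tabulate(memb)))
  if (length(big) < 2) return(NA_real_)
  d <- D[big, big]
  mean(d[upper.tri(d)])
}

# Newman modularity of a partition (membership vector) of an unweighted graph
modularity_brute <- function(A, membership) {
  m <- sum(A) / 2
  if (m == 0) return(0)
  deg <- rowSums(A)
  q <- 0
  for (c in unique(membership)) {
    idx <- which(membership == c)
    e_c <- sum(A[idx, idx]) / 2
    d_c <- sum(deg[idx])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(code, mx) {
    k <- length(code) + 1L
    if (k > n) {
      out[[length(out) + 1L]] <<- code
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) rec(c(code, v), max(mx, v))
  }
  rec(integer(), 0L)
  out
}

max_modularity_brute <- function(A) {
  parts <- all_partitions(nrow(A))
  max(vapply(parts, function(p) modularity_brute(A, p), numeric(1)))
}

# textbook ACE, written independently of the package's implementation
ace_brute <- function(counts, thr = 10) {
  counts <- counts[counts > 0]
  rare <- counts[counts <= thr]
  abund <- counts[counts > thr]
  if (!length(rare)) return(length(abund))
  Nrare <- sum(rare)
  F1 <- sum(rare == 1)
  Cace <- 1 - F1 / Nrare
  if (Cace == 0) {
    f2 <- sum(counts == 2)
    return(length(counts) + F1 * (F1 - 1) / (2 * (f2 + 1)))
  }
  Srare <- length(rare)
  num <- 0
  for (i in 1:thr) num <- num + i * (i - 1) * sum(rare == i)
  g2 <- max(Srare / Cace * num / (Nrare * (Nrare - 1)) - 1, 0)
  length(abund) + Srare / Cace + F1 / Cace * g2
}

# Spearman rho by rank-then-Pearson
spearman_brute <- function(x, y) stats::cor(rank(x), rank(y))

# simulate observations from a five-latent recursive path model with known
# standardized path signs; each latent measured by `p` manifests with strong
# loadings. Returns list(data, blocks, paths, true_signs).
simulate_path_model <- function(n = 200, p = 2, seed = 1) {
  set.seed(seed)
  # treatment -> soil -> enzyme -> microbe -> yield with extra direct paths
  b <- list(
    c("treatment", "soil",    0.7),
    c("treatment", "enzyme",  0.4),
    c("soil",      "enzyme",  0.5),
    c("soil",      "microbe", -0.6),
    c("enzyme",    "microbe", 0.5),
    c("soil",      "yield",   0.5),
    c("microbe",   "yield",   -0.4)
  )
  lv <- c("treatment", "soil", "enzyme", "microbe", "yield")
  L <- matrix(0, 5, 5, dimnames = list(lv, lv))
  for (e in b) L[e[2], e[1]] <- as.numeric(e[3])
  eta <- matrix(0, n, 5, dimnames = list(NULL, lv))
  eta[, "treatment"] <- rnorm(n)
  for (v in lv[-1]) {
    mu <- eta %*% L[v, ]
    res_sd <- sqrt(max(1 - stats::var(as.numeric(mu)), 0.2))
    eta[, v] <- as.numeric(mu) + rnorm(n, sd = res_sd)
  }
  dat <- list()
  blocks <- list()
  for (v in lv) {
    cols <- paste0(v, "_m", seq_len(p))
    for (j in seq_len(p))
      dat[[cols[j]]] <- 0.9 * eta[, v] + rnorm(n, sd = sqrt(1 - 0.81))
    blocks[[v]] <- cols
  }
  list(
    data = as.data.frame(dat),
    blocks = do.call(salimend::plspm_blocks, blocks),
    paths = salimend::plspm_paths(
      do.call(salimend::plspm_blocks, blocks),
      lapply(b, function(e) e[1:2])),
    true_signs = lapply(b, function(e)
      list(from = e[1], to = e[2], sign = sign(as.numeric(e[3]))))
  )
}

# minimal hand-built abundance_matrix for diversity/network tests
make_abundance <- function(counts, phylum = NULL, genus = NULL,
                           treatment = NULL, kingdom = "bacteria") {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("t%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%d", seq_len(ncol(counts)))
  if (is.null(phylum)) phylum <- paste0("P", seq_len(nrow(counts)))
  if (is.null(genus)) genus <- paste0("G", seq_len(nrow(counts)))
  if (is.null(treatment)) treatment <- rep("CK", ncol(counts))
  structure(
    list(counts = counts,
         taxonomy = data.frame(taxon_id = rownames(counts),
                               phylum = phylum, genus = genus,
                               stringsAsFactors = FALSE),
         metadata = data.frame(sample_id = colnames(counts),
                               treatment = treatment,
                               replicate = seq_len(ncol(counts)),
                               stringsAsFactors = FALSE),
         kingdom = kingdom),
    class = "abundance_matrix")
}
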