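test_that("perfect monotone relations produce signed edges", {
  x <- c(1, 3, 5, 7, 9, 11)
  cnt <- rbind(a = x, b = x * 2 + 1, c = rev(x))
  es <- correlation_edges(cnt, edge_rule(), min_prevalence = 0)
  key <- paste(es$taxon_a, es$taxon_b)
  expect_true("a b" %in% key)
  expect_equal(es$r[key == "a b"], 1)
  expect_equal(es$sign[key == "a b"], "positive")
  expect_true("a c" %in% key)
  expect_equal(es$r[key == "a c"], -1)
  expect_equal(es$sign[key == "a c"], "negative")
})

test_that("edge inference matches a brute-force double loop", {
  set.seed(21)
  cnt <- matrix(rpois(20 * 9, 12), 20, 9,
                dimnames = list(paste0("t", 1:20), paste0("s", 1:9)))
  rule <- edge_rule(r_threshold = 0.6, p_threshold = 0.1)
  es <- correlation_edges(cnt, rule, min_prevalence = 0)
  got <- sort(paste(es$taxon_a, es$taxon_b))
  want <- character()
  for (i in 1:19) for (j in (i + 1):20) {
    ct <- suppressWarnings(cor.test(cnt[i, ], cnt[j, ], method = "spearman",
                                    exact = FALSE))
    if (abs(ct$estimate) > 0.6 && ct$p.value < 0.1)
      want <- c(want, paste0("t", i, " t", j))
  }
  expect_identical(got, sort(want))
})

test_that("constant taxa are excluded and loose rules complete the graph", {
  cnt <- rbind(a = c(5, 5, 5, 5, 5), b = c(1, 2, 3, 4, 5),
               c = c(2, 1, 4, 3, 5), d = c(9, 7, 5, 3, 1))
  expect_warning(es <- correlation_edges(cnt, edge_rule(), 0), "constant")
  expect_false("a" %in% c(es$taxon_a, es$taxon_b))
  # r -> 0, p -> 1 keeps every non-constant pair
  loose <- edge_rule(r_threshold = 1e-9, p_threshold = 0.999999)
  expect_warning(es2 <- correlation_edges(cnt, loose, 0), "constant")
  expect_equal(nrow(es2), choose(3, 2))
})

test_that("edge sets are invariant to sample and taxon ordering", {
  set.seed(31)
  cnt <- matrix(rpois(12 * 8, 10), 12, 8,
                dimnames = list(paste0("t", 1:12), paste0("s", 1:8)))
  rule <- edge_rule(r_threshold = 0.5, p_threshold = 0.2)
  canon <- function(es) {
    k <- t(apply(es[, c("taxon_a", "taxon_b")], 1, sort))
    o <- order(k[, 1], k[, 2])
    data.frame(a = k[o, 1], b = k[o, 2], r = round(es$r[o], 12))
  }
  es1 <- correlation_edges(cnt, rule, 0)
  es2 <- correlation_edges(cnt[sample(12), sample(8)], rule, 0)
  expect_equal(canon(es1), canon(es2))
})

test_that("triangle and path topologies match hand enumeration", {
  tri <- igraph::make_graph(~ A - B, B - C, A - C)
  tt <- topology(tri)
  expect_equal(tt$nodes, 3); expect_equal(tt$links, 3)
  expect_equal(tt$avg_degree, 2)
  expect_equal(tt$avg_clustering, 1)
  expect_equal(tt$avg_path_length, 1)
  p3 <- igraph::make_graph(~ A - B, B - C)
  tp <- topology(p3)
  expect_equal(tp$avg_clustering, 0)
  expect_equal(tp$avg_path_length, 4 / 3)
  expect_equal(tp$avg_degree, 2 * 2 / 3)
  expect_error(topology(igraph::make_empty_graph(0)), "empty")
})

test_that("greedy modularity on two disjoint triangles is the exhaustive optimum", {
  g <- igraph::make_graph(~ A - B, B - C, A - C, D - E, E - F, D - F)
  tt <- topology(g)
  A <- adj_from_edges(LETTERS[1:6],
                      c("A", "B", "A", "D", "E", "D"),
                      c("B", "C", "C", "E", "F", "F"))
  expect_equal(tt$modularity, max_modularity_brute(A), tolerance = 1e-12)
  # two cliques beat the single-community partition
  expect_gt(tt$modularity, modularity_brute(A, rep(1, 6)))
})

test_that("average degree identity holds on constructed graphs", {
  set.seed(41)
  for (i in 1:5) {
    cnt <- matrix(rpois(15 * 7, 8), 15, 7)
    es <- correlation_edges(cnt, edge_rule(r_threshold = 0.5,
                                           p_threshold = 0.3), 0)
    if (nrow(es) == 0) next
    g <- cooccurrence_graph(es)
    tt <- topology(g)
    expect_equal(tt$avg_degree, 2 * tt$links / tt$nodes)
    # isolated nodes dropped by default: every node has an edge
    expect_true(all(igraph::degree(g) >= 1))
    gk <- cooccurrence_graph(es, keep_isolates = TRUE)
    expect_equal(igraph::vcount(gk), length(attr(es, "nodes")))
  }
})

test_that("network report deltas are plain percent changes", {
  a <- data.frame(nodes = 10, links = 20, avg_degree = 4)
  expect_equal(unname(compare_networks(a, a)), c(0, 0, 0))
  b <- data.frame(nodes = 12, links = 10, avg_degree = 2)
  d <- compare_networks(a, b)
  expect_equal(unname(d["links"]), -50)
  expect_equal(unname(d["nodes"]), 20)
  expect_error(compare_networks(data.frame(links = 0), data.frame(links = 3)),
               "zero reference")
})

test_that("per-treatment networks annotate taxonomy and treatment", {
  set.seed(51)
  cnt <- matrix(rpois(10 * 12, 15), 10, 12,
                dimnames = list(paste0("t", 1:10),
                                paste0("s", 1:12)))
  ab <- make_abundance(cnt, phylum = rep(c("P1", "P2"), 5),
                       treatment = rep(c("CK", "BC"), each = 6))
  ns <- networks_by_treatment(ab, edge_rule(r_threshold = 0.3,
                                            p_threshold = 0.9))
  expect_setequal(names(ns$graphs), c("CK", "BC"))
  expect_equal(nrow(ns$topology), 2)
  g <- ns$graphs$CK
  if (igraph::vcount(g) > 0)
    expect_true(all(igraph::V(g)$phylum %in% c("P1", "P2")))
})
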