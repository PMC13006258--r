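test_that("rank aggregation closes to 1 and pools the tail into Others", {
  # single taxon: everything is that group
  ab1 <- make_abundance(matrix(c(5L, 9L, 3L), 1, 3), phylum = "OnlyP")
  agg1 <- aggregate_rank(ab1, "phylum")
  expect_equal(unname(agg1["OnlyP", ]), rep(1, 3))
  # 12 equal-abundance phyla with top_n = 10 leaves 2/12 in Others
  ab12 <- make_abundance(matrix(10L, 12, 4), phylum = paste0("P", 1:12))
  agg12 <- aggregate_rank(ab12, "phylum", top_n = 10)
  expect_equal(unname(agg12["Others", ]), rep(2 / 12, 4))
  expect_equal(unname(colSums(agg12)), rep(1, 4), tolerance = 1e-9)
  expect_error(aggregate_rank(make_abundance(matrix(0L, 2, 2)), "phylum"),
               "empty sample")
})

test_that("rank aggregation equals brute-force group sums", {
  set.seed(3)
  cnt <- matrix(rpois(30 * 6, 20), 30, 6)
  phyla <- sample(paste0("P", 1:7), 30, replace = TRUE)
  ab <- make_abundance(cnt, phylum = phyla)
  agg <- aggregate_rank(ab, "phylum", top_n = 4)
  for (j in 1:6) {
    tot <- sum(cnt[, j])
    for (ph in setdiff(rownames(agg), "Others"))
      expect_equal(agg[ph, j], sum(cnt[phyla == ph, j]) / tot)
    expect_equal(sum(agg[, j]), 1, tolerance = 1e-9)
  }
})

test_that("observed species counts nonzero taxa", {
  expect_equal(observed_species(c(3, 0, 1)), 2)
  expect_equal(observed_species(rep(0, 5)), 0)
  expect_error(observed_species(c(-1, 2)), ">= 0")
  set.seed(1)
  for (i in 1:10) {
    v <- rpois(40, 0.8)
    expect_lte(observed_species(v), length(v))
  }
})

test_that("Chao1 matches its hand-computed forms", {
  # no singletons: nothing to extrapolate
  expect_equal(chao1(c(5, 3, 2, 2)), 4)
  # classic form: S=3, F1=2, F2=1 -> 3 + 4/2 = 5
  expect_equal(chao1(c(1, 1, 2), bias_corrected = FALSE), 5)
  # bias-corrected with no doubletons: S=5, F1=5 -> 5 + 5*4/2 = 15
  expect_equal(chao1(rep(1, 5)), 15)
  expect_error(chao1(rep(0, 3)), "empty")
  expect_error(chao1(c(1, 1, 3), bias_corrected = FALSE), "doubletons")
})

test_that("Chao1 dominates observed richness, with equality iff F1 <= 1", {
  set.seed(42)
  for (i in 1:1000) {
    v <- rpois(60, runif(1, 0.3, 5))
    if (all(v == 0)) next
    ch <- chao1(v)
    s <- observed_species(v)
    expect_gte(ch, s)
    if (sum(v == 1) <= 1) expect_equal(ch, s) else expect_gt(ch, s)
  }
})

test_that("ACE matches a second textbook implementation and vegan", {
  # no rare taxa at all
  expect_equal(ace(c(20, 50, 11)), 3)
  # all singletons: zero coverage falls back to Chao1
  expect_warning(val <- ace(rep(1, 4)), "Chao1")
  expect_equal(val, chao1(rep(1, 4)))
  set.seed(5)
  for (i in 1:50) {
    v <- rpois(80, runif(1, 0.5, 8))
    v <- v[v > 0]
    if (length(v) < 5 || sum(v == 1) == sum(v <= 10)) next
    expect_equal(ace(v), ace_brute(v), tolerance = 1e-12)
  }
  # cross-check against vegan's estimator on integer samples
  for (i in 1:5) {
    v <- rpois(100, 2.5)
    est <- vegan::estimateR(v)
    expect_equal(ace(v), unname(est["S.ACE"]), tolerance = 1e-8)
    expect_equal(chao1(v), unname(est["S.chao1"]), tolerance = 1e-8)
  }
})

test_that("PCoA respects zero distances and 1-D configurations", {
  # two identical pairs of samples coincide in ordination space
  rel <- rbind(a = c(0.5, 0.5, 0), b = c(0.5, 0.5, 0),
               c = c(0, 0.2, 0.8), d = c(0, 0.2, 0.8))
  ord <- beta_ordination(rel, "bray")
  expect_lt(max(abs(ord$coordinates["a", ] - ord$coordinates["b", ])), 1e-6)
  expect_lt(max(abs(ord$coordinates["c", ] - ord$coordinates["d", ])), 1e-6)
  expect_lt(max(abs(colMeans(ord$coordinates))), 1e-6)  # centred
  # collinear points under euclidean distance live on one axis
  pts <- cbind(seq(0, 1, length.out = 5), 2 * seq(0, 1, length.out = 5))
  orde <- beta_ordination(pts, "euclidean")
  expect_equal(orde$proportion[1], 1, tolerance = 1e-9)
  expect_true(all(diff(orde$proportion) <= 1e-12))
  expect_error(beta_ordination(matrix(1, 4, 3), "bray"), "identical")
})

test_that("ordination embeds brute-force Bray-Curtis dissimilarities", {
  set.seed(6)
  rel <- matrix(runif(4 * 8), 4, 8)
  rel <- rel / rowSums(rel)
  rownames(rel) <- paste0("s", 1:4)
  ord <- beta_ordination(rel, "bray", k = 3)
  dmat <- as.matrix(ord$distances)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(dmat[i, j], bc_brute(rel[i, ], rel[j, ]), tolerance = 1e-12)
  }
  # counts go in as relative abundances: same distances either way
  cnt <- matrix(c(10L, 0L, 5L, 5L, 2L, 8L, 0L, 10L, 4L, 6L, 1L, 9L), 3, 4)
  ab <- make_abundance(cnt)
  orda <- beta_ordination(ab, "bray")
  rel2 <- t(sweep(cnt, 2, colSums(cnt), "/"))
  dmat2 <- as.matrix(orda$distances)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(dmat2[i, j], bc_brute(rel2[i, ], rel2[j, ]),
                 tolerance = 1e-12)
})

test_that("PCoA on euclidean distances recovers PCA coordinates", {
  set.seed(11)
  pts <- matrix(rnorm(7 * 3), 7, 3)
  ord <- beta_ordination(pts, "euclidean", k = 2)
  pc <- prcomp(pts, center = TRUE, scale. = FALSE)
  expect_equal(abs(unname(ord$coordinates)), abs(unname(pc$x[, 1:2])),
               tolerance = 1e-8)
})

test_that("alpha comparison recovers generator truth and flags", {
  base <- data.frame(sample_id = paste0("s", 1:6),
                     treatment = rep(c("CK", "T"), each = 3),
                     replicate = rep(1:3, 2))
  same <- cbind(base, observed = rep(100, 6), ace = rep(110, 6),
                chao1 = rep(105, 6))
  # identical groups: zero change; the t test degenerates, so perturb
  same$observed <- same$observed + c(-1, 0, 1, -1, 0, 1)
  cmp <- alpha_compare(same, indices = "observed")
  expect_equal(cmp$percent_change, 0)
  expect_equal(cmp$flag, "ns")
  # a 2x shift in the underlying mean is recovered within noise
  set.seed(12)
  shift <- cbind(base[rep(1:6, 4), ],
                 observed = c(rnorm(12, 100, 5), rnorm(12, 200, 5)))
  shift$treatment <- rep(c("CK", "T"), each = 12)
  shift$sample_id <- paste0("s", 1:24)
  cmp2 <- alpha_compare(shift, indices = "observed")
  expect_equal(cmp2$percent_change, 100, tolerance = 0.1)
  expect_equal(cmp2$flag, "*")
  # sign of the change equals the sign of the mean difference
  expect_equal(sign(cmp2$percent_change),
               sign(cmp2$treatment_mean - cmp2$reference_mean))
  expect_error(alpha_compare(same, reference = "ZZ"), "reference")
})
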