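test_that("generation is byte-identical under a fixed seed", {
  d <- study_design(seed = 7)
  s <- effect_spec(d)
  expect_identical(generate_indicators(d, s), generate_indicators(d, s))
  expect_identical(generate_abundance(d, s, "fungi"),
                   generate_abundance(d, s, "fungi"))
  expect_identical(generate_yield(d, s), generate_yield(d, s))
  # different seed gives different draws
  expect_false(identical(generate_yield(d, s, seed = 1)$yield,
                         generate_yield(d, s, seed = 2)$yield))
})

test_that("zero replicate noise degenerates to the treatment x stage mean", {
  d <- study_design(stages = c("a", "b"), seed = 3)
  s <- effect_spec(d, cv = 0)
  it <- generate_indicators(d, s)
  tc <- it[it$indicator == "TC" & it$stage == "a", ]
  expected <- s$baselines["TC"] * s$effects[tc$treatment, "TC"] *
    s$stage_profile["a", "TC"]
  expect_equal(tc$value, unname(expected))
  # each treatment's replicates all identical
  expect_true(all(tapply(tc$value, tc$treatment, stats::sd) == 0))
})

test_that("abundance columns close exactly at the library size", {
  d <- study_design(seed = 11)
  s <- effect_spec(d)
  ab <- generate_abundance(d, s, "bacteria", library_size = 4321L)
  expect_true(all(colSums(ab$counts) == 4321L))
  expect_true(all(ab$counts >= 0))
  expect_true(is.integer(ab$counts))
  expect_setequal(ab$taxonomy$taxon_id, rownames(ab$counts))
})

test_that("infinite Dirichlet concentration recovers the treatment profile", {
  d <- study_design(seed = 5)
  s <- effect_spec(d)
  ab <- generate_abundance(d, s, "fungi", library_size = 200000L,
                           concentration = Inf)
  rel <- sweep(ab$counts, 2, colSums(ab$counts), "/")
  phylum_rel <- rowsum(rel, ab$taxonomy$phylum)
  for (tr in d$treatments) {
    cols <- ab$metadata$sample_id[ab$metadata$treatment == tr]
    prof <- s$profiles$fungi[tr, rownames(phylum_rel)]
    expect_lt(max(abs(rowMeans(phylum_rel[, cols, drop = FALSE]) - prof)),
              0.01)
  }
})

test_that("generator hits its configured salinity-reduction band", {
  d <- study_design(stages = "maturity", seed = 100)
  s <- effect_spec(d)
  ratios <- vapply(1:200, function(i) {
    it <- generate_indicators(d, s, seed = i)
    tds <- it[it$indicator == "TDS", ]
    mean(tds$value[tds$treatment == "RBC"]) /
      mean(tds$value[tds$treatment == "CK"])
  }, numeric(1))
  expect_gt(mean(ratios), s$tds_band[1])
  expect_lt(mean(ratios), s$tds_band[2])
})

test_that("yield generator is centred on its configured treatment effects", {
  d <- study_design(seed = 42)
  s <- effect_spec(d)
  pc <- vapply(1:500, function(i) {
    y <- generate_yield(d, s, seed = i)
    percent_change(mean(y$yield[y$treatment == "CK"]),
                   mean(y$yield[y$treatment == "RBC"]))
  }, numeric(1))
  expect_gt(mean(pc), 22)
  expect_lt(mean(pc), 33)
  # sd = 0 collapses to the means
  s0 <- s
  s0$yield$sd <- 0
  y0 <- generate_yield(d, s0)
  expect_equal(y0$yield,
               s0$yield$mean[match(y0$treatment, s0$yield$treatment)])
})

test_that("effect directions survive replicate noise", {
  d <- study_design(stages = "maturity", seed = 1)
  s <- effect_spec(d)
  up <- c("TC", "TN", "TOC", "SMC")
  hits <- matrix(0L, 200, length(up) + 1L,
                 dimnames = list(NULL, c(up, "TDS")))
  for (i in 1:200) {
    it <- generate_indicators(d, s, seed = 1000L + i)
    for (ind in up) {
      sm <- treatment_summary(it, ind, "maturity")
      hits[i, ind] <- sm$mean[sm$treatment == "RBC"] >
        sm$mean[sm$treatment == "CK"]
    }
    sm <- treatment_summary(it, "TDS", "maturity")
    hits[i, "TDS"] <- sm$mean[sm$treatment == "RBC"] <
      sm$mean[sm$treatment == "CK"]
  }
  expect_true(all(colMeans(hits) >= 0.95))
})

test_that("invalid specs are rejected", {
  d <- study_design()
  expect_error(effect_spec(d, baselines = c(XYZ = 1)), "unknown indicator")
  expect_error(effect_spec(d, baselines = c(TC = -1)), "non-positive")
  expect_error(effect_spec(d, effects = list(BC = c(TC = -0.5))),
               "strictly positive")
  expect_error(study_design(replicates = 1), "replicates")
  expect_error(study_design(treatments = c("A", "A")), "unique")
  s <- effect_spec(d)
  expect_error(generate_abundance(d, s, "bacteria", library_size = 10),
               ">= 100")
  expect_error(generate_abundance(d, s, "bacteria", n_taxa = 3),
               "at least the number of named groups")
})

test_that("written study files round-trip through the readers", {
  dir <- withr::local_tempdir()
  st <- generate_study(study_design(seed = 2), n_taxa = 40,
                       library_size = 500)
  paths <- write_study(st, dir)
  expect_true(all(file.exists(paths)))
  meta <- read.delim(paths["metadata"])
  ab <- read_abundance(paths["bacteria"], meta, "bacteria")
  expect_identical(unname(ab$counts), unname(st$bacteria$counts))
  expect_identical(ab$taxonomy$phylum, st$bacteria$taxonomy$phylum)
})
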