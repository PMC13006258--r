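---
title: "Methods: soil quality indexing, microbiome analytics and path modeling in salimend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil quality indexing, microbiome analytics and path modeling in salimend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salimend)
```

`salimend` reimplements, as a tested pipeline, the computational chain of a
saline-soil amendment field trial: three treatments (untreated control CK,
cotton-stalk biochar BC, rhamnolipid-modified biochar RBC), three replicate
pits each, soil indicators tracked over the growing season, amplicon count
tables for bacteria and fungi, and per-pit peanut yield. This vignette
documents the models, the tunable parameters, the numerical choices, and
what the synthetic-data generator does and does not emulate.

## Salinity calibration

Total dissolved solids (g/kg) are predicted from the electrical
conductivity of a 5:1 water:soil extract (µS/cm at 25 °C) by the linear
calibration `TDS = 0.0032 · EC − 1.7739`. The line crosses zero near
EC ≈ 554 µS/cm, so low-salinity extracts would yield negative solids; the
source material is silent on this regime, and `tds_from_ec()` clips
negative predictions to zero with a warning rather than returning a
physically impossible value. Above the clip point the function is affine,
which the test suite asserts directly.

## The Soil Quality Index

Twelve indicators enter the index: moisture (SMC), total dissolved solids
(TDS), total carbon (TC), total nitrogen (TN), organic carbon (TOC), five
enzyme activities (urease RUE, sucrase SUC, alkaline phosphatase AKP,
catalase CAT, cellulase SCL), and a bacterial and a fungal richness value.
Each is scored linearly onto [0, 1] with extremes taken over the whole
scoring population (all samples pooled across treatments; a per-stage
option exists because the pooling population is a genuine modelling
choice). TDS is the single "less is better" indicator — salinity harms
soil quality — and uses the complementary score; everything else scores
"more is better".

Weights are objective: a PCA of the standardized 12-indicator matrix,
components retained by the Kaiser rule (eigenvalue > 1; the retention rule
is configurable because it is a convention, not a law), communality of
indicator *i* = sum of its squared loadings over retained components, and
`W_i` = communality_i / Σ communalities. The index is the weighted sum
`SQI = Σ W_i S_i ∈ [0, 1]`. Feeding the published communality table of the
motivating trial (`field_reference$communalities`) through
`communality_weights()` reproduces its printed weights to three decimals.

Yield is regressed on SQI at replicate level (nine points). The motivating
trial's printed regression was evidently fitted on replicate-level points
too — its three treatment means give a different slope — so replicate
level is the default granularity here, with the operation accepting either.

Which richness statistic fills the "Bacteria"/"Fungi" rows is not
derivable from the source material; `salimend` exposes it as a
configuration choice (`sqi$diversity_indicator`): the default `"table"`
uses the indicator table's columns as supplied (the generator fills them
with Chao1-like values), while `"chao1"`, `"ace"` or `"observed"`
recompute the values from the count matrices.

## Diversity estimators

Observed species counts nonzero taxa. Chao1 defaults to the bias-corrected
form `S_obs + F1(F1−1)/(2(F2+1))`, defined even without doubletons; the
classic form `S_obs + F1²/(2F2)` is available when `F2 > 0`. ACE uses the
standard rare/abundant split at 10 reads, coverage `C = 1 − F1/N_rare` and
a squared coefficient-of-variation term floored at zero; when every rare
taxon is a singleton the coverage is zero and the estimator falls back to
Chao1 with a warning. Both estimators are verified against hand-computed
fixtures, an independently coded textbook implementation, and
`vegan::estimateR`.

No rarefaction is applied by default: alpha diversity runs on raw counts
and beta diversity on relative abundances (the generator's libraries are
equal-sized by construction, so rarefaction would be a no-op there; with
real data of unequal depth the user should normalise first). Beta
diversity is classical PCoA of Bray-Curtis dissimilarities (Jaccard and
Euclidean selectable); negative eigenvalues are reported and axis
proportions computed over the positive part. The distance metric of the
original ordination is not recoverable from the source material, hence the
configurable default.

## Co-occurrence networks

Edges connect taxon pairs whose Spearman correlation satisfies |r| > 0.7
and p < 0.05 (raw, two-sided, asymptotic — ties make exact p-values
unavailable). No multiple-testing correction is applied by default, which
mirrors the stated rule; Benjamini–Hochberg is available behind a flag. A
prevalence filter (present in ≥ 1/3 of samples by default) precedes
correlation, and constant taxa are excluded with a warning since their
correlation is undefined.

Two conventions deserve emphasis. First, nodes are taxa (default
taxon/genus level) *annotated* by phylum: phylum-level graphs could never
contain the 150+ nodes that treatment-wise topology tables report, so the
finer rank is the only consistent reading. Second, taxa left without any
retained edge are dropped from the node set by default (making node counts
treatment-dependent), with `keep_isolates = TRUE` available.

The topology report gives nodes, links, average degree 2L/N, the mean
local clustering coefficient with degree < 2 nodes contributing zero, the
mean shortest-path length over pairs inside the largest connected
component (the source material is silent on disconnected graphs), and the
modularity of a greedy agglomerative partition of the unsigned graph. The
greedy agglomeration is deterministic, so reports reproduce exactly. On
all shipped small-graph fixtures the metrics agree with brute-force
recomputation, and on two disjoint triangles the greedy modularity attains
the exhaustive-partition optimum.

A practical constraint: a Spearman test on three replicates can never
reach p < 0.05, so per-treatment networks require at least four replicates
per treatment. With the default three-replicate design `run_pipeline()`
builds one pooled network per kingdom; `networks_by_treatment()` produces
treatment-wise networks whenever the replication supports them.

## Driver attribution

Taxon-environment relations are screened by Spearman correlation with
flags at p < 0.05 and p < 0.01, uncorrected by default (mirroring the
heatmap convention of the motivating analysis), BH optional. Community
structure is summarised by PCA scores of Hellinger-transformed relative
abundances — the square-root transform blunts compositional artifacts;
raw proportions are selectable. Axis signs are fixed by forcing the most
abundant group's loading to be nonnegative, making scores deterministic
across platforms.

"Variance explained" per factor is the out-of-bag R² of a seeded
single-factor random-forest regression on the PC score, floored at zero
and scaled to 0–100. Single-factor models are the default because they
yield per-factor percentages that need not sum to 100, matching how such
bar charts are usually read; a joint-model permutation-importance variant
is available. Neither variant claims to reproduce any particular published
percentage — that would require the raw study data.

## PLS path modeling

`fit_plspm()` implements the classical iterative algorithm: manifests
standardized; outer weights initialized at one; inner estimation by the
centroid scheme (signs of latent correlations; factorial and path schemes
selectable); mode-A outer estimation (weights = correlations of manifests
with the inner estimate); scores rescaled to zero mean, unit variance;
iterate until the largest absolute change in normalized outer weights
falls below `1e-7` (maximum 300 iterations, with non-convergence reported
together with the last delta). Path coefficients are then OLS of each
endogenous latent on its predecessors, loadings are manifest–latent
correlations, block communality is the mean squared loading, and
`GoF = √(mean communality × mean R²)` with the communality mean taken over
multi-manifest blocks (a single-indicator block measures its latent
exactly) and the R² mean over endogenous latents.

All blocks are reflective (mode A); measurement modes are never stated in
the kind of analysis this mirrors, and mode A is the conventional default.
Latent sign indeterminacy is resolved by aligning each latent with its
manifests (positive loading sum). On single-indicator blocks the whole
model provably collapses to OLS among standardized observed variables,
which the tests assert against closed-form least squares; a two-latent
single-indicator model returns exactly the manifest correlation.

The pipeline's default structural model uses one exogenous single-indicator
dummy block per non-reference treatment (BC, RBC). Including a third dummy
for the reference as well would make every inner regression that receives
all three singular (the dummies sum to one), which `fit_plspm()` reports
as an error ("singular predecessor set") rather than silently resolving.

Bootstrap significance resamples rows with replacement (default 500
replicates, seeded, hence fully reproducible), reports percentile
confidence intervals, and a two-sided p-value from the bootstrap tail mass
on the opposite side of zero (floored at `2/(B+1)`); refits failing in
more than 20 % of replicates abort with diagnostics.

## The synthetic-data generator

The generator defines the study conditions the tests exercise:

* **Design:** CK/BC/RBC × 3 replicate pits × 4 growth stages.
* **Indicators:** log-normal replicate noise around treatment × stage
  means (positivity is guaranteed — enzyme activities cannot go negative),
  with a 5 % coefficient of variation matching the tightness of the
  published treatment tables (yield CV ≈ 3.8 %, SQI CV ≈ 4 %). Treatment
  multipliers are midpoints of the published seasonal effect ranges (e.g.
  RBC total dissolved solids ×0.519, within the configured 0.43–0.61
  band; organic carbon ×4.07; catalase ×0.86). Carbon, nitrogen and
  moisture follow a rise-then-fall seasonal profile, salinity a phase
  fluctuation, enzymes and richness are stage-constant (they were assayed
  once, at maturity).
* **Communities:** taxon counts are Dirichlet-multinomial around
  treatment-specific phylum profiles (control profile at the midpoints of
  the published abundance ranges, treatment profiles from the stated
  enrichment/suppression factors, renormalized), with library sizes of
  6000 (bacteria) and 2000 (fungi) reads — the per-sample scale of the
  sequencing effort being emulated — and concentration 200 (moderate
  overdispersion; `Inf` collapses to the exact profile).
* **Yield:** normal noise truncated at zero around the published
  treatment means and standard deviations (CK 5089.53 ± 192.96,
  BC 5762.47 ± 135.79, RBC 6492.69 ± 272.75 kg/ha), so the configured
  RBC-vs-CK gain is +27.6 %.
* **Seeding:** one master seed; each stage derives a child seed by a
  fixed, documented offset (`salimend:::seed_offsets`), so studies are
  byte-identical under a fixed seed and stages are independently
  reproducible.

The distributional forms (log-normal, truncated normal,
Dirichlet-multinomial) are this package's own choices — the published
material reports only means and dispersions — and are therefore stated,
not inferred.

What the generator does **not** emulate: sequencing reads and their error
structure (only count tables); within-season temporal autocorrelation
beyond independent stage means; and richness differences between
treatments in the count tables — composition shifts are emulated, but all
treatments share a richness structure, so treatment effects on diversity
enter through the Chao1-like indicator columns rather than the counts.
Consequently, passing tests demonstrate the correctness of the
computational chain under realistic effect sizes and noise, not the
reproduction of any field-data-dependent quantity (absolute network
topology, published variance-explained percentages, the published GoF of
0.71, or the published replicate-level yield regression).

## Problem sizes and determinism in the test suite

The suite favours small, fully checkable problems: exhaustive-partition
modularity on ≤ 6 nodes (203 partitions), brute-force shortest paths and
clustering on the same fixtures, 1000-sample property sweeps for the
richness estimators, 200-resimulation Monte-Carlo checks of the
generator's configured effect bands, 20-seed sign-recovery for the
five-latent path model at n = 200, and a 100-seed Monte-Carlo of the
SQI/yield stage of the pipeline (the stage whose ordering claims are being
verified; one full all-stage run is asserted separately). Every stochastic
test fixes its seed, and end-to-end determinism is asserted by comparing
the key-numbers table across two identical runs.
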