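#' Define a field-trial study design
#'
#' Describes the layout the synthetic generator emulates: an ordered set of
#' treatments, a fixed number of replicate pits per treatment, and ordered
#' growth stages at which soil indicators are sampled. The default mirrors a
#' three-treatment saline-soil amendment trial: untreated control (CK),
#' cotton-stalk biochar (BC), and rhamnolipid-modified biochar (RBC), with
#' three replicate pits each.
#'
#' @param treatments character, unique ordered treatment labels; the first is
#'   taken as the reference (control) downstream.
#' @param replicates integer >= 2, replicate pits per treatment.
#' @param stages character, ordered growth-stage labels (>= 1).
#' @param seed non-negative integer master seed; per-stage child seeds are
#'   derived by the fixed offsets in `seed_offsets`.
#' @return an object of class `study_design`.
#' @export
study_design <- function(treatments = c("CK", "BC", "RBC"),
                         replicates = 3L,
                         stages = c("seedling", "flowering",
                                    "pod_setting", "maturity"),
                         seed = 1L) {
  treatments <- as.character(treatments)
  if (anyDuplicated(treatments)) stop("treatment labels must be unique")
  if (length(treatments) < 1L) stop("need at least one treatment")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 2L)
    stop("`replicates` must be an integer >= 2 (variance-based stages need it)")
  stages <- as.character(stages)
  if (length(stages) < 1L) stop("need at least one growth stage")
  assert_scalar_number(seed, "seed", nonneg = TRUE)
  structure(
    list(treatments = treatments, replicates = replicates,
         stages = stages, seed = as.integer(seed)),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", length(x$treatments), "treatments x",
      x$replicates, "replicates,", length(x$stages), "growth stages\n")
  cat("  treatments:", paste(x$treatments, collapse = ", "), "\n")
  cat("  stages:    ", paste(x$stages, collapse = ", "), "\n")
  cat("  seed:      ", x$seed, "\n")
  invisible(x)
}

# The 12 indicators entering the soil quality index.
sqi_indicators <- c("SMC", "TDS", "TC", "TN", "TOC", "RUE", "SUC",
                    "AKP", "CAT", "SCL", "Bacteria", "Fungi")

# Baseline control-soil means. Physicochemistry follows the trial site's
# reported sandy-loam baseline (total C 17.98, total N 0.61, organic C
# 1.53 g/kg; 5:1 extract EC around 3.5 mS/cm, i.e. ~9.4 g/kg dissolved
# solids). Enzyme activities and diversity proxies are typical magnitudes for
# saline sandy loam.
default_baselines <- c(
  SMC = 12,     # moisture, % w/w
  TDS = 9.4,    # total dissolved solids, g/kg
  TC  = 17.98,  # total carbon, g/kg
  TN  = 0.61,   # total nitrogen, g/kg
  TOC = 1.53,   # organic carbon, g/kg
  RUE = 20,     # urease, ug NH4-N/g/d
  SUC = 15,     # sucrase, mg glucose/g/d
  AKP = 10,     # alkaline phosphatase, umol/g/d
  CAT = 12,     # catalase, umol H2O2/g/d
  SCL = 5,      # cellulase, mg glucose/g/d
  Bacteria = 1500, # bacterial richness proxy (Chao1-like)
  Fungi    = 300   # fungal richness proxy (Chao1-like)
)

# Treatment multipliers relative to control, taken as midpoints of the
# seasonal effect ranges observed in the motivating trial (e.g. modified
# biochar: total C +30.3..45.2 %, dissolved solids -39.4..-56.8 %, urease
# +31.7 %, catalase -14.1 %; plain biochar weaker on most, stronger on AKP).
default_effects <- list(
  BC = c(SMC = 1.15,  TDS = 0.80,  TC = 1.159, TN = 1.177, TOC = 2.018,
         RUE = 1.15,  SUC = 1.18,  AKP = 1.2772, CAT = 0.7228, SCL = 1.80,
         Bacteria = 0.882, Fungi = 1.04),
  RBC = c(SMC = 1.340, TDS = 0.519, TC = 1.378, TN = 1.422, TOC = 4.071,
          RUE = 1.3167, SUC = 1.3362, AKP = 1.0361, CAT = 0.8587,
          SCL = 2.6066, Bacteria = 0.95, Fungi = 1.114)
)

# Band the modified-biochar dissolved-solids multiplier is designed to sit
# in (a 39-57 % reduction); used by generator self-checks.
rbc_tds_band <- c(0.43, 0.61)

# Seasonal modulation of the treatment mean. Carbon, nitrogen and moisture
# rise then fall over the season; salinity fluctuates in phases; enzyme and
# diversity proxies are modelled stage-constant (they were assayed once, at
# maturity, in the motivating trial).
default_stage_profile <- function(stages, indicator) {
  k <- length(stages)
  hump  <- c(SMC = TRUE, TC = TRUE, TN = TRUE, TOC = TRUE)
  if (isTRUE(hump[indicator])) {
    # symmetric rise-then-fall around mid-season, +/-10 %
    x <- seq(0, 1, length.out = max(k, 2L))[seq_len(k)]
    0.95 + 0.15 * sin(pi * x)
  } else if (identical(indicator, "TDS")) {
    # phase fluctuation, +/-8 %
    1 + 0.08 * cos(seq(0, 2 * pi, length.out = max(k, 2L))[seq_len(k)])
  } else {
    rep(1, k)
  }
}

# --- default community profiles ------------------------------------------

# Phylum-level relative-abundance profiles per treatment: control profile at
# the midpoints of the abundance ranges seen in the motivating trial,
# treatment profiles obtained by the stated enrichment/suppression factors
# and renormalised.
bacteria_base_profile <- c(
  Proteobacteria = 32.17, Firmicutes = 26.36, Bacteroidetes = 7.99,
  Planctomycetes = 7.27, Acidobacteria = 7.23, Chloroflexi = 5.86,
  Actinobacteria = 4.84, Gemmatimonadetes = 3.75, Nitrospirae = 1.16,
  Rhodothermaeota = 0.99, Others = 2.41
)
bacteria_adjust <- list(
  BC  = c(Proteobacteria = 0.97, Firmicutes = 1.25, Acidobacteria = 1.05),
  RBC = c(Proteobacteria = 1.0163, Firmicutes = 1.0335,
          Acidobacteria = 1.1739, Chloroflexi = 1.128)
)

fungi_base_profile <- c(
  Ascomycota = 78, Basidiomycota = 13.1, Chytridiomycota = 2.17,
  Mucoromycota = 2.8, Zoopagomycota = 0.01, Blastocladiomycota = 0.04,
  Cryptomycota = 0.004, Others = 3.9
)
fungi_adjust <- list(
  BC  = c(Ascomycota = 1.06, Chytridiomycota = 1.30, Zoopagomycota = 3,
          Basidiomycota = 0.70),
  RBC = c(Ascomycota = 1.1501, Chytridiomycota = 1.7630,
          Zoopagomycota = 8.5529, Basidiomycota = 0.35, Mucoromycota = 0.60)
)

# Named genera used to label the most abundant taxa per phylum; remaining
# taxa get synthetic genus labels.
genus_pool <- list(
  bacteria = list(
    Firmicutes = c("Bacillus", "Neobacillus", "Metabacillus", "Niallia",
                   "Peribacillus"),
    Acidobacteria = "Luteitalea", Chloroflexi = "Litorilinea",
    Bacteroidetes = "Sediminibacterium", Gemmatimonadetes = "Longimicrobium",
    Proteobacteria = "Wenzhouxiangella"
  ),
  fungi = list(
    Ascomycota = c("Stolonocarpus", "Aspergillus", "Allocanariomyces",
                   "Penicillium", "Trichurus", "Chaetomium", "Colletotrichum",
                   "Alternaria", "Fusarium"),
    Basidiomycota = "Entoloma"
  )
)

build_profiles <- function(treatments, base, adjust) {
  base <- base / sum(base)
  out <- matrix(rep(base, length(treatments)), nrow = length(treatments),
                byrow = TRUE, dimnames = list(treatments, names(base)))
  for (tr in intersect(treatments, names(adjust))) {
    f <- adjust[[tr]]
    out[tr, names(f)] <- out[tr, names(f)] * f
    out[tr, ] <- out[tr, ] / sum(out[tr, ])
  }
  out
}

#' Default effect specification for the synthetic study
#'
#' Bundles everything the generator needs: per-indicator control baselines
#' and coefficient of variation, per-treatment multiplicative effects,
#' seasonal stage profiles, phylum-level community profiles per treatment
#' for bacteria and fungi, and per-treatment yield means and standard
#' deviations. Defaults emulate the effect directions and magnitudes of the
#' motivating saline-soil amendment trial; yield defaults are its reported
#' treatment means (CK 5089.53 +/- 192.96, BC 5762.47 +/- 135.79, RBC
#' 6492.69 +/- 272.75 kg/ha).
#'
#' @param design a [study_design()].
#' @param baselines named numeric, control means per indicator.
#' @param cv positive scalar coefficient of variation of replicate noise
#'   (may be 0 for noise-free tables).
#' @param effects named list per non-reference treatment of named multiplier
#'   vectors (missing indicators default to 1).
#' @param yield data.frame with columns `treatment`, `mean`, `sd`.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(design,
                        baselines = default_baselines,
                        cv = 0.05,
                        effects = default_effects,
                        yield = NULL) {
  stopifnot(inherits(design, "study_design"))
  if (is.null(names(baselines)) || any(!nzchar(names(baselines))))
    stop("`baselines` must be a named numeric vector")
  if (any(baselines <= 0)) stop("non-positive baseline mean")
  unknown <- setdiff(names(baselines), c(sqi_indicators, "EC"))
  if (length(unknown))
    stop("unknown indicator in spec: ", paste(unknown, collapse = ", "))
  assert_scalar_number(cv, "cv", nonneg = TRUE)
  ref <- design$treatments[1L]
  eff <- matrix(1, nrow = length(design$treatments),
                ncol = length(baselines),
                dimnames = list(design$treatments, names(baselines)))
  for (tr in intersect(design$treatments, names(effects))) {
    f <- effects[[tr]]
    bad <- setdiff(names(f), names(baselines))
    if (length(bad))
      stop("unknown indicator in spec: ", paste(bad, collapse = ", "))
    if (any(f <= 0)) stop("effect multipliers must be strictly positive")
    eff[tr, names(f)] <- f
  }
  if (is.null(yield)) {
    yield <- data.frame(
      treatment = c("CK", "BC", "RBC"),
      mean = c(5089.53, 5762.47, 6492.69),
      sd   = c(192.96, 135.79, 272.75)
    )
    yield <- yield[yield$treatment %in% design$treatments, , drop = FALSE]
    missing_tr <- setdiff(design$treatments, yield$treatment)
    if (length(missing_tr))
      yield <- rbind(yield, data.frame(treatment = missing_tr,
                                       mean = 5000, sd = 200))
    yield <- yield[match(design$treatments, yield$treatment), ]
  }
  if (!all(c("treatment", "mean", "sd") %in% names(yield)))
    stop("`yield` needs columns treatment, mean, sd")
  if (any(yield$sd < 0)) stop("yield sd must be >= 0")
  stage_profile <- sapply(names(baselines), function(ind)
    default_stage_profile(design$stages, ind))
  stage_profile <- matrix(stage_profile, nrow = length(design$stages),
                          dimnames = list(design$stages, names(baselines)))
  profiles <- list(
    bacteria = build_profiles(design$treatments, bacteria_base_profile,
                              bacteria_adjust),
    fungi    = build_profiles(design$treatments, fungi_base_profile,
                              fungi_adjust)
  )
  structure(
    list(baselines = baselines, cv = cv, effects = eff,
         stage_profile = stage_profile, profiles = profiles,
         yield = yield, reference = ref, tds_band = rbc_tds_band),
    class = "effect_spec"
  )
}

sample_ids <- function(design) {
  data.frame(
    sample_id = paste(rep(design$treatments, each = design$replicates),
                      rep(seq_len(design$replicates),
                          length(design$treatments)), sep = "_"),
    treatment = rep(design$treatments, each = design$replicates),
    replicate = rep(seq_len(design$replicates), length(design$treatments)),
    stringsAsFactors = FALSE
  )
}

# Log-normal draw parameterised by arithmetic mean m and coefficient of
# variation cv; cv = 0 degenerates to the mean exactly.
rlnorm_mean_cv <- function(n, m, cv) {
  if (cv == 0) return(rep_len(m, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic soil-indicator table
#'
#' One record per sample x growth stage x indicator, drawn from a log-normal
#' noise model around the treatment x stage mean (positivity is guaranteed;
#' enzyme activities cannot go negative). Deterministic for a fixed seed.
#'
#' @param design a [study_design()].
#' @param spec an [effect_spec()].
#' @param seed integer; defaults to the design's derived indicator seed.
#' @return a long `data.frame` of class `indicator_table` with columns
#'   `sample_id`, `treatment`, `replicate`, `stage`, `indicator`, `value`.
#' @export
generate_indicators <- function(design, spec,
                                seed = child_seed(design$seed, "indicators")) {
  stopifnot(inherits(design, "study_design"), inherits(spec, "effect_spec"))
  meta <- sample_ids(design)
  inds <- names(spec$baselines)
  grid <- expand.grid(stage = design$stages, indicator = inds,
                      row = seq_len(nrow(meta)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(
    sample_id = meta$sample_id[grid$row],
    treatment = meta$treatment[grid$row],
    replicate = meta$replicate[grid$row],
    stage     = grid$stage,
    indicator = grid$indicator,
    stringsAsFactors = FALSE
  )
  m <- spec$baselines[out$indicator] *
    spec$effects[cbind(out$treatment, out$indicator)] *
    spec$stage_profile[cbind(out$stage, out$indicator)]
  out$value <- with_seed(seed, rlnorm_mean_cv(length(m), m, spec$cv))
  # fixed record order: sample, stage, indicator
  out <- out[order(match(out$sample_id, meta$sample_id),
                   match(out$stage, design$stages),
                   match(out$indicator, inds)), ]
  rownames(out) <- NULL
  class(out) <- c("indicator_table", "data.frame")
  out
}

#' Pivot an indicator table to wide (one column per indicator)
#' @param table an `indicator_table` (long form).
#' @return a wide `data.frame`, one row per sample x stage.
#' @export
indicator_wide <- function(table) {
  stopifnot(is.data.frame(table))
  w <- stats::reshape(as.data.frame(table), direction = "wide",
                      idvar = c("sample_id", "treatment", "replicate", "stage"),
                      timevar = "indicator")
  names(w) <- sub("^value\\.", "", names(w))
  attr(w, "reshapeWide") <- NULL
  rownames(w) <- NULL
  w
}

# Allocate n_taxa across phyla proportionally to profile mass (>=1 each),
# then split each phylum's mass over its member taxa with a geometric decay,
# giving a realistic dominance structure. Entirely deterministic.
build_taxonomy <- function(profile_cols, n_taxa, kingdom) {
  phyla <- names(profile_cols)
  if (n_taxa < length(phyla))
    stop("`n_taxa` must be at least the number of named groups (",
         length(phyla), ")")
  raw <- profile_cols / sum(profile_cols) * n_taxa
  n_per <- pmax(floor(raw), 1L)   # keeps names (first arg wins)
  # largest-remainder adjustment to hit n_taxa exactly
  while (sum(n_per) < n_taxa) {
    i <- which.max(raw - n_per)
    n_per[i] <- n_per[i] + 1L
  }
  while (sum(n_per) > n_taxa) {
    cand <- which(n_per > 1L)
    i <- cand[which.min((raw - n_per)[cand])]
    n_per[i] <- n_per[i] - 1L
  }
  pool <- genus_pool[[kingdom]]
  rows <- lapply(phyla, function(ph) {
    k <- n_per[[ph]]
    named <- if (!is.null(pool[[ph]])) pool[[ph]] else character()
    genus <- c(named, sprintf("%s_g%02d", ph,
                              seq_len(max(0L, k - length(named)))))[seq_len(k)]
    w <- 0.7^(seq_len(k) - 1L)
    data.frame(phylum = ph, genus = genus, weight = w / sum(w),
               stringsAsFactors = FALSE)
  })
  tax <- do.call(rbind, rows)
  tax$taxon_id <- sprintf("%s_t%03d", substr(kingdom, 1, 3),
                          seq_len(nrow(tax)))
  tax[, c("taxon_id", "phylum", "genus", "weight")]
}

#' Generate a synthetic amplicon count matrix
#'
#' Per-sample counts are drawn compositionally: sample proportions come from
#' a Dirichlet distribution centred on the treatment's taxon-level profile
#' (phylum profile spread over member taxa), then counts from a multinomial
#' with fixed library size, so column sums are exact. `concentration = Inf`
#' collapses the Dirichlet to the profile itself.
#'
#' @param design a [study_design()].
#' @param spec an [effect_spec()].
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @param library_size reads per sample (>= 100).
#' @param n_taxa number of taxa (>= number of named phylum groups).
#' @param concentration Dirichlet concentration; larger = less overdispersion.
#' @param seed integer seed.
#' @return an object of class `abundance_matrix`: a list with `counts`
#'   (taxa x samples integer matrix), `taxonomy` (taxon_id, phylum, genus),
#'   `metadata` (sample_id, treatment, replicate) and `kingdom`.
#' @export
generate_abundance <- function(design, spec,
                               kingdom = c("bacteria", "fungi"),
                               library_size = if (kingdom == "bacteria") 6000L else 2000L,
                               n_taxa = if (kingdom == "bacteria") 200L else 60L,
                               concentration = 200,
                               seed = child_seed(design$seed, kingdom)) {
  kingdom <- match.arg(kingdom)
  stopifnot(inherits(design, "study_design"), inherits(spec, "effect_spec"))
  if (library_size < 100) stop("`library_size` must be >= 100")
  prof <- spec$profiles[[kingdom]]
  if (any(abs(rowSums(prof) - 1) > 1e-8))
    stop("treatment profile does not sum to 1 within 1e-8")
  tax <- build_taxonomy(prof[1L, ], n_taxa, kingdom)
  meta <- sample_ids(design)
  # taxon-level profile per treatment
  taxon_prof <- sapply(design$treatments, function(tr)
    prof[tr, tax$phylum] * tax$weight)
  taxon_prof <- sweep(taxon_prof, 2, colSums(taxon_prof), "/")
  counts <- with_seed(seed, {
    vapply(seq_len(nrow(meta)), function(j) {
      p0 <- taxon_prof[, meta$treatment[j]]
      p <- if (is.infinite(concentration)) p0 else {
        g <- stats::rgamma(length(p0), shape = concentration * p0, rate = 1)
        if (sum(g) == 0) p0 else g / sum(g)
      }
      as.integer(stats::rmultinom(1L, size = library_size, prob = p))
    }, integer(nrow(tax)))
  })
  dimnames(counts) <- list(tax$taxon_id, meta$sample_id)
  structure(
    list(counts = counts,
         taxonomy = tax[, c("taxon_id", "phylum", "genus")],
         metadata = meta, kingdom = kingdom),
    class = "abundance_matrix"
  )
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("Abundance matrix (%s): %d taxa x %d samples, %d phyla\n",
              x$kingdom, nrow(x$counts), ncol(x$counts),
              length(unique(x$taxonomy$phylum))))
  invisible(x)
}

#' Generate synthetic per-pit yields
#'
#' One yield value per treatment x replicate, drawn from a normal
#' distribution truncated at zero (resampling the rare negative draw).
#' `sd = 0` returns the treatment means exactly.
#'
#' @param design a [study_design()].
#' @param spec an [effect_spec()] (its `yield` slot holds means and sds,
#'   kg/ha).
#' @param seed integer seed.
#' @return data.frame with `sample_id`, `treatment`, `replicate`, `yield`.
#' @export
generate_yield <- function(design, spec,
                           seed = child_seed(design$seed, "yield")) {
  stopifnot(inherits(design, "study_design"), inherits(spec, "effect_spec"))
  if (any(spec$yield$sd < 0)) stop("yield sd must be >= 0")
  meta <- sample_ids(design)
  pars <- spec$yield[match(meta$treatment, spec$yield$treatment), ]
  meta$yield <- with_seed(seed, {
    vapply(seq_len(nrow(meta)), function(i) {
      if (pars$sd[i] == 0) return(pars$mean[i])
      repeat {
        y <- stats::rnorm(1L, pars$mean[i], pars$sd[i])
        if (y >= 0) return(y)
      }
    }, numeric(1))
  })
  meta
}

#' Generate a complete synthetic study
#'
#' Indicator table, bacterial and fungal count matrices, and yields, all
#' derived from one master seed by fixed offsets.
#'
#' @param design a [study_design()].
#' @param spec an [effect_spec()]; defaults to `effect_spec(design)`.
#' @param ... passed on to [generate_abundance()] (e.g. `n_taxa`,
#'   `library_size`, `concentration`) for both kingdoms.
#' @return an object of class `synthetic_study`: list with `design`, `spec`,
#'   `indicators`, `bacteria`, `fungi`, `yield`.
#' @export
generate_study <- function(design = study_design(),
                           spec = effect_spec(design), ...) {
  structure(
    list(design = design, spec = spec,
         indicators = generate_indicators(design, spec),
         bacteria = generate_abundance(design, spec, "bacteria", ...),
         fungi    = generate_abundance(design, spec, "fungi", ...),
         yield    = generate_yield(design, spec)),
    class = "synthetic_study"
  )
}

#' Write a synthetic study to TSV files
#'
#' Writes `metadata.tsv`, `indicators.tsv` (wide), `bacteria.tsv` /
#' `fungi.tsv` (taxa rows x sample columns, leading columns `taxon_id`,
#' `phylum`, `genus`), and `yield.tsv`.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    metadata = file.path(dir, "metadata.tsv"),
    indicators = file.path(dir, "indicators.tsv"),
    bacteria = file.path(dir, "bacteria.tsv"),
    fungi = file.path(dir, "fungi.tsv"),
    yield = file.path(dir, "yield.tsv")
  )
  meta <- sample_ids(study$design)
  write_tsv_file(meta, paths["metadata"])
  write_tsv_file(indicator_wide(study$indicators), paths["indicators"])
  for (k in c("bacteria", "fungi")) {
    ab <- study[[k]]
    write_tsv_file(cbind(ab$taxonomy, as.data.frame(ab$counts)), paths[k])
  }
  write_tsv_file(study$yield, paths["yield"])
  invisible(paths)
}

#' Read an abundance TSV back into an `abundance_matrix`
#'
#' @param path TSV written by [write_study()] (columns `taxon_id`, `phylum`,
#'   `genus`, then one column per sample).
#' @param metadata data.frame with `sample_id`, `treatment`, `replicate`.
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @return an `abundance_matrix`.
#' @export
read_abundance <- function(path, metadata, kingdom = "bacteria") {
  df <- read_tsv_file(path)
  need <- c("taxon_id", "phylum", "genus")
  if (!all(need %in% names(df)))
    stop("abundance TSV needs leading columns taxon_id, phylum, genus")
  counts <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  rownames(counts) <- df$taxon_id
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, taxonomy = df[, need],
                 metadata = metadata, kingdom = kingdom),
            class = "abundance_matrix")
}
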