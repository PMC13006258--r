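#' Default run configuration
#'
#' Builds the configuration list consumed by [run_pipeline()]: generator
#' settings (or input paths), the master seed, per-stage toggles and
#' parameters. The list round-trips losslessly through YAML
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param seed master seed; stage seeds derive from it by fixed offsets.
#' @param out_dir optional output directory; `NULL` keeps everything in
#'   memory.
#' @param stages named logical vector toggling pipeline stages.
#' @return a `run_config` list.
#' @export
default_run_config <- function(seed = 1L, out_dir = NULL,
                               stages = c(soil = TRUE, sqi = TRUE,
                                          diversity = TRUE, network = TRUE,
                                          drivers = TRUE, plspm = TRUE)) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    generator = list(enabled = TRUE,
                     treatments = c("CK", "BC", "RBC"),
                     replicates = 3L,
                     growth_stages = c("seedling", "flowering",
                                       "pod_setting", "maturity"),
                     cv = 0.05,
                     library_size_bacteria = 6000L,
                     library_size_fungi = 2000L,
                     n_taxa_bacteria = 200L,
                     n_taxa_fungi = 60L,
                     concentration = 200),
    inputs = NULL,
    stages = as.list(stages),
    sqi = list(stage = "maturity", diversity_indicator = "table",
               retain = "kaiser"),
    network = list(r_threshold = 0.7, p_threshold = 0.05,
                   min_prevalence = 1 / 3),
    drivers = list(transform = "hellinger", n_tree = 500L),
    plspm = list(scheme = "centroid", n_boot = 0L)
  ), class = "run_config")
}

#' @rdname default_run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' Validate pipeline input files
#'
#' Checks TSV schemas and cross-table consistency: metadata columns,
#' indicator coverage, abundance sample columns present in the metadata
#' (absence is a hard error; extra metadata samples are a warning), and
#' taxonomy completeness.
#'
#' @param paths named list/vector with elements `metadata`, `indicators`,
#'   `bacteria`, `fungi`, `yield` (any subset).
#' @return list with character vectors `errors` and `warnings`.
#' @export
validate_inputs <- function(paths) {
  errors <- character(); warnings <- character()
  note <- function(lst, msg) c(lst, msg)
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]]))
      errors <- note(errors, paste0("missing file: ", nm, " (", paths[[nm]], ")"))
  }
  if (length(errors)) return(list(errors = errors, warnings = warnings))
  meta <- NULL
  if (!is.null(paths$metadata)) {
    meta <- read_tsv_file(paths$metadata)
    need <- c("sample_id", "treatment", "replicate")
    if (!all(need %in% names(meta)))
      errors <- note(errors, "metadata must have sample_id, treatment, replicate")
  }
  if (!is.null(paths$indicators)) {
    ind <- read_tsv_file(paths$indicators)
    if (!all(c("sample_id", "treatment", "stage") %in% names(ind)))
      errors <- note(errors, "indicator table must have sample_id, treatment, stage")
    if (!is.null(meta) && all(c("sample_id") %in% names(ind))) {
      extra <- setdiff(meta$sample_id, ind$sample_id)
      if (length(extra))
        warnings <- note(warnings, paste0("metadata sample(s) without indicators: ",
                                          paste(extra, collapse = ", ")))
    }
  }
  for (k in c("bacteria", "fungi")) {
    if (is.null(paths[[k]])) next
    ab <- read_tsv_file(paths[[k]])
    lead <- c("taxon_id", "phylum", "genus")
    if (!all(lead %in% names(ab))) {
      errors <- note(errors, paste0(k, " table must start with taxon_id, phylum, genus"))
      next
    }
    if (anyNA(ab$phylum) || any(!nzchar(ab$phylum)))
      errors <- note(errors, paste0(k, ": incomplete phylum taxonomy"))
    samples <- setdiff(names(ab), lead)
    if (!is.null(meta)) {
      orphan <- setdiff(samples, meta$sample_id)
      if (length(orphan))
        errors <- note(errors, paste0(k, " sample(s) absent from metadata: ",
                                      paste(orphan, collapse = ", ")))
      extra <- setdiff(meta$sample_id, samples)
      if (length(extra))
        warnings <- note(warnings, paste0("metadata sample(s) without ", k,
                                          " counts: ", paste(extra, collapse = ", ")))
    }
  }
  if (!is.null(paths$yield)) {
    yl <- read_tsv_file(paths$yield)
    if (!all(c("sample_id", "yield") %in% names(yl)))
      errors <- note(errors, "yield table must have sample_id, yield")
  }
  list(errors = errors, warnings = warnings)
}

load_study_inputs <- function(inputs) {
  v <- validate_inputs(inputs)
  if (length(v$errors))
    stop("input validation failed:\n  ", paste(v$errors, collapse = "\n  "))
  meta <- read_tsv_file(inputs$metadata)
  ind_wide <- read_tsv_file(inputs$indicators)
  long <- stats::reshape(
    ind_wide, direction = "long",
    varying = setdiff(names(ind_wide),
                      c("sample_id", "treatment", "replicate", "stage")),
    v.names = "value", timevar = "indicator",
    times = setdiff(names(ind_wide),
                    c("sample_id", "treatment", "replicate", "stage")),
    idvar = c("sample_id", "stage"))
  rownames(long) <- NULL
  class(long) <- c("indicator_table", "data.frame")
  list(metadata = meta,
       indicators = long,
       bacteria = read_abundance(inputs$bacteria, meta, "bacteria"),
       fungi = read_abundance(inputs$fungi, meta, "fungi"),
       yield = read_tsv_file(inputs$yield))
}

kn_row <- function(stage, metric, value)
  data.frame(stage = stage, metric = metric, value = as.numeric(value),
             stringsAsFactors = FALSE)

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on either a generated
#' synthetic study or user-supplied TSV inputs: treatment summaries and
#' percent-change envelopes for the soil indicators; alpha/beta diversity;
#' the PCA-communality-weighted soil quality index and the yield-SQI
#' regression; per-kingdom co-occurrence networks with topology reports;
#' Spearman/random-forest driver attribution; and the PLS path model.
#' Fails fast with the failing stage named. Reruns with the same config are
#' bit-identical.
#'
#' @param config a `run_config` (see [default_run_config()]) or the path
#'   to a YAML file holding one.
#' @return object of class `run_report`: `key_numbers` (data.frame stage /
#'   metric / value), `results` (per-stage objects), `manifest` (files
#'   written, if `out_dir` set), `seed`, `version`, `stages_run`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- as.integer(config$seed)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  enabled <- function(s) isTRUE(config$stages[[s]])
  results <- list(); kn <- list(); manifest <- character()

  # --- inputs -------------------------------------------------------------
  if (isTRUE(config$generator$enabled)) {
    g <- config$generator
    design <- study_design(g$treatments, g$replicates, g$growth_stages,
                           seed = seed)
    spec <- effect_spec(design, cv = g$cv)
    study <- run_stage("generate", list(
      metadata = sample_ids(design),
      indicators = generate_indicators(design, spec),
      bacteria = generate_abundance(design, spec, "bacteria",
                                    library_size = g$library_size_bacteria,
                                    n_taxa = g$n_taxa_bacteria,
                                    concentration = g$concentration),
      fungi = generate_abundance(design, spec, "fungi",
                                 library_size = g$library_size_fungi,
                                 n_taxa = g$n_taxa_fungi,
                                 concentration = g$concentration),
      yield = generate_yield(design, spec)))
    reference <- design$treatments[1L]
    stages_vec <- design$stages
  } else {
    if (is.null(config$inputs)) stop("generator disabled and no inputs given")
    study <- run_stage("load_inputs", load_study_inputs(config$inputs))
    reference <- unique(study$metadata$treatment)[1L]
    stages_vec <- unique(study$indicators$stage)
  }
  results$study <- study
  treatments <- unique(study$metadata$treatment)
  sqi_stage <- config$sqi$stage
  if (!sqi_stage %in% stages_vec) sqi_stage <- stages_vec[length(stages_vec)]

  # --- soil ---------------------------------------------------------------
  if (enabled("soil")) {
    soil <- run_stage("soil", {
      inds <- unique(study$indicators$indicator)
      env_rows <- list()
      for (ind in inds) {
        per_stage <- lapply(stages_vec, function(st)
          treatment_summary(study$indicators, ind, st))
        for (tr in setdiff(treatments, reference)) {
          pcs <- vapply(per_stage, function(s)
            percent_change(s$mean[s$treatment == reference],
                           s$mean[s$treatment == tr]), numeric(1))
          env_rows[[length(env_rows) + 1L]] <- data.frame(
            indicator = ind, treatment = tr,
            min_change = min(pcs), max_change = max(pcs),
            stringsAsFactors = FALSE)
        }
      }
      list(summary_at_sqi_stage = lapply(
             stats::setNames(nm = inds), treatment_summary,
             table = study$indicators, stage = sqi_stage),
           change_envelope = do.call(rbind, env_rows))
    })
    results$soil <- soil
    env <- soil$change_envelope
    for (i in seq_len(nrow(env)))
      kn[[length(kn) + 1L]] <- kn_row(
        "soil", sprintf("pct_change_%s_%s_max", env$indicator[i],
                        env$treatment[i]), env$max_change[i])
  }

  # --- diversity ----------------------------------------------------------
  if (enabled("diversity")) {
    div <- run_stage("diversity", {
      out <- list()
      for (k in c("bacteria", "fungi")) {
        alpha <- alpha_diversity(study[[k]])
        out[[k]] <- list(
          alpha = alpha,
          alpha_vs_reference = alpha_compare(alpha, reference = reference),
          ordination = beta_ordination(study[[k]]),
          phylum = aggregate_rank(study[[k]], "phylum"),
          genus = aggregate_rank(study[[k]], "genus"))
      }
      out
    })
    results$diversity <- div
    for (k in c("bacteria", "fungi")) {
      kn[[length(kn) + 1L]] <- kn_row(
        "diversity", paste0(k, "_pco1_pct"),
        100 * div[[k]]$ordination$proportion[1L])
      cmp <- div[[k]]$alpha_vs_reference
      chao_rbc <- cmp[cmp$index == "chao1", ]
      for (i in seq_len(nrow(chao_rbc)))
        kn[[length(kn) + 1L]] <- kn_row(
          "diversity", sprintf("%s_chao1_pct_change_%s", k,
                               chao_rbc$treatment[i]),
          chao_rbc$percent_change[i])
    }
  }

  # --- sqi ----------------------------------------------------------------
  if (enabled("sqi")) {
    sq <- run_stage("sqi", {
      wide <- indicator_wide(study$indicators)
      wide <- wide[wide$stage == sqi_stage, , drop = FALSE]
      wide <- wide[match(study$metadata$sample_id, wide$sample_id), ]
      mat <- as.matrix(wide[, intersect(sqi_indicators, names(wide)),
                            drop = FALSE])
      rownames(mat) <- wide$sample_id
      # richness indicators recomputed from the count tables when present
      if (config$sqi$diversity_indicator %in% c("chao1", "ace", "observed") &&
          !is.null(study$bacteria)) {
        for (k in c("bacteria", "fungi")) {
          a <- alpha_diversity(study[[k]])
          col <- if (k == "bacteria") "Bacteria" else "Fungi"
          mat[, col] <- a[[config$sqi$diversity_indicator]][
            match(rownames(mat), a$sample_id)]
        }
      }
      st <- score_table(mat)
      comm <- pca_communalities(mat, retain = config$sqi$retain)
      wts <- communality_weights(comm)
      sqi <- compute_sqi(st, wts, treatment = wide$treatment)
      yl <- study$yield[match(rownames(mat), study$yield$sample_id), ]
      fit <- fit_yield_sqi(sqi$sqi, yl$yield)
      ymeans <- tapply(yl$yield, factor(yl$treatment, treatments), mean)
      list(scores = st, communalities = comm, weights = wts, sqi = sqi,
           yield_fit = fit, yield_means = ymeans)
    })
    results$sqi <- sq
    bt <- sq$sqi$by_treatment
    ref_sqi <- bt$mean[bt$treatment == reference]
    ref_y <- sq$yield_means[[reference]]
    for (tr in treatments) {
      kn[[length(kn) + 1L]] <- kn_row("sqi", paste0("sqi_mean_", tr),
                                      bt$mean[bt$treatment == tr])
      if (tr != reference) {
        kn[[length(kn) + 1L]] <- kn_row(
          "sqi", paste0("sqi_pct_change_", tr),
          percent_change(ref_sqi, bt$mean[bt$treatment == tr]))
        kn[[length(kn) + 1L]] <- kn_row(
          "sqi", paste0("yield_pct_change_", tr),
          percent_change(ref_y, sq$yield_means[[tr]]))
      }
    }
    kn[[length(kn) + 1L]] <- kn_row("sqi", "yield_sqi_slope",
                                    sq$yield_fit$slope)
    kn[[length(kn) + 1L]] <- kn_row("sqi", "yield_sqi_r_squared",
                                    sq$yield_fit$r_squared)
  }

  # --- network ------------------------------------------------------------
  if (enabled("network")) {
    net <- run_stage("network", {
      rule <- edge_rule(r_threshold = config$network$r_threshold,
                       p_threshold = config$network$p_threshold)
      out <- list()
      per_treatment <- min(table(study$metadata$treatment)) >= 4L
      for (k in c("bacteria", "fungi")) {
        if (per_treatment) {
          out[[k]] <- networks_by_treatment(
            study[[k]], rule, config$network$min_prevalence)
        } else {
          # with < 4 replicates per treatment the per-treatment correlation
          # test has no power; one pooled network per kingdom instead
          es <- correlation_edges(study[[k]]$counts, rule,
                                  config$network$min_prevalence)
          g <- cooccurrence_graph(es, study[[k]]$taxonomy, treatment = "all")
          out[[k]] <- structure(
            list(graphs = list(all = g),
                 topology = cbind(treatment = "all", topology(g)),
                 edges = list(all = es), kingdom = k),
            class = "network_set")
        }
      }
      out
    })
    results$network <- net
    for (k in c("bacteria", "fungi")) {
      tp <- net[[k]]$topology
      for (i in seq_len(nrow(tp))) {
        pre <- sprintf("%s_%s_", k, tp$treatment[i])
        kn[[length(kn) + 1L]] <- kn_row("network", paste0(pre, "links"),
                                        tp$links[i])
        kn[[length(kn) + 1L]] <- kn_row("network", paste0(pre, "modularity"),
                                        tp$modularity[i])
      }
    }
  }

  # --- drivers ------------------------------------------------------------
  if (enabled("drivers") && enabled("sqi")) {
    drv <- run_stage("drivers", {
      wide <- indicator_wide(study$indicators)
      wide <- wide[wide$stage == sqi_stage, , drop = FALSE]
      wide <- wide[match(study$metadata$sample_id, wide$sample_id), ]
      env <- wide[, intersect(c("RUE", "SUC", "AKP", "CAT", "SCL", "TC",
                                "TOC", "TN", "TDS", "SMC"), names(wide)),
                  drop = FALSE]
      env$SQI <- results$sqi$sqi$sqi[wide$sample_id]
      env$Y <- study$yield$yield[match(wide$sample_id,
                                       study$yield$sample_id)]
      out <- list(env = env)
      for (k in c("bacteria", "fungi")) {
        rel <- aggregate_rank(study[[k]], "phylum")
        pcs <- community_pc_scores(rel, transform = config$drivers$transform)
        out[[k]] <- list(
          correlations = taxon_env_correlation(rel, env),
          pc_scores = pcs,
          variance_explained = rf_variance_explained(
            env, pcs$scores[, 1L], n_tree = config$drivers$n_tree,
            seed = child_seed(seed, "drivers")))
      }
      out
    })
    results$drivers <- drv
    for (k in c("bacteria", "fungi")) {
      ve <- drv[[k]]$variance_explained
      top <- ve[which.max(ve$variance_explained), ]
      kn[[length(kn) + 1L]] <- kn_row(
        "drivers", sprintf("%s_top_factor_variance_explained", k),
        top$variance_explained)
    }
  }

  # --- plspm --------------------------------------------------------------
  if (enabled("plspm") && enabled("sqi") && enabled("diversity")) {
    pm <- run_stage("plspm", {
      wide <- indicator_wide(study$indicators)
      wide <- wide[wide$stage == sqi_stage, , drop = FALSE]
      wide <- wide[match(study$metadata$sample_id, wide$sample_id), ]
      dat <- wide
      # treatment enters through amendment dummies against the reference;
      # a dummy per treatment would make the inner regressions singular
      for (tr in setdiff(treatments, reference))
        dat[[paste0("is_", tr)]] <- as.numeric(dat$treatment == tr)
      for (k in c("bacteria", "fungi")) {
        a <- results$diversity[[k]]$alpha
        col <- if (k == "bacteria") "bact_chao1" else "fung_chao1"
        dat[[col]] <- a$chao1[match(dat$sample_id, a$sample_id)]
      }
      dat$yield <- study$yield$yield[match(dat$sample_id,
                                           study$yield$sample_id)]
      amend <- setdiff(treatments, reference)
      blk_args <- c(
        stats::setNames(lapply(amend, function(tr) paste0("is_", tr)), amend),
        list(soil = intersect(c("SMC", "TDS", "TC", "TN", "TOC"), names(dat)),
             enzyme = intersect(c("RUE", "SUC", "AKP", "CAT", "SCL"),
                                names(dat)),
             bacteria = "bact_chao1", fungi = "fung_chao1",
             yield = "yield"))
      blocks <- do.call(plspm_blocks, blk_args)
      edges <- c(
        lapply(amend, function(tr) c(tr, "soil")),
        lapply(amend, function(tr) c(tr, "enzyme")),
        list(c("soil", "enzyme"),
             c("soil", "bacteria"), c("enzyme", "bacteria"),
             c("soil", "fungi"), c("enzyme", "fungi"),
             c("soil", "yield"), c("enzyme", "yield"),
             c("bacteria", "yield"), c("fungi", "yield")))
      paths <- plspm_paths(blocks, edges)
      fit <- fit_plspm(dat, blocks, paths, scheme = config$plspm$scheme)
      boot <- NULL
      if (config$plspm$n_boot >= 100L)
        boot <- bootstrap_paths(dat, blocks, paths,
                                scheme = config$plspm$scheme,
                                n_boot = config$plspm$n_boot,
                                seed = child_seed(seed, "plspm"))
      list(fit = fit, bootstrap = boot)
    })
    results$plspm <- pm
    kn[[length(kn) + 1L]] <- kn_row("plspm", "gof", pm$fit$gof)
    kn[[length(kn) + 1L]] <- kn_row(
      "plspm", "path_soil_to_yield",
      pm$fit$path_matrix["yield", "soil"])
  }

  key_numbers <- do.call(rbind, kn)
  # --- outputs ------------------------------------------------------------
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (isTRUE(config$generator$enabled)) {
      study_obj <- structure(
        list(design = design, spec = spec, indicators = study$indicators,
             bacteria = study$bacteria, fungi = study$fungi,
             yield = study$yield),
        class = "synthetic_study")
      manifest <- c(manifest, write_study(study_obj, config$out_dir))
    }
    kn_path <- file.path(config$out_dir, "key_numbers.tsv")
    write_tsv_file(key_numbers, kn_path)
    manifest <- c(manifest, kn_path)
    if (!is.null(results$sqi)) {
      wpath <- file.path(config$out_dir, "sqi_weights.tsv")
      write_tsv_file(data.frame(indicator = names(results$sqi$weights),
                                communality = as.numeric(results$sqi$communalities),
                                weight = as.numeric(results$sqi$weights)),
                     wpath)
      manifest <- c(manifest, wpath)
    }
    if (!is.null(results$network)) {
      for (k in c("bacteria", "fungi")) {
        tpath <- file.path(config$out_dir, paste0("topology_", k, ".tsv"))
        write_tsv_file(results$network[[k]]$topology, tpath)
        manifest <- c(manifest, tpath)
        for (tr in names(results$network[[k]]$graphs)) {
          gpath <- file.path(config$out_dir,
                             sprintf("network_%s_%s.graphml", k, tr))
          igraph::write_graph(results$network[[k]]$graphs[[tr]], gpath,
                              format = "graphml")
          manifest <- c(manifest, gpath)
        }
      }
    }
  }
  structure(
    list(key_numbers = key_numbers, results = results, manifest = manifest,
         seed = seed,
         version = as.character(utils::packageVersion("salimend")),
         stages_run = names(Filter(isTRUE, config$stages))),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ", salimend ", x$version, ")\n",
      sep = "")
  cat("Stages:", paste(x$stages_run, collapse = ", "), "\n")
  cat("Key numbers:\n")
  print(x$key_numbers, row.names = FALSE)
  invisible(x)
}
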