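## End-to-end orchestration: simulate -> harmonize -> wscore -> interaction
## -> pls -> gsea -> tissue, over plain TSV/GMT/JSON interchange files so
## every intermediate is diffable. Each output carries a header comment with
## the stage name, seed, and a config hash; a JSON manifest records stages,
## outputs, seeds, and wall time.

#' Polynomial rolling hash of a config (serialized to JSON), as hex digits
#' @keywords internal
#' @noRd
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out <- NULL  # hash the scientific config, not the output location
  bytes <- utf8ToInt(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                                   digits = NA)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Default pipeline configuration
#'
#' Nested sections mirroring each stage's parameters, with per-stage seeds
#' derived from the global seed. Problem sizes are desk-scale: the cohort
#' mirrors the default [cohort_config()], expression uses 1000 genes with a
#' 20-gene planted set, the spin test uses 1000 permutations and the
#' bootstrap 1000 replicates.
#'
#' @param seed Global integer seed.
#' @param out Output directory (created if missing).
#' @return A nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L, out = tempfile("protectomap_")) {
  seed <- as.integer(seed)
  structure(list(
    seed = seed,
    out = out,
    stages = list(harmonize = TRUE, wscore = TRUE, interaction = TRUE,
                  pls = TRUE, gsea = TRUE, tissue = TRUE),
    cohort = list(seed = seed),
    expression = list(n_genes = 1000, smoothing_length = 0.3,
                      planted_set_size = 20, planted_coupling = 0.8,
                      seed = seed + 1L),
    pls = list(n_components = 2, n_perm = 1000, n_boot = 1000,
               boot_components = 1, seed = seed + 2L),
    gsea = list(n_random_sets = 50, set_size_range = c(5, 200),
                min_size = 5, max_size = 2000, n_perm = 1000,
                setcover_k = 10, seed = seed + 3L),
    tissue = list(n_tissues = 54, n_brain = 13, brain_fold = 8,
                  seed = seed + 4L)
  ), class = "pipeline_config")
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes the enabled stages in order on generated data: cohort simulation,
#' site harmonization, normative W-scoring of patients, per-region
#' sex-interaction estimation and atrophy tests, PLS with spin-based
#' component significance and bootstrap gene ratios, preranked gene-set
#' enrichment with set-cover reduction, and the brain-vs-periphery tissue
#' comparison of the top gene against a mid-ranked reference gene. All
#' stages are deterministic given the config.
#'
#' @param config A `pipeline_config` (see [default_pipeline_config()]).
#' @return The run manifest (list), invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  t0 <- Sys.time()
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  stamp <- function(df, name, stage) {
    write_tsv_stamped(df, file.path(out, name), stage = stage,
                      seed = config$seed, config_hash = hash)
    name
  }
  manifest <- list(seed = config$seed, config_hash = hash,
                   package_version = as.character(
                     utils::packageVersion("protectomap")),
                   stages = list())
  note <- function(stage, outputs) {
    manifest$stages[[stage]] <<- list(
      outputs = outputs,
      elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                        2))
  }

  ## -- simulate ------------------------------------------------------------
  ccfg <- do.call(cohort_config, config$cohort)
  geom <- generate_geometry(ccfg$n_regions, seed = config$seed)
  cohort <- generate_cohort(ccfg, geom)
  thick_df <- data.frame(id = rownames(cohort$thickness),
                         cohort$thickness, check.names = FALSE)
  note("simulate",
       c(stamp(cohort$participants, "participants.tsv", "simulate"),
         stamp(thick_df, "thickness.tsv", "simulate"),
         stamp(geom, "geometry.tsv", "simulate")))

  ## -- harmonize -----------------------------------------------------------
  thickness <- cohort$thickness
  if (isTRUE(config$stages$harmonize)) {
    model <- combat_fit(thickness, cohort$participants)
    thickness <- combat_apply(model, thickness, cohort$participants)
    dump <- model[c("covariates", "site_levels", "n_per_site", "alpha")]
    dump$gamma_star <- model$gamma_star
    dump$delta_star <- model$delta_star
    jsonlite::write_json(dump, file.path(out, "combat_model.json"),
                         digits = NA)
    hdf <- data.frame(id = rownames(thickness), thickness,
                      check.names = FALSE)
    note("harmonize", c(stamp(hdf, "thickness_harmonized.tsv", "harmonize"),
                        "combat_model.json"))
  }

  ## -- wscore --------------------------------------------------------------
  results <- list()
  inter <- NULL
  if (isTRUE(config$stages$wscore)) {
    pt <- cohort$participants
    is_ctl <- pt$group == "control"
    norm <- fit_normative(thickness[is_ctl, , drop = FALSE], pt[is_ctl, ])
    W <- compute_wscores(thickness[!is_ctl, , drop = FALSE], pt[!is_ctl, ],
                         norm)
    wdf <- data.frame(id = rownames(W), W, check.names = FALSE)
    note("wscore", stamp(wdf, "wscores.tsv", "wscore"))

    ## -- interaction & atrophy ----------------------------------------------
    if (isTRUE(config$stages$interaction)) {
      psex <- pt$sex[!is_ctl]
      inter <- sex_interaction_estimates(W, psex)
      atro <- list(M = regional_atrophy_test(W, psex, "M"),
                   F = regional_atrophy_test(W, psex, "F"))
      atro_sum <- lapply(atro, function(a)
        a[c("n", "n_sig_p", "n_sig_q", "prop_sig_p", "prop_sig_q")])
      jsonlite::write_json(atro_sum, file.path(out, "atrophy_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      note("interaction", c(stamp(inter, "interaction.tsv", "interaction"),
                            "atrophy_summary.json"))
      results$atrophy <- atro_sum
    }
  }

  ## -- expression + pls ----------------------------------------------------
  if (isTRUE(config$stages$pls) && !is.null(inter)) {
    ecfg <- do.call(expression_config, config$expression)
    expr <- generate_expression(ecfg, geom, planted_interaction_map(ccfg))
    edf <- data.frame(region_id = rownames(expr$expression),
                      expr$expression, check.names = FALSE)
    stamp(edf, "expression.tsv", "expression")
    y <- inter$beta
    pcfg <- config$pls
    model <- pls_fit(expr$expression, y, n_components = pcfg$n_components)
    nulls <- spin_permutations(geom, n_perm = pcfg$n_perm, seed = pcfg$seed)
    p_spin <- lv_significance(model, expr$expression, y, nulls)
    boot <- bootstrap_gene_weights(expr$expression, y,
                                   components = pcfg$boot_components,
                                   n_boot = pcfg$n_boot,
                                   seed = pcfg$seed + 1L)
    rsc <- region_score_correlation(model, y, component = 1)
    comp_df <- data.frame(component = seq_len(pcfg$n_components),
                          frac_y_variance = model$frac_y_variance,
                          cum_frac = model$cum_frac, p_spin = p_spin)
    stamp(comp_df, "components.tsv", "pls")
    stamp(data.frame(region_id = rownames(expr$expression), model$scores,
                     check.names = FALSE), "scores.tsv", "pls")
    ranked <- bootstrap_ranked_list(boot, component = pcfg$boot_components[1])
    stamp(data.frame(gene = names(ranked), bootstrap_ratio = ranked),
          "gene_ratios.tsv", "pls")
    results$pls <- list(frac_y_variance = model$frac_y_variance,
                        p_spin = p_spin, score_cor_r = rsc$r,
                        score_cor_p = rsc$p)
    note("pls", c("expression.tsv", "components.tsv", "scores.tsv",
                  "gene_ratios.tsv"))

    ## -- gsea ---------------------------------------------------------------
    if (isTRUE(config$stages$gsea)) {
      gcfg <- config$gsea
      sets <- generate_genesets(colnames(expr$expression),
                                expr$planted_genes,
                                n_random_sets = gcfg$n_random_sets,
                                size_range = gcfg$set_size_range,
                                seed = gcfg$seed)
      write_gmt(sets, file.path(out, "genesets.gmt"))
      enr <- gsea_preranked(ranked, sets, min_size = gcfg$min_size,
                            max_size = gcfg$max_size, n_perm = gcfg$n_perm,
                            seed = gcfg$seed + 1L)
      reduced <- weighted_set_cover(enr[!is.na(enr$q) & enr$q < 0.05, ],
                                    k = gcfg$setcover_k)
      flat <- enr[, setdiff(names(enr), "leading_edge")]
      stamp(flat, "enrichment.tsv", "gsea")
      stamp(reduced[, setdiff(names(reduced), "leading_edge")],
            "enrichment_reduced.tsv", "gsea")
      results$gsea <- list(
        top_term = enr$term[1],
        planted_rank_by_nes = match("planted_interaction_set", enr$term),
        planted_q = enr$q[enr$term == "planted_interaction_set"])
      note("gsea", c("genesets.gmt", "enrichment.tsv",
                     "enrichment_reduced.tsv"))
    }

    ## -- tissue -------------------------------------------------------------
    if (isTRUE(config$stages$tissue)) {
      tcfg <- config$tissue
      top_gene <- names(ranked)[1]
      ref_gene <- names(ranked)[ceiling(length(ranked) / 2)]
      tt <- generate_tissue_table(colnames(expr$expression),
                                  n_tissues = tcfg$n_tissues,
                                  n_brain = tcfg$n_brain,
                                  brain_enriched_genes = top_gene,
                                  brain_fold = tcfg$brain_fold,
                                  seed = tcfg$seed)
      tdf <- data.frame(gene = rownames(tt$tpm), tt$tpm, check.names = FALSE)
      stamp(tdf, "tissues.tsv", "tissue")
      stamp(tt$labels, "tissue_labels.tsv", "tissue")
      cmp <- brain_enrichment_compare(tt, top_gene, ref_gene)
      results$tissue <- list(gene = top_gene, reference = ref_gene,
                             counts = cmp$counts, chi2 = cmp$chi2, p = cmp$p)
      jsonlite::write_json(results$tissue,
                           file.path(out, "tissue_enrichment.json"),
                           auto_unbox = TRUE, digits = NA)
      note("tissue", c("tissues.tsv", "tissue_labels.tsv",
                       "tissue_enrichment.json"))
    }
  }

  manifest$results <- results
  manifest$wall_time_s <- round(as.numeric(difftime(Sys.time(), t0,
                                                    units = "secs")), 2)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
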