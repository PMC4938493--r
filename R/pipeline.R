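#' Default pipeline configuration
#'
#' Stage parameters of the end-to-end synthetic run.  The network stage
#' uses the conventional soft power 6 with minimum module size 30; the
#' differential stage runs 50 permutations per shuffling scheme; the
#' Bayesian-network stage runs a ten-to-twenty-gene problem with an
#' ensemble of 300 networks (a desk-scale ensemble; the sampler's own
#' default is 1000), cis-eQTL prior penalty 3, consensus threshold 0.3 and
#' neighborhood depth 3; the drug stage uses 1000 permutations.
#'
#' @return named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    beta = 6L,
    min_size = 30L,
    deep_split = 2L,
    sv_alpha = 0.05,
    sv_B = 100L,
    sv_remove = FALSE,
    n_perm = 50L,
    robustness_splits = 10L,
    robustness_label_perm = 30L,
    eqtl_window = 1e6,
    eqtl_alpha = 1e-3,
    lambda = 3,
    n_networks = 300L,
    n_restarts = 6L,
    max_parents = 3L,
    consensus_threshold = 0.3,
    h = 3L,
    tfbs_threshold = 0.85,
    drug_n_perm = 1000L,
    stages = c("simulate", "preprocess", "network", "mdc", "enrich",
               "conserve", "traits", "tfbs", "bayesnet", "drugscore", "pin")
  )
}

config_ranges <- function() {
  list(
    beta = c(1, 30), min_size = c(2, Inf), deep_split = c(0, 4),
    sv_alpha = c(1e-6, 0.5), sv_B = c(10, Inf), n_perm = c(20, Inf),
    robustness_splits = c(10, Inf), robustness_label_perm = c(10, Inf),
    eqtl_window = c(0, Inf), eqtl_alpha = c(0, 1), lambda = c(0, Inf),
    n_networks = c(100, Inf), n_restarts = c(1, Inf),
    max_parents = c(1, Inf), consensus_threshold = c(1e-9, 1),
    h = c(1, Inf), tfbs_threshold = c(1e-9, 1), drug_n_perm = c(100, Inf),
    seed = c(0, 2^31 - 2))
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a named list or a YAML/JSON file path.  Unknown keys are
#' reported with the nearest valid key; out-of-range values are aggregated
#' into one error message; missing keys are filled with defaults.
#'
#' @param config named list, file path, or NULL for pure defaults.
#' @return the normalized configuration list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  defaults <- default_pipeline_config()
  errs <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  for (k in unknown) {
    near <- names(defaults)[which.min(utils::adist(k, names(defaults)))]
    errs <- c(errs, sprintf("unknown key '%s' (did you mean '%s'?)", k, near))
  }
  merged <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  rng <- config_ranges()
  for (k in names(rng)) {
    v <- merged[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) ||
        v < rng[[k]][1] || v > rng[[k]][2])
      errs <- c(errs, sprintf("'%s' = %s out of range [%s, %s]",
                              k, format(merged[[k]]), rng[[k]][1], rng[[k]][2]))
  }
  bad_stage <- setdiff(merged$stages, defaults$stages)
  if (length(bad_stage) > 0)
    errs <- c(errs, paste("unknown stage(s):", paste(bad_stage, collapse = ", ")))
  deps <- list(preprocess = "simulate", network = "preprocess",
               mdc = "network", enrich = "mdc", conserve = "network",
               traits = "network", tfbs = "simulate", bayesnet = "simulate",
               drugscore = "simulate", pin = "simulate")
  for (st in merged$stages) {
    need <- deps[[st]]
    if (!is.null(need) && !need %in% merged$stages)
      errs <- c(errs, sprintf("stage '%s' requires disabled stage '%s'", st, need))
  }
  if (length(errs) > 0)
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  merged
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-study pipeline
#'
#' Generates the synthetic study, corrects expression, builds the
#' coexpression network and modules, computes MDC with permutation FDR,
#' enrichment and composite module ranking, cross-species conservation,
#' trait and grade associations, TFBS enrichment with composite TF ranks,
#' the Bayesian-network consensus with key drivers, drug connectivity
#' scores, and protein-network enrichment, writing each stage's tables
#' under `out_dir` and a reproducibility manifest (config hash, seeds, file
#' checksums).
#'
#' @param config pipeline configuration (list or path); see
#'   [validate_config()].
#' @param out_dir output directory.
#' @param sim_config optional [simulation_config()]; defaults to the
#'   reference study conditions at the pipeline seed.
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("dcxnet_run_"),
                         sim_config = NULL) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = cfg)
  on_stage <- function(s) s %in% cfg$stages

  # --- simulate -------------------------------------------------------------
  if (is.null(sim_config)) sim_config <- simulation_config(seed = cfg$seed)
  study <- generate_synthetic_study(sim_config)
  res$study <- study
  if (on_stage("simulate"))
    write_synthetic_study(study, file.path(out_dir, "inputs"))

  co <- study$cohort
  es <- expression_study(co$expr, condition = co$condition,
                         covariates = co$covariates[, c("age", "sex")])

  # --- preprocess -----------------------------------------------------------
  if (on_stage("preprocess")) {
    es <- adjust_covariates(es, c("age", "sex"))
    res$svs <- estimate_surrogate_variables(
      es, character(0), alpha = cfg$sv_alpha, B = cfg$sv_B,
      seed = substream_seed(cfg$seed, "sva"))
    # the generator plants no unmeasured confounder: leading residual PCs
    # are the module factors themselves, so removal is opt-in
    if (isTRUE(cfg$sv_remove)) es <- remove_svs(es, res$svs)
    write_expression(es, file.path(out_dir, "expression_corrected.tsv"))
    write_tsv(data.frame(sample = rownames(res$svs$sv), res$svs$sv,
                         check.names = FALSE),
              file.path(out_dir, "surrogate_variables.tsv"))
  }

  # --- network --------------------------------------------------------------
  if (on_stage("network")) {
    tom <- topological_overlap(soft_adjacency(correlation_matrix(es), cfg$beta))
    partition <- detect_modules(tom, min_size = cfg$min_size,
                                deep_split = cfg$deep_split)
    res$partition <- partition
    write_tsv(data.frame(gene = names(partition), module = unname(partition)),
              file.path(out_dir, "modules.tsv"))
    egs <- module_eigengenes(es, partition)
    res$eigengenes <- egs
    write_tsv(data.frame(sample = rownames(egs), egs, check.names = FALSE),
              file.path(out_dir, "eigengenes.tsv"))
    res$robustness <- module_robustness(
      es, partition, n_splits = cfg$robustness_splits,
      seed = substream_seed(cfg$seed, "robust"), beta = cfg$beta,
      n_label_perm = cfg$robustness_label_perm)
    write_tsv(res$robustness, file.path(out_dir, "module_robustness.tsv"))
    res$expression_audit <- compare_module_expression(es, partition)
    write_tsv(res$expression_audit$module_medians,
              file.path(out_dir, "module_median_expression.tsv"))
  }

  # --- mdc ------------------------------------------------------------------
  if (on_stage("mdc")) {
    expr_case <- es$expr[, es$condition == "case", drop = FALSE]
    expr_ctrl <- es$expr[, es$condition == "control", drop = FALSE]
    res$mdc <- mdc_fdr(expr_case, expr_ctrl, res$partition,
                       n_perm = cfg$n_perm,
                       seed = substream_seed(cfg$seed, "mdc"),
                       beta = cfg$beta)
    write_tsv(res$mdc, file.path(out_dir, "mdc.tsv"))
    res$preservation <- median_rank_preservation(expr_ctrl, expr_case,
                                                 res$partition, beta = cfg$beta)
    write_tsv(res$preservation, file.path(out_dir, "median_rank.tsv"))
  }

  # --- enrich ---------------------------------------------------------------
  if (on_stage("enrich")) {
    signatures <- list(de_signature = co$de_truth)
    res$enrichment <- module_signature_enrichment(res$partition, signatures)
    write_tsv(res$enrichment, file.path(out_dir, "enrichment.tsv"))
    res$module_rank <- rank_modules(res$mdc, res$enrichment)
    write_tsv(res$module_rank, file.path(out_dir, "module_rank.tsv"))
  }

  # --- conserve -------------------------------------------------------------
  if (on_stage("conserve")) {
    sp2 <- generate_homologous_species(sim_config, co$partition_truth)
    res$conservation <- map_modules_across_species(
      res$partition, sp2$partition_b, sp2$homology)
    write_tsv(res$conservation, file.path(out_dir, "conservation.tsv"))
  }

  # --- traits ---------------------------------------------------------------
  if (on_stage("traits")) {
    res$trait_assoc <- module_trait_correlations(res$eigengenes, study$traits)
    res$trait_rank <- rank_modules_by_traits(res$trait_assoc)
    write_tsv(res$trait_assoc, file.path(out_dir, "module_traits.tsv"))
    write_tsv(res$trait_rank$ranking, file.path(out_dir, "trait_ranking.tsv"))
    res$grade <- lapply(colnames(res$eigengenes), function(mo) {
      ga <- grade_association(res$eigengenes[, mo], co$grade)
      data.frame(module = mo, H = ga$H, p = ga$p,
                 neg_log10_p = ga$neg_log10_p)
    })
    res$grade <- do.call(rbind, res$grade)
    write_tsv(res$grade, file.path(out_dir, "grade_association.tsv"))
  }

  # --- tfbs -----------------------------------------------------------------
  if (on_stage("tfbs")) {
    mo <- study$motifs
    planted <- motif_from_consensus(mo$consensus, name = "TF_planted")
    decoys <- tfbs_decoy_motifs(mo$consensus, seed = substream_seed(cfg$seed, "decoys"))
    motifs <- c(list(TF_planted = planted), decoys)
    de_p <- de_neg_log10_by_gene(co)
    tf_gene <- stats::setNames(
      c(co$de_truth[1], setdiff(names(de_p), co$de_truth)[seq_len(length(decoys))]),
      names(motifs))
    recs <- lapply(names(motifs), function(nm) {
      sc <- scan_and_score_motif(mo$target, mo$background, motifs[[nm]],
                                 cfg$tfbs_threshold)
      data.frame(tf = nm, z_score = sc$enrichment$z_score,
                 fisher_p = sc$enrichment$fisher_p,
                 de_neg_log10_p = unname(de_p[tf_gene[nm]]))
    })
    res$tfbs <- composite_tf_rank(do.call(rbind, recs))
    write_tsv(res$tfbs, file.path(out_dir, "tfbs_rank.tsv"))
  }

  # --- bayesnet -------------------------------------------------------------
  if (on_stage("bayesnet")) {
    gen <- study$genetic
    res$eqtls <- detect_cis_eqtls(gen$expr, gen$genotypes, gen$gene_pos,
                                  gen$snp_pos, window = cfg$eqtl_window,
                                  alpha = cfg$eqtl_alpha)
    write_tsv(res$eqtls, file.path(out_dir, "cis_eqtls.tsv"))
    cis_genes <- res$eqtls$gene[res$eqtls$cis]
    ens <- mcmc_sample_dags(t(gen$expr), cis_genes = cis_genes,
                            lambda = cfg$lambda, n_networks = cfg$n_networks,
                            n_restarts = cfg$n_restarts,
                            max_parents = cfg$max_parents,
                            seed = substream_seed(cfg$seed, "bn"))
    res$consensus <- consensus_network(ens, cfg$consensus_threshold)
    write_tsv(res$consensus$edges, file.path(out_dir, "consensus_edges.tsv"))
    res$key_drivers <- causal_regulators(res$consensus, h = cfg$h)
    write_tsv(res$key_drivers, file.path(out_dir, "key_drivers.tsv"))
  }

  # --- drugscore ------------------------------------------------------------
  if (on_stage("drugscore")) {
    dr <- study$drugs
    res$drug_scores <- score_drug_profiles(
      dr$profiles, dr$compound, dr$query_truth, n_perm = cfg$drug_n_perm,
      seed = substream_seed(cfg$seed, "drugs-score"))
    write_tsv(res$drug_scores, file.path(out_dir, "drug_scores.tsv"))
  }

  # --- pin ------------------------------------------------------------------
  if (on_stage("pin")) {
    pp <- study$ppi
    extras <- grep("^p", pp$universe, value = TRUE)
    expressed <- c(grep("^g", pp$universe, value = TRUE),
                   extras[seq_len(floor(length(extras) / 2))])
    ppi <- build_ppi(pp$edges, expressed)
    nbhd <- first_degree_neighborhood(ppi, pp$seed_protein)
    res$pin <- pin_enrichment(nbhd, list(planted_annotation = pp$annotation),
                              ppi$universe)
    res$pin_neighborhood <- nbhd
    write_tsv(res$pin, file.path(out_dir, "pin_enrichment.tsv"))
  }

  # --- manifest -------------------------------------------------------------
  files <- sort(list.files(out_dir, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  cfg_hash <- substr(
    tools::md5sum(write_tsv(
      data.frame(key = names(unlist(cfg)), value = unname(unlist(cfg))),
      file.path(out_dir, "config_resolved.tsv"))), 1, 32)
  files <- sort(unique(c(files, "config_resolved.tsv")))
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(config_hash = unname(cfg_hash), seed = cfg$seed,
                   stages = cfg$stages,
                   files = stats::setNames(as.list(unname(sums)), files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

# shuffled-consensus decoy motifs for the composite ranking
tfbs_decoy_motifs <- function(consensus, n = 2L, seed = 1L) {
  with_seed(seed, {
    out <- list()
    for (i in seq_len(n)) {
      dec <- paste(sample(strsplit(consensus, "")[[1]]), collapse = "")
      nm <- sprintf("TF_decoy%d", i)
      out[[nm]] <- motif_from_consensus(dec, name = nm)
    }
    out
  })
}

# per-gene case/control differential expression, -log10 Welch p
de_neg_log10_by_gene <- function(cohort) {
  case <- cohort$expr[, cohort$condition == "case", drop = FALSE]
  ctrl <- cohort$expr[, cohort$condition == "control", drop = FALSE]
  p <- vapply(rownames(cohort$expr), function(g)
    stats::t.test(case[g, ], ctrl[g, ])$p.value, numeric(1))
  -log10(pmax(p, .Machine$double.xmin))
}
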