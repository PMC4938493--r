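#' Configuration for the synthetic systems-genetics study
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' object.  The defaults are the package's reference study conditions: four
#' planted coexpression modules of 50 genes each among 300 genes, a 60+60
#' case/control cohort, one module gaining intra-module correlation in cases
#' (0.3 to 0.7), one losing it (0.7 to 0.3), two stable, half of the gaining
#' module differentially expressed at one standard deviation, an F2 genetic
#' cohort with a cis-eQTL-driven causal chain, one trait loaded on the gained
#' module's eigengene, compound rank profiles shifting a designated query
#' set, promoters with a planted FOXO-like motif, and a protein-interaction
#' graph with an annotated neighborhood.
#'
#' @param n_genes total number of genes (planted modules plus independent
#'   background noise genes).
#' @param module_sizes integer vector of planted module sizes; their sum must
#'   not exceed `n_genes`.
#' @param n_case,n_ctrl sample counts per condition.
#' @param intra_corr_ctrl,intra_corr_case per-module target intra-module
#'   correlations in `[0,1)` under each condition.
#' @param de_module index of the module receiving planted differential
#'   expression.
#' @param de_fraction fraction of that module made DE.
#' @param de_delta DE effect size in within-gene standard deviations.
#' @param n_f2 sample count of the genetic (F2) cohort.
#' @param n_snps number of independent SNPs genotyped in the F2 cohort.
#' @param cis_effect additive allele effect on the driver gene, expression
#'   SDs per allele.
#' @param chain_spec data frame `parent`, `child`, `coef` describing the
#'   linear structural-equation chain downstream of the driver (first parent
#'   is the driver); must be acyclic.
#' @param n_extra_genes independent genes added to the genetic cohort beyond
#'   the chain nodes.
#' @param trait_spec data frame `trait`, `module` (planted module index, NA
#'   for a pure-noise trait), `loading`, `noise_sd`.
#' @param drug_spec list with `n_genes`, `n_replicates`, `n_query` designated
#'   query genes, `shift` top/bottom rank quantile, and `compounds` data
#'   frame (`name`, `direction` in up/down/null).
#' @param motif_spec list with `consensus` (A/C/G/T string), `n_target`,
#'   `n_background`, `promoter_length`, `sites_target`, `sites_background`,
#'   `base_freq` named A/C/G/T probabilities.
#' @param ppi_spec list with `n_extra` background proteins, `neighborhood`
#'   size of the seeded hub neighborhood, `p_background` random edge density,
#'   `annot_frac_neighborhood`, `annot_frac_background`.
#' @param covariate_effect slope of a shared age covariate on expression
#'   (default 0: covariates are generated but carry no signal, so planted
#'   correlations are exact).
#' @param seed global integer seed; every generator derives a sub-stream
#'   from it via [substream_seed()].
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 300L,
                              module_sizes = c(50L, 50L, 50L, 50L),
                              n_case = 60L, n_ctrl = 60L,
                              intra_corr_ctrl = c(0.3, 0.7, 0.5, 0.5),
                              intra_corr_case = c(0.7, 0.3, 0.5, 0.5),
                              de_module = 1L, de_fraction = 0.5, de_delta = 1,
                              n_f2 = 200L, n_snps = 10L, cis_effect = 1,
                              chain_spec = data.frame(
                                parent = c("g001", "g002"),
                                child  = c("g002", "g003"),
                                coef   = c(0.8, 0.8)),
                              n_extra_genes = 5L,
                              trait_spec = data.frame(
                                trait   = c("stress_response", sprintf("null_trait%d", 1:5)),
                                module  = c(1L, rep(NA_integer_, 5)),
                                loading = c(0.7, rep(0, 5)),
                                noise_sd = c(0.7, rep(1, 5))),
                              drug_spec = list(
                                n_genes = 1000L, n_replicates = 5L,
                                n_query = 20L, shift = 0.05,
                                compounds = data.frame(
                                  name = c("cmpd_up", "cmpd_down", "cmpd_null1",
                                           "cmpd_null2", "cmpd_null3"),
                                  direction = c("up", "down", "null", "null", "null"))),
                              motif_spec = list(
                                consensus = "TTGTTTACTTTG", n_target = 50L,
                                n_background = 500L, promoter_length = 1000L,
                                sites_target = 40L, sites_background = 5L,
                                base_freq = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)),
                              ppi_spec = list(
                                n_extra = 100L, neighborhood = 30L,
                                p_background = 0.02,
                                annot_frac_neighborhood = 0.5,
                                annot_frac_background = 0.05),
                              covariate_effect = 0,
                              seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  module_sizes <- vapply(module_sizes, check_count, integer(1), name = "module_sizes")
  if (sum(module_sizes) > n_genes)
    stop("sum(module_sizes) exceeds n_genes", call. = FALSE)
  n_case <- check_count(n_case, "n_case"); n_ctrl <- check_count(n_ctrl, "n_ctrl")
  check_prob(intra_corr_ctrl, "intra_corr_ctrl", open_hi = TRUE)
  check_prob(intra_corr_case, "intra_corr_case", open_hi = TRUE)
  if (length(intra_corr_ctrl) != length(module_sizes) ||
      length(intra_corr_case) != length(module_sizes))
    stop("intra-module correlations must match the number of modules", call. = FALSE)
  check_prob(de_fraction, "de_fraction")
  stopifnot(is.data.frame(chain_spec),
            all(c("parent", "child", "coef") %in% names(chain_spec)))
  assert_acyclic_chain(chain_spec)
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(
    n_genes = n_genes, module_sizes = module_sizes,
    n_case = n_case, n_ctrl = n_ctrl,
    intra_corr_ctrl = intra_corr_ctrl, intra_corr_case = intra_corr_case,
    de_module = as.integer(de_module), de_fraction = de_fraction,
    de_delta = de_delta,
    n_f2 = check_count(n_f2, "n_f2"), n_snps = check_count(n_snps, "n_snps"),
    cis_effect = cis_effect, chain_spec = chain_spec,
    n_extra_genes = as.integer(n_extra_genes),
    trait_spec = trait_spec, drug_spec = drug_spec, motif_spec = motif_spec,
    ppi_spec = ppi_spec, covariate_effect = covariate_effect, seed = seed),
    class = "simulation_config")
}

assert_acyclic_chain <- function(chain_spec) {
  nodes <- unique(c(chain_spec$parent, chain_spec$child))
  g <- igraph::graph_from_data_frame(chain_spec[, c("parent", "child")],
                                     vertices = nodes)
  if (!igraph::is_dag(g)) stop("chain_spec contains a cycle", call. = FALSE)
  invisible(TRUE)
}

# module labels follow the classic coexpression color convention
module_color_labels <- function(k) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue", "darkred", "darkgreen", "thistle2",
            "skyblue", "white", "darkturquoise")
  if (k <= length(base)) base[seq_len(k)] else
    c(base, sprintf("module%03d", seq_len(k - length(base))))
}

#' Generate a planted-module case/control expression study
#'
#' Each planted module follows a one-factor Gaussian model per sample:
#' `x_g = sqrt(rho) * f + sqrt(1 - rho) * e`, with `rho` the configured
#' intra-module correlation for the sample's condition, so the population
#' correlation between any two module genes equals `rho` exactly.  Genes of
#' the designated DE module receive a mean shift of `de_delta` SDs in cases.
#' Background genes are independent standard normal noise.
#'
#' @param config a [simulation_config()].
#' @return list with `expr` (gene x sample matrix, conditions concatenated),
#'   `condition` factor (`control`/`case`), `covariates` data frame (age,
#'   sex), `partition_truth` named gene-to-module map ("grey" for
#'   background), `dc_truth` per-module gain/loss/stable labels, `de_truth`
#'   character vector of planted DE genes, `factor_scores` the latent module
#'   factors (true eigengene profiles), and the seed used.
#' @export
generate_case_control <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  sseed <- substream_seed(config$seed, "expression")
  with_seed(sseed, {
    nmod <- length(config$module_sizes)
    labels <- module_color_labels(nmod)
    genes <- sprintf("g%03d", seq_len(config$n_genes))
    n_tot <- config$n_case + config$n_ctrl
    samples <- c(sprintf("ctrl_%02d", seq_len(config$n_ctrl)),
                 sprintf("case_%02d", seq_len(config$n_case)))
    condition <- factor(rep(c("control", "case"), c(config$n_ctrl, config$n_case)),
                        levels = c("control", "case"))
    partition <- rep("grey", config$n_genes)
    names(partition) <- genes
    expr <- matrix(stats::rnorm(config$n_genes * n_tot), config$n_genes, n_tot,
                   dimnames = list(genes, samples))
    fs <- matrix(stats::rnorm(nmod * n_tot), n_tot, nmod,
                 dimnames = list(samples, labels))
    offset <- 0L
    for (m in seq_len(nmod)) {
      idx <- offset + seq_len(config$module_sizes[m])
      offset <- offset + config$module_sizes[m]
      partition[idx] <- labels[m]
      rho <- ifelse(condition == "case",
                    config$intra_corr_case[m], config$intra_corr_ctrl[m])
      # e is already in expr; mix in the shared factor
      expr[idx, ] <- sweep(expr[idx, , drop = FALSE], 2, sqrt(1 - rho), `*`) +
        outer(rep(1, length(idx)), sqrt(rho) * fs[, m])
    }
    if (config$covariate_effect != 0) {
      age_z <- stats::rnorm(n_tot)
    } else age_z <- stats::rnorm(n_tot)
    covariates <- data.frame(
      sample = samples,
      age = round(70 + 8 * age_z, 1),
      sex = sample(c("F", "M"), n_tot, replace = TRUE),
      row.names = samples)
    if (config$covariate_effect != 0) {
      n_aff <- max(1L, round(0.2 * config$n_genes))
      aff <- sample(config$n_genes, n_aff)
      expr[aff, ] <- expr[aff, ] +
        outer(rep(config$covariate_effect, n_aff), age_z)
    }
    de_truth <- character(0)
    if (config$de_fraction > 0) {
      mod_genes <- genes[partition == labels[config$de_module]]
      n_de <- round(config$de_fraction * length(mod_genes))
      de_truth <- sort(sample(mod_genes, n_de))
      expr[de_truth, condition == "case"] <-
        expr[de_truth, condition == "case"] + config$de_delta
    }
    dc_truth <- ifelse(config$intra_corr_case > config$intra_corr_ctrl, "gain",
                ifelse(config$intra_corr_case < config$intra_corr_ctrl, "loss",
                       "stable"))
    names(dc_truth) <- labels
    # ordinal pathological grade: controls 0, cases spread over 1..4
    grade <- ifelse(condition == "case",
                    sample(1:4, n_tot, replace = TRUE), 0L)
    names(grade) <- samples
    list(expr = expr, condition = condition, covariates = covariates,
         grade = grade, partition_truth = partition, dc_truth = dc_truth,
         de_truth = de_truth, factor_scores = fs, seed = sseed)
  })
}

#' Generate an F2 genetic cohort with a cis-eQTL-driven causal chain
#'
#' SNP genotypes are drawn independently with F2 intercross proportions
#' 1:2:1 on dosages 0/1/2.  The driver gene (first parent of `chain_spec`)
#' equals `cis_effect` times its cis SNP dosage plus unit Gaussian noise;
#' downstream genes follow the linear structural equations of `chain_spec`;
#' extra genes are independent noise.  Gene i sits at position `i * 1e7` and
#' SNP i at 1 kb from gene i, so SNP 1 is cis to the driver and the
#' remaining SNPs are cis to genes they do not influence.
#'
#' @param config a [simulation_config()].
#' @return list with `genotypes` (sample x SNP dosage matrix), `expr`
#'   (gene x sample), `gene_pos`/`snp_pos` base-pair positions,
#'   `eqtl_truth` data frame (snp, gene), `driver_truth` the driver gene id,
#'   and the seed used.
#' @export
generate_genetic_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  assert_acyclic_chain(config$chain_spec)
  sseed <- substream_seed(config$seed, "genetic")
  with_seed(sseed, {
    chain <- config$chain_spec
    nodes <- unique(c(chain$parent, chain$child))
    driver <- chain$parent[1]
    extra <- if (config$n_extra_genes > 0)
      sprintf("x%03d", seq_len(config$n_extra_genes)) else character(0)
    genes <- c(nodes, extra)
    n <- config$n_f2
    samples <- sprintf("f2_%03d", seq_len(n))
    geno <- matrix(sample(0:2, n * config$n_snps, replace = TRUE,
                          prob = c(0.25, 0.5, 0.25)),
                   n, config$n_snps,
                   dimnames = list(samples, sprintf("snp%03d", seq_len(config$n_snps))))
    expr <- matrix(stats::rnorm(length(genes) * n), length(genes), n,
                   dimnames = list(genes, samples))
    expr[driver, ] <- expr[driver, ] + config$cis_effect * geno[, 1]
    # children in topological order
    g <- igraph::graph_from_data_frame(chain[, c("parent", "child")],
                                       vertices = nodes)
    for (v in names(igraph::topo_sort(g))) {
      pa <- chain[chain$child == v, , drop = FALSE]
      if (nrow(pa) == 0) next
      expr[v, ] <- expr[v, ] +
        colSums(pa$coef * expr[pa$parent, , drop = FALSE])
    }
    gene_pos <- stats::setNames((seq_along(genes)) * 1e7, genes)
    snp_pos <- stats::setNames(
      gene_pos[pmin(seq_len(config$n_snps), length(genes))] + 1000,
      colnames(geno))
    list(genotypes = geno, expr = expr, gene_pos = gene_pos, snp_pos = snp_pos,
         eqtl_truth = data.frame(snp = "snp001", gene = driver),
         driver_truth = driver, seed = sseed)
  })
}

#' Generate replicate compound rank profiles with planted connectivity
#'
#' Every replicate of every compound is a full permutation of ranks
#' `1..G`.  For an "up" compound the designated query genes are placed
#' uniformly within the top `shift` quantile of ranks, for a "down" compound
#' within the bottom quantile; null compounds are uniform permutations.
#'
#' @param config a [simulation_config()].
#' @return list with `profiles` (gene x replicate rank matrix, replicate
#'   columns named `<compound>_r<i>`), `compound` factor per column,
#'   `query_truth` designated gene ids, `direction_truth` per compound, and
#'   the seed used.
#' @export
generate_drug_rank_profiles <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  sp <- config$drug_spec
  sseed <- substream_seed(config$seed, "drugs")
  with_seed(sseed, {
    G <- as.integer(sp$n_genes)
    genes <- sprintf("d%04d", seq_len(G))
    if (anyDuplicated(genes)) stop("duplicate gene ids in drug universe")
    query <- sort(sample(genes, sp$n_query))
    k <- max(sp$n_query, floor(sp$shift * G))
    cols <- list(); compound <- character(0)
    for (i in seq_len(nrow(sp$compounds))) {
      nm <- sp$compounds$name[i]; dir <- sp$compounds$direction[i]
      for (r in seq_len(sp$n_replicates)) {
        ranks <- stats::setNames(integer(G), genes)
        if (dir == "null") {
          ranks[] <- sample.int(G)
        } else {
          slot <- if (dir == "up") seq_len(k) else (G - k + 1):G
          qr <- sample(slot, sp$n_query)
          ranks[query] <- qr
          ranks[setdiff(genes, query)] <- sample(setdiff(seq_len(G), qr))
        }
        cols[[paste0(nm, "_r", r)]] <- ranks
        compound <- c(compound, nm)
      }
    }
    profiles <- do.call(cbind, cols)
    rownames(profiles) <- genes
    list(profiles = profiles, compound = factor(compound),
         query_truth = query,
         direction_truth = stats::setNames(sp$compounds$direction,
                                           sp$compounds$name),
         seed = sseed)
  })
}

#' Generate target/background promoters with planted motif sites
#'
#' Promoters are i.i.d. draws from the configured base composition; the
#' consensus motif (or its reverse complement, strand chosen at random) is
#' written over the sequence at a random position in a random subset of
#' promoters, one site per chosen promoter, positions and strands recorded.
#'
#' @param config a [simulation_config()].
#' @return list with `target`/`background` named character vectors of
#'   sequences, `sites` data frame (seq, start0 0-based, strand, set), the
#'   consensus, and the seed used.
#' @export
generate_motif_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  sp <- config$motif_spec
  motif <- toupper(sp$consensus)
  if (!grepl("^[ACGT]+$", motif)) stop("consensus must be over A/C/G/T")
  L <- nchar(motif)
  if (L >= sp$promoter_length) stop("motif longer than promoter")
  sseed <- substream_seed(config$seed, "motifs")
  with_seed(sseed, {
    bf <- sp$base_freq / sum(sp$base_freq)
    gen_seqs <- function(n, prefix) {
      s <- vapply(seq_len(n), function(i)
        paste(sample(names(bf), sp$promoter_length, replace = TRUE, prob = bf),
              collapse = ""), character(1))
      stats::setNames(s, sprintf("%s%03d", prefix, seq_len(n)))
    }
    target <- gen_seqs(sp$n_target, "tgt")
    background <- gen_seqs(sp$n_background, "bkg")
    rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
    plant <- function(seqs, n_sites, set) {
      if (n_sites == 0)
        return(list(seqs = seqs, sites = data.frame(
          seq = character(0), start0 = integer(0), strand = character(0),
          set = character(0))))
      if (n_sites > length(seqs))
        stop("more planted sites than promoters in set ", set)
      chosen <- sample(names(seqs), n_sites)
      rows <- vector("list", n_sites)
      for (i in seq_along(chosen)) {
        nm <- chosen[i]
        pos <- sample.int(sp$promoter_length - L + 1, 1)  # 1-based
        strand <- sample(c("+", "-"), 1)
        ins <- if (strand == "+") motif else rc(motif)
        substr(seqs[nm], pos, pos + L - 1) <- ins
        rows[[i]] <- data.frame(seq = nm, start0 = pos - 1L, strand = strand,
                                set = set)
      }
      list(seqs = seqs, sites = do.call(rbind, rows))
    }
    tg <- plant(target, sp$sites_target, "target")
    bg <- plant(background, sp$sites_background, "background")
    list(target = tg$seqs, background = bg$seqs,
         sites = rbind(tg$sites, bg$sites), consensus = motif, seed = sseed)
  })
}

#' Generate a protein-interaction graph with an annotated hub neighborhood
#'
#' A designated seed protein is wired to a dense first-degree neighborhood;
#' the rest of the universe carries sparse random background edges.  An
#' annotation set covers a configured fraction of the neighborhood and a
#' much smaller fraction of the background, giving the enrichment stage a
#' recoverable planted signal.
#'
#' @param config a [simulation_config()].
#' @param proteins optional protein universe; defaults to the expression
#'   gene ids plus `ppi_spec$n_extra` synthetic extras.
#' @return list with `edges` data frame (a, b, source), `seed_protein`,
#'   `annotation` character vector (the planted set), `universe`, and the
#'   seed used.
#' @export
generate_ppi <- function(config, proteins = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  sp <- config$ppi_spec
  sseed <- substream_seed(config$seed, "ppi")
  with_seed(sseed, {
    if (is.null(proteins))
      proteins <- c(sprintf("g%03d", seq_len(config$n_genes)),
                    sprintf("p%03d", seq_len(sp$n_extra)))
    seedp <- proteins[1]
    nb <- sample(setdiff(proteins, seedp), sp$neighborhood)
    edges <- data.frame(a = seedp, b = nb, source = "planted")
    n <- length(proteins)
    m <- round(sp$p_background * n * (n - 1) / 2)
    ia <- sample.int(n, m, replace = TRUE)
    ib <- sample.int(n, m, replace = TRUE)
    keep <- ia != ib
    bg <- unique(data.frame(
      a = proteins[pmin(ia, ib)[keep]], b = proteins[pmax(ia, ib)[keep]],
      source = "background"))
    edges <- rbind(edges, bg)
    neighborhood <- c(seedp, nb)
    outside <- setdiff(proteins, neighborhood)
    annotation <- c(
      sample(neighborhood, round(sp$annot_frac_neighborhood * length(neighborhood))),
      sample(outside, round(sp$annot_frac_background * length(outside))))
    list(edges = edges, seed_protein = seedp, annotation = sort(annotation),
         universe = proteins, seed = sseed)
  })
}

#' Generate a homologous second species for conservation testing
#'
#' Builds a second-species gene universe paired 1-to-1 with every gene of
#' the case/control study, adds a configurable fraction of extra random
#' many-to-many pairs, and carries the planted module memberships across
#' with relabelled module names.  The planted modules are therefore exactly
#' conserved up to homology noise.
#'
#' @param config a [simulation_config()].
#' @param partition_truth named gene -> module map from
#'   [generate_case_control()].
#' @param mm_fraction fraction of extra many-to-many pairs (default 0.05).
#' @return list with `homology` data frame (a = study genes, b = partner
#'   genes), `partition_b` named partner partition, and the seed used.
#' @export
generate_homologous_species <- function(config, partition_truth,
                                        mm_fraction = 0.05) {
  sseed <- substream_seed(config$seed, "homology")
  with_seed(sseed, {
    genes_a <- names(partition_truth)
    genes_b <- sub("^g", "mg", genes_a)
    hom <- data.frame(a = genes_a, b = genes_b)
    n_mm <- round(mm_fraction * length(genes_a))
    if (n_mm > 0) {
      extra <- data.frame(a = sample(genes_a, n_mm, replace = TRUE),
                          b = sample(genes_b, n_mm, replace = TRUE))
      hom <- unique(rbind(hom, extra))
    }
    partition_b <- stats::setNames(
      ifelse(partition_truth == "grey", "grey",
             paste0("ms_", partition_truth)), genes_b)
    list(homology = hom, partition_b = partition_b, seed = sseed)
  })
}

#' Generate the sample-by-trait table tied to planted module eigengenes
#'
#' Each configured trait equals `loading` times the latent factor of its
#' module (the true eigengene profile) plus Gaussian noise of the configured
#' SD; traits with `NA` module are pure noise.
#'
#' @param config a [simulation_config()].
#' @param cohort output of [generate_case_control()] (provides the latent
#'   factor scores).
#' @return data frame of samples x traits, plus attribute `trait_truth`.
#' @export
generate_traits <- function(config, cohort) {
  stopifnot(inherits(config, "simulation_config"))
  sseed <- substream_seed(config$seed, "traits")
  with_seed(sseed, {
    fs <- cohort$factor_scores
    n <- nrow(fs)
    out <- lapply(seq_len(nrow(config$trait_spec)), function(i) {
      row <- config$trait_spec[i, ]
      base <- if (is.na(row$module)) rep(0, n) else row$loading * fs[, row$module]
      base + stats::rnorm(n, sd = row$noise_sd)
    })
    tab <- as.data.frame(out, col.names = config$trait_spec$trait,
                         row.names = rownames(fs))
    attr(tab, "trait_truth") <- config$trait_spec
    tab
  })
}

#' Generate the full synthetic study
#'
#' Runs every generator off one global seed and bundles the results with
#' their planted ground truth.  Regeneration with the same config is
#' bit-identical.
#'
#' @param config a [simulation_config()].
#' @return object of class `synthetic_study`.
#' @export
generate_synthetic_study <- function(config = simulation_config()) {
  cohort <- generate_case_control(config)
  study <- list(
    config = config,
    cohort = cohort,
    genetic = generate_genetic_cohort(config),
    drugs = generate_drug_rank_profiles(config),
    motifs = generate_motif_dataset(config),
    ppi = generate_ppi(config),
    traits = generate_traits(config, cohort),
    seed = config$seed)
  class(study) <- "synthetic_study"
  study
}

#' Write a synthetic study to plain-text files
#'
#' Expression/trait/genotype TSVs (genes or SNPs in rows), GMT truth sets,
#' FASTA promoters, an edge-list TSV and a JSON truth manifest, all
#' diffable, under `dir`.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_synthetic_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- character(0)
  wtsv <- function(x, name, rowlab) {
    path <- file.path(dir, name)
    df <- data.frame(rowlab = rownames(x), x, check.names = FALSE)
    names(df)[1] <- rowlab
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  co <- study$cohort
  f <- c(f, wtsv(co$expr, "expression.tsv", "gene"))
  utils::write.table(
    data.frame(sample = colnames(co$expr), condition = as.character(co$condition),
               co$covariates[colnames(co$expr), c("age", "sex")]),
    fp <- file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  f <- c(f, fp)
  f <- c(f, wtsv(t(study$genetic$genotypes), "genotypes.tsv", "snp"))
  f <- c(f, wtsv(study$genetic$expr, "f2_expression.tsv", "gene"))
  f <- c(f, wtsv(as.matrix(study$traits), "traits.tsv", "sample"))
  f <- c(f, wtsv(study$drugs$profiles, "drug_ranks.tsv", "gene"))
  gmt <- c(paste(c("planted_de", "synthetic", co$de_truth), collapse = "\t"),
           paste(c("drug_query", "synthetic", study$drugs$query_truth), collapse = "\t"),
           paste(c("ppi_annotation", "synthetic", study$ppi$annotation), collapse = "\t"))
  writeLines(gmt, fp <- file.path(dir, "truth_sets.gmt")); f <- c(f, fp)
  write_fasta(study$motifs$target, fp <- file.path(dir, "promoters_target.fa"))
  f <- c(f, fp)
  write_fasta(study$motifs$background, fp <- file.path(dir, "promoters_background.fa"))
  f <- c(f, fp)
  utils::write.table(study$ppi$edges, fp <- file.path(dir, "ppi_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  f <- c(f, fp)
  manifest <- list(
    seed = study$seed,
    partition_truth = as.list(co$partition_truth),
    dc_truth = as.list(co$dc_truth),
    de_truth = co$de_truth,
    driver_truth = study$genetic$driver_truth,
    eqtl_truth = study$genetic$eqtl_truth,
    drug_direction_truth = as.list(study$drugs$direction_truth),
    motif_consensus = study$motifs$consensus)
  jsonlite::write_json(manifest, fp <- file.path(dir, "truth_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  f <- c(f, fp)
  invisible(f)
}

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path, width = 80L)
  invisible(path)
}
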