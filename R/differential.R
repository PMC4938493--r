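#' Intramodular connectivity
#'
#' `k_i = sum_{j in module, j != i} a_ij`: connectivity restricted to the
#' module's own genes, so genes outside the module never contribute.
#'
#' @param adj adjacency matrix (zero diagonal).
#' @param module character vector of module gene ids.
#' @return named numeric vector of per-gene connectivities.
#' @export
intramodular_connectivity <- function(adj, module) {
  if (!all(module %in% rownames(adj)))
    stop("module gene(s) absent from adjacency: ",
         paste(setdiff(module, rownames(adj)), collapse = ", "))
  if (length(module) < 2) stop("singleton module")
  sub <- adj[module, module, drop = FALSE]
  diag(sub) <- 0
  rowSums(sub)
}

#' Modular differential connectivity
#'
#' Ratio of the mean intramodular connectivity of the module's genes in the
#' case network to the same genes' mean connectivity in the control
#' network.  MDC > 1 indicates gained coexpression in cases, MDC < 1 lost.
#'
#' @param adj_case,adj_ctrl adjacency matrices over the same gene universe.
#' @param module module gene ids.
#' @return the MDC ratio (NA with a warning when the control connectivity
#'   is zero).
#' @export
mdc <- function(adj_case, adj_ctrl, module) {
  stopifnot(identical(rownames(adj_case), rownames(adj_ctrl)))
  kc <- mean(intramodular_connectivity(adj_case, module))
  k0 <- mean(intramodular_connectivity(adj_ctrl, module))
  if (k0 <= 0) {
    warning("zero control connectivity; MDC undefined")
    return(NA_real_)
  }
  kc / k0
}

#' Classify an MDC value against the significance thresholds
#'
#' `gained` requires MDC > 2 and FDR < 0.001; `lost` requires MDC < 0.5 and
#' FDR < 0.001; everything else is `conserved`.
#'
#' @param mdc_value numeric MDC.
#' @param fdr numeric FDR.
#' @return `"gained"`, `"lost"` or `"conserved"`.
#' @export
classify_mdc <- function(mdc_value, fdr) {
  ifelse(is.na(mdc_value) | is.na(fdr), NA_character_,
    ifelse(mdc_value > 2 & fdr < 0.001, "gained",
      ifelse(mdc_value < 0.5 & fdr < 0.001, "lost", "conserved")))
}

#' MDC with dual-shuffle permutation FDR
#'
#' Computes the observed MDC per module from soft adjacencies built per
#' condition, then two permutation nulls: (i) sample shuffle — condition
#' labels permuted and both networks rebuilt ("random edges"); (ii) gene
#' shuffle — module memberships permuted over the gene universe ("random
#' nodes").  For each scheme the empirical FDR of a module is the add-one
#' fraction of null MDCs at least as extreme as the observed value, one
#' sided relative to 1 in the observed direction; the final FDR is the
#' larger of the two estimates.  Adjacencies use the supplied `beta`
#' throughout (no re-selection inside the null).
#'
#' With `add_one = TRUE` the estimate is `(count + 1) / (n_perm + 1)`,
#' which never reports zero but floors the FDR at `1 / (n_perm + 1)` — at
#' moderate permutation counts that floor sits above the 0.001
#' classification threshold and no module could ever be called gained or
#' lost, so the raw `count / n_perm` estimate is the default.
#'
#' @param expr_case,expr_ctrl gene x sample matrices over the same genes.
#' @param partition module partition (grey excluded from output).
#' @param n_perm permutations per scheme (>= 20).
#' @param seed integer seed.
#' @param beta soft power.
#' @param add_one use the add-one (never-zero) FDR estimate?
#' @return data frame: module, mdc, fdr_samples, fdr_genes, fdr,
#'   classification.
#' @export
mdc_fdr <- function(expr_case, expr_ctrl, partition, n_perm = 50L, seed = 1L,
                    beta = 6L, add_one = FALSE) {
  n_perm <- check_count(n_perm, "n_perm", min = 20L)
  stopifnot(identical(rownames(expr_case), rownames(expr_ctrl)))
  genes <- rownames(expr_case)
  mods <- setdiff(sort(unique(partition)), "grey")
  mod_genes <- lapply(mods, function(mo) {
    mg <- intersect(names(partition)[partition == mo], genes)
    if (length(mg) == 0) stop("module has no overlap with gene universe: ", mo)
    mg
  })
  names(mod_genes) <- mods
  build <- function(mat) soft_adjacency(correlation_matrix(mat), beta)
  adj_case <- build(expr_case); adj_ctrl <- build(expr_ctrl)
  obs <- vapply(mod_genes, function(mg) mdc(adj_case, adj_ctrl, mg), numeric(1))
  all_expr <- cbind(expr_ctrl, expr_case)
  n_ctrl <- ncol(expr_ctrl); n_tot <- ncol(all_expr)
  with_seed(substream_seed(seed, "mdc-fdr"), {
    null_samples <- matrix(NA_real_, length(mods), n_perm,
                           dimnames = list(mods, NULL))
    for (p in seq_len(n_perm)) {
      idx <- sample.int(n_tot)
      a1 <- build(all_expr[, idx[seq_len(n_ctrl)], drop = FALSE])
      a2 <- build(all_expr[, idx[(n_ctrl + 1):n_tot], drop = FALSE])
      null_samples[, p] <- vapply(mod_genes, function(mg) mdc(a2, a1, mg),
                                  numeric(1))
    }
    null_genes <- matrix(NA_real_, length(mods), n_perm,
                         dimnames = list(mods, NULL))
    for (p in seq_len(n_perm)) {
      shuffled <- stats::setNames(sample(genes), genes)
      null_genes[, p] <- vapply(mod_genes, function(mg)
        mdc(adj_case, adj_ctrl, unname(shuffled[mg])), numeric(1))
    }
    one_sided_fdr <- function(o, null) {
      # "as extreme" on the observed side of 1
      if (is.na(o)) return(NA_real_)
      ext <- if (o >= 1) sum(null >= o, na.rm = TRUE)
             else sum(null <= o, na.rm = TRUE)
      if (add_one) (ext + 1) / (n_perm + 1) else ext / n_perm
    }
    fdr_s <- vapply(seq_along(mods), function(i)
      one_sided_fdr(obs[i], null_samples[i, ]), numeric(1))
    fdr_g <- vapply(seq_along(mods), function(i)
      one_sided_fdr(obs[i], null_genes[i, ]), numeric(1))
    fdr <- pmax(fdr_s, fdr_g)
    data.frame(module = mods, mdc = unname(obs),
               fdr_samples = fdr_s, fdr_genes = fdr_g, fdr = fdr,
               classification = classify_mdc(unname(obs), fdr),
               row.names = NULL)
  })
}

#' medianRank module preservation
#'
#' Per module: observed density (mean intramodular adjacency in the test
#' network) and connectivity preservation (correlation of intramodular
#' connectivity between reference and test networks) are ranked across
#' modules (rank 1 = best preserved, i.e. highest statistic); the
#' medianRank is the median of the two ranks.  Ties are broken
#' deterministically by module name.
#'
#' @param expr_ref,expr_test gene x sample matrices, shared genes.
#' @param partition module partition (grey excluded).
#' @param beta soft power.
#' @return data frame: module, density, connectivity, density_rank,
#'   connectivity_rank, medianRank; ordered by medianRank.
#' @export
median_rank_preservation <- function(expr_ref, expr_test, partition, beta = 6L) {
  stopifnot(identical(rownames(expr_ref), rownames(expr_test)))
  mods <- setdiff(sort(unique(partition)), "grey")
  if (length(mods) < 2) stop("need at least 2 modules")
  adj_ref <- soft_adjacency(correlation_matrix(expr_ref), beta)
  adj_test <- soft_adjacency(correlation_matrix(expr_test), beta)
  st <- t(vapply(mods, function(mo) {
    mg <- names(partition)[partition == mo]
    preservation_stats(adj_ref, adj_test, mg)
  }, c(density = 0, connectivity = 0)))
  # higher statistic = better preserved = lower rank; ties by module name
  rank_desc <- function(x) {
    o <- order(-x, mods)
    r <- integer(length(x)); r[o] <- seq_along(x); r
  }
  dr <- rank_desc(st[, "density"])
  cr <- rank_desc(st[, "connectivity"])
  out <- data.frame(module = mods, density = st[, "density"],
                    connectivity = st[, "connectivity"],
                    density_rank = dr, connectivity_rank = cr,
                    medianRank = (dr + cr) / 2, row.names = NULL)
  out[order(out$medianRank, out$module), ]
}
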