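#' Fisher exact enrichment of two gene sets over a universe
#'
#' Builds the 2x2 table (`a` = overlap, `b` = set A only, `c` = set B only,
#' `d` = neither) and reports the two-sided Fisher exact p from the
#' hypergeometric distribution, the sample odds ratio `(a d)/(b c)` and its
#' 95% asymptotic CI (log-OR +/- 1.96 SE).  A zero cell yields OR 0 or
#' infinity with a Haldane-corrected (add 0.5) CI, flagged in the output.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of the enrichment universe.
#' @param alternative `"two.sided"` (default), `"greater"`, `"less"`.
#' @return list of class `enrichment_result`: counts `a,b,c,d`,
#'   `odds_ratio`, `ci_lower`, `ci_upper`, `p`, `haldane` flag.
#' @export
fisher_enrichment <- function(set_a, set_b, universe,
                              alternative = "two.sided") {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  set_a <- intersect(unique(set_a), universe)
  set_b <- intersect(unique(set_b), universe)
  a <- length(intersect(set_a, set_b))
  b <- length(set_a) - a
  cc <- length(set_b) - a
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  haldane <- (a == 0 || b == 0 || cc == 0 || d == 0)
  or <- if (b * cc > 0) (a * d) / (b * cc)
        else if (a * d > 0) Inf else 0
  h <- if (haldane) 0.5 else 0
  se <- sqrt(1 / (a + h) + 1 / (b + h) + 1 / (cc + h) + 1 / (d + h))
  lor <- log((a + h) * (d + h) / ((b + h) * (cc + h)))
  structure(list(a = a, b = b, c = cc, d = d, odds_ratio = or,
                 ci_lower = exp(lor - 1.96 * se),
                 ci_upper = exp(lor + 1.96 * se),
                 p = min(p, 1), haldane = haldane,
                 alternative = alternative),
            class = "enrichment_result")
}

#' Enrichment of every module for every signature
#'
#' @param partition module partition (grey included as its own set).
#' @param signatures named list of gene sets.
#' @param universe enrichment universe; defaults to the partition's genes.
#' @param method multiple-testing method applied across the whole table.
#' @return data frame: module, signature, a..d, odds_ratio, p, p_adjusted.
#' @export
module_signature_enrichment <- function(partition, signatures,
                                        universe = names(partition),
                                        method = "bonferroni") {
  mods <- sort(unique(partition))
  rows <- list()
  for (mo in mods) {
    mg <- names(partition)[partition == mo]
    for (sg in names(signatures)) {
      er <- fisher_enrichment(mg, signatures[[sg]], universe)
      rows[[length(rows) + 1]] <- data.frame(
        module = mo, signature = sg, a = er$a, b = er$b, c = er$c, d = er$d,
        odds_ratio = er$odds_ratio, p = er$p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_p(out$p, if (method == "bonferroni") "bonferroni" else "bh")
  out
}

#' Composite module ranking by differential connectivity and DE enrichment
#'
#' Each criterion contributes a 0/1 flag per module: the MDC flag is 1 when
#' the module is classified gained or lost; each signature flag is 1 when
#' the module's Bonferroni-adjusted enrichment p is below 0.05.  Modules are
#' ranked by descending flag count, ties broken by the minimum enrichment p,
#' then by module name.
#'
#' @param mdc_table output of [mdc_fdr()].
#' @param enrichment_table output of [module_signature_enrichment()] with
#'   Bonferroni adjustment.
#' @return data frame: module, mdc_flag, per-signature flags,
#'   criteria_count, min_p, rank; ordered by rank.
#' @export
rank_modules <- function(mdc_table, enrichment_table) {
  mods <- mdc_table$module
  mdc_flag <- as.integer(mdc_table$classification %in% c("gained", "lost"))
  sigs <- unique(enrichment_table$signature)
  flags <- sapply(sigs, function(sg) {
    sub <- enrichment_table[enrichment_table$signature == sg, ]
    as.integer(sub$p_adjusted[match(mods, sub$module)] < 0.05)
  })
  flags <- matrix(flags, nrow = length(mods),
                  dimnames = list(mods, paste0("flag_", sigs)))
  minp <- vapply(mods, function(mo)
    min(enrichment_table$p[enrichment_table$module == mo], 1), numeric(1))
  count <- mdc_flag + rowSums(flags)
  ord <- order(-count, minp, mods)
  out <- data.frame(module = mods, mdc_flag = mdc_flag, flags,
                    criteria_count = count, min_p = minp,
                    check.names = FALSE, row.names = NULL)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Expand a gene set through a many-to-many homology map
#'
#' Keeps every pair: each gene maps to all of its partners, so a 1-to-1
#' pair is never dropped and an n-to-m group expands to all n x m pairs.
#'
#' @param genes character vector on side `from`.
#' @param homology data frame with columns `a` (species 1) and `b`
#'   (species 2).
#' @param from `"a"` or `"b"`: which side `genes` live on.
#' @return character vector of partner genes on the other side.
#' @export
expand_homology <- function(genes, homology, from = "a") {
  to <- if (from == "a") "b" else "a"
  unique(homology[[to]][homology[[from]] %in% genes])
}

#' Cross-species module conservation
#'
#' Every species-A module is mapped through homology ("all possible pairs"
#' kept) and tested by Fisher's exact test against every species-B module
#' over the shared universe (genes with at least one homology pair present
#' in both partitions).  p-values are Bonferroni-corrected over all
#' module-module comparisons; a pair is conserved when the adjusted p is
#' below 0.05 and the odds ratio exceeds 2.
#'
#' @param partition_a,partition_b module partitions of the two species.
#' @param homology homology data frame (`a` = species of `partition_a`).
#' @param include_grey test grey modules too?
#' @return data frame: module_a, module_b, overlap, odds_ratio, p,
#'   p_bonferroni, conserved.
#' @export
map_modules_across_species <- function(partition_a, partition_b, homology,
                                       include_grey = FALSE) {
  genes_a <- names(partition_a); genes_b <- names(partition_b)
  mapped_a <- genes_a[genes_a %in% homology$a &
                        vapply(genes_a, function(g) any(
                          homology$b[homology$a == g] %in% genes_b), logical(1))]
  # universe on species-B side: genes with >=1 pair present on both sides
  universe_b <- intersect(genes_b, homology$b[homology$a %in% genes_a])
  if (length(universe_b) == 0) stop("empty shared universe")
  mods_a <- sort(unique(partition_a)); mods_b <- sort(unique(partition_b))
  if (!include_grey) {
    mods_a <- setdiff(mods_a, "grey"); mods_b <- setdiff(mods_b, "grey")
  }
  rows <- list()
  for (ma in mods_a) {
    ga <- names(partition_a)[partition_a == ma]
    ga_b <- expand_homology(ga, homology, from = "a")
    for (mb in mods_b) {
      gb <- names(partition_b)[partition_b == mb]
      er <- fisher_enrichment(ga_b, gb, universe_b)
      rows[[length(rows) + 1]] <- data.frame(
        module_a = ma, module_b = mb, overlap = er$a,
        odds_ratio = er$odds_ratio, p = er$p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- adjust_p(out$p, "bonferroni")
  out$conserved <- out$p_bonferroni < 0.05 & out$odds_ratio > 2
  out
}

#' Median expression per module and the grey-vs-assigned audit
#'
#' Per-gene median expression is summarized per module, with decile
#' annotations of each module's median against the all-gene distribution,
#' and the grey (unassigned) genes are compared against all assigned genes
#' by a two-sample Kolmogorov-Smirnov test — lowly expressed genes are
#' expected to fail to cluster, so grey should sit low.
#'
#' @param study expression study or matrix.
#' @param partition module partition including grey.
#' @return list: `module_medians` data frame (module, n, median, decile),
#'   `ks` htest or NULL (grey empty), `gene_medians`.
#' @export
compare_module_expression <- function(study, partition) {
  mat <- if (inherits(study, "expression_study")) study$expr else study
  gm <- apply(mat, 1, stats::median)
  mods <- sort(unique(partition))
  md <- vapply(mods, function(mo) stats::median(gm[names(partition)[partition == mo]]),
               numeric(1))
  dec <- findInterval(md, stats::quantile(gm, probs = seq(0.1, 0.9, 0.1))) + 1L
  tab <- data.frame(module = mods,
                    n = as.integer(table(partition)[mods]),
                    median = md, decile = dec, row.names = NULL)
  grey <- gm[names(partition)[partition == "grey"]]
  assigned <- gm[names(partition)[partition != "grey"]]
  ks <- NULL
  if (length(grey) == 0) {
    message("grey module empty; KS audit skipped")
  } else {
    ks <- suppressWarnings(stats::ks.test(grey, assigned))
  }
  list(module_medians = tab, ks = ks, gene_medians = gm)
}
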