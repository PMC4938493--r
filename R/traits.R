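#' Module eigengene to trait correlations
#'
#' Pearson (or Spearman) correlation and p-value per module x trait over
#' pairwise-complete samples, BH FDR computed jointly across the full
#' matrix.  A module-trait association is flagged significant when both
#' p < 0.05 and FDR < 0.05.  Traits with fewer than 5 complete values are
#' skipped with a warning.
#'
#' @param eigengenes sample x module matrix (see [module_eigengenes()]).
#' @param trait_table data frame or matrix of samples x traits; NA allowed.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data frame: module, trait, n, r, p, fdr, significant.
#' @export
module_trait_correlations <- function(eigengenes, trait_table,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  tt <- as.data.frame(trait_table)
  common <- intersect(rownames(eigengenes), rownames(tt))
  if (length(common) == 0) stop("no shared samples")
  eg <- eigengenes[common, , drop = FALSE]
  tt <- tt[common, , drop = FALSE]
  keep <- vapply(tt, function(x) sum(!is.na(x)) >= 5, logical(1))
  if (any(!keep))
    warning("trait(s) with <5 complete values skipped: ",
            paste(names(tt)[!keep], collapse = ", "))
  tt <- tt[, keep, drop = FALSE]
  rows <- list()
  for (mo in colnames(eg)) for (tr in names(tt)) {
    ok <- !is.na(tt[[tr]])
    ct <- suppressWarnings(
      stats::cor.test(eg[ok, mo], tt[[tr]][ok], method = method))
    rows[[length(rows) + 1]] <- data.frame(
      module = mo, trait = tr, n = sum(ok),
      r = unname(ct$estimate), p = ct$p.value)
  }
  out <- do.call(rbind, rows)
  out$fdr <- adjust_p(out$p, "bh")
  out$significant <- out$p < 0.05 & out$fdr < 0.05
  out
}

#' Rank modules by their number of significant trait associations
#'
#' Modules are sorted by descending count of significant associations (ties
#' by module name).  Among significant associations, those whose
#' `-log10(p)` falls in the top quartile of all significant associations
#' are flagged `top_quartile`.
#'
#' @param association_table output of [module_trait_correlations()].
#' @return list: `ranking` data frame (module, n_significant, rank) and
#'   `associations` the input with a `top_quartile` flag.
#' @export
rank_modules_by_traits <- function(association_table) {
  if (nrow(association_table) == 0) stop("empty association table")
  at <- association_table
  counts <- tapply(at$significant, at$module, sum)
  mods <- names(counts)
  ord <- order(-as.integer(counts), mods)
  ranking <- data.frame(module = mods[ord],
                        n_significant = as.integer(counts)[ord],
                        rank = seq_along(mods), row.names = NULL)
  at$top_quartile <- FALSE
  sig <- which(at$significant)
  if (length(sig) > 0) {
    strength <- -log10(pmax(at$p[sig], .Machine$double.xmin))
    thr <- stats::quantile(strength, 0.75)
    at$top_quartile[sig] <- strength >= thr
  }
  list(ranking = ranking, associations = at)
}

#' Associate an eigengene with an ordinal grade by Kruskal-Wallis
#'
#' Tie-corrected Kruskal-Wallis with the chi-square approximation; for
#' total n of at most 10 the p-value is computed by exhaustive enumeration
#' of all assignments of values to groups instead.  A constant eigengene
#' (all ties, H = 0) reports p = 1.
#'
#' @param eigengene numeric sample vector.
#' @param grade ordinal grade per sample (factor or numeric).
#' @return list: `H`, `p`, `neg_log10_p`, `method`.
#' @export
grade_association <- function(eigengene, grade) {
  grade <- as.factor(grade)
  if (nlevels(droplevels(grade)) < 2) stop("need at least 2 grade levels")
  if (any(table(grade) < 2)) stop("each grade level needs >= 2 samples")
  if (stats::sd(eigengene) == 0)
    return(list(H = 0, p = 1, neg_log10_p = 0, method = "degenerate"))
  n <- length(eigengene)
  if (n <= 10) {
    H_obs <- kw_statistic(eigengene, grade)
    perms <- all_group_assignments(as.integer(grade))
    H_null <- vapply(perms, function(g)
      kw_statistic(eigengene, factor(g)), numeric(1))
    p <- mean(H_null >= H_obs - 1e-12)
    return(list(H = H_obs, p = p, neg_log10_p = -log10(p), method = "exact"))
  }
  kt <- stats::kruskal.test(eigengene, grade)
  p <- kt$p.value
  list(H = unname(kt$statistic), p = p, neg_log10_p = -log10(p),
       method = "chisq")
}

# tie-corrected Kruskal-Wallis H
kw_statistic <- function(x, g) {
  n <- length(x)
  r <- rank(x)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(x)
  cf <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H / cf
}

# all distinct assignments of n values into groups with the given sizes
all_group_assignments <- function(g) {
  n <- length(g)
  lv <- sort(unique(g))
  out <- list()
  # choose positions for each level in turn
  build <- function(avail, levels_left, assignment) {
    if (length(levels_left) == 0) {
      out[[length(out) + 1]] <<- assignment
      return()
    }
    lev <- levels_left[1]
    size <- sum(g == lev)
    if (length(levels_left) == 1) {
      assignment[avail] <- lev
      out[[length(out) + 1]] <<- assignment
      return()
    }
    for (cm in utils::combn(avail, size, simplify = FALSE)) {
      a2 <- assignment
      a2[cm] <- lev
      build(setdiff(avail, cm), levels_left[-1], a2)
    }
  }
  build(seq_len(n), lv, integer(n))
  out
}
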