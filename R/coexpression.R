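#' Pairwise Pearson correlation matrix of genes
#'
#' @param study an `expression_study` or gene x sample matrix.
#' @return symmetric gene x gene correlation matrix, unit diagonal.
#' @export
correlation_matrix <- function(study) {
  mat <- if (inherits(study, "expression_study")) study$expr else study
  if (ncol(mat) < 3) stop("need at least 3 samples")
  v <- apply(mat, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(rownames(mat)[v == 0], collapse = ", "))
  r <- stats::cor(t(mat))
  diag(r) <- 1
  r
}

#' Soft-threshold adjacency
#'
#' Unsigned weighted network: `a_ij = |r_ij|^beta` off-diagonal; the
#' diagonal is stored as 0 so connectivity sums exclude self-edges.
#'
#' @param corr correlation matrix.
#' @param beta positive integer soft power.
#' @return adjacency matrix in `[0,1]` with attribute `beta`.
#' @export
soft_adjacency <- function(corr, beta = 6L) {
  if (!is.numeric(beta) || length(beta) != 1 || beta < 1 || beta != floor(beta))
    stop("beta must be an integer >= 1")
  a <- abs(corr)^beta
  diag(a) <- 0
  attr(a, "beta") <- as.integer(beta)
  a
}

# scale-free fit R^2: log10(freq) ~ log10(mean k) over degree bins
scale_free_r2 <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(0)
  cuts <- cut(k, breaks = n_bins)
  freq <- tapply(k, cuts, length)
  mk <- tapply(k, cuts, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(0)
  fit <- stats::lm(log10(freq[keep]) ~ log10(mk[keep]))
  summary(fit)$r.squared
}

#' Choose the soft power by scale-free topology fit
#'
#' Returns the smallest candidate `beta` whose degree distribution attains a
#' log-log scale-free fit R^2 of at least `r2_target`; if none qualifies the
#' conventional default 6 is returned with a warning.
#'
#' @param corr correlation matrix.
#' @param grid candidate integer powers.
#' @param r2_target required fit R^2.
#' @return integer beta with attribute `fit_table` (beta, r2).
#' @export
pick_beta <- function(corr, grid = 1:20, r2_target = 0.8) {
  if (length(grid) == 0) stop("empty beta grid")
  r2 <- vapply(grid, function(b) {
    a <- soft_adjacency(corr, b)
    scale_free_r2(rowSums(a))
  }, numeric(1))
  tab <- data.frame(beta = grid, r2 = r2)
  ok <- which(r2 >= r2_target)
  if (length(ok) == 0) {
    warning("no beta reached the scale-free target R^2 = ", r2_target,
            "; falling back to 6")
    beta <- 6L
  } else beta <- as.integer(grid[min(ok)])
  attr(beta, "fit_table") <- tab
  beta
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, with `k_i` the connectivity `sum_u a_iu`; `TOM_ii = 1`.
#'
#' @param adj adjacency matrix (zero diagonal).
#' @return TOM matrix in `[0,1]`, unit diagonal.
#' @export
topological_overlap <- function(adj) {
  a <- unclass(adj)
  diag(a) <- 0
  num <- a %*% a + a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- num / denom
  diag(tom) <- 1
  attributes(tom) <- list(dim = dim(a), dimnames = dimnames(a))
  tom
}

# --- adaptive dendrogram branch cutting -------------------------------------
#
# Top-down variant of dynamic branch cutting on the average-linkage tree of
# 1 - TOM.  Merges above the cut height (h5 + 0.99 (hmax - h5), with h5 the
# 5th percentile of joining heights) are severed; each remaining branch is
# accepted as a module when it is cohesive (mean within-branch
# dissimilarity, the "core scatter", below a ceiling) and separated (gap
# between its attachment height and its scatter above a floor); otherwise
# its children are examined.  An accepted branch is split further only if
# both children independently qualify.  Scatter and gap are normalized to
# the [h5, cut height] range so the criterion adapts to the dendrogram's
# scale; deep_split in 0..4 maps to progressively permissive scatter
# ceilings, as in the classic dynamic-cut parameterization.
deep_split_params <- function(deep_split) {
  if (!deep_split %in% 0:4) stop("deep_split must be in 0..4")
  max_scatter <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1]
  list(max_scatter = max_scatter, min_gap = (1 - max_scatter) * 3 / 4)
}

#' Detect coexpression modules by adaptive branch cutting
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' with branches cut top-down by a cohesion/separation criterion (see
#' Details in the package vignette).  Clusters smaller than `min_size`, and
#' genes on branches that never qualify, are assigned the reserved label
#' `"grey"`.  Module labels are colors ordered by module size.
#'
#' @param tom TOM (or any similarity in `[0,1]` with unit diagonal).
#' @param min_size minimum module size (>= 2).
#' @param deep_split split aggressiveness, 0 (conservative) to 4.
#' @return named character vector gene -> module label (class
#'   `module_partition`), with attribute `dendrogram` (the hclust object).
#' @export
detect_modules <- function(tom, min_size = 30L, deep_split = 2L) {
  min_size <- check_count(min_size, "min_size", min = 2L)
  par <- deep_split_params(deep_split)
  d <- 1 - tom
  diag(d) <- 0
  genes <- rownames(tom)
  n <- length(genes)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  # bottom-up pass: per internal node, member count and sum of within pairs.
  # For average linkage, the cross-pair dissimilarity sum of a merge equals
  # height * |L| * |R|.
  m <- nrow(hc$merge)
  size <- numeric(m); dsum <- numeric(m)
  members <- vector("list", m)
  node_info <- function(id) {
    if (id < 0) list(size = 1, dsum = 0) else
      list(size = size[id], dsum = dsum[id])
  }
  for (i in seq_len(m)) {
    l <- node_info(hc$merge[i, 1]); r <- node_info(hc$merge[i, 2])
    size[i] <- l$size + r$size
    dsum[i] <- l$dsum + r$dsum + hc$height[i] * l$size * r$size
  }
  scatter <- ifelse(size > 1, dsum / (size * (size - 1) / 2), 0)
  h5 <- stats::quantile(hc$height, 0.05, names = FALSE)
  hmax <- max(hc$height)
  cut_h <- h5 + 0.99 * (hmax - h5)
  span <- max(cut_h - h5, 1e-12)
  norm_h <- function(x) (x - h5) / span
  for (i in seq_len(m)) {  # children precede parents in hclust merge order
    l <- hc$merge[i, 1]; r <- hc$merge[i, 2]
    members[[i]] <- c(if (l < 0) -l else members[[l]],
                      if (r < 0) -r else members[[r]])
  }
  node_members <- function(id) if (id < 0) -id else members[[id]]
  qualifies <- function(id, attach_h) {
    if (id < 0) return(FALSE)
    if (size[id] < min_size) return(FALSE)
    (norm_h(scatter[id]) <= par$max_scatter) &&
      (norm_h(attach_h) - norm_h(scatter[id]) >= par$min_gap)
  }
  labels <- rep(NA_integer_, n)
  next_label <- 0L
  assign_module <- function(idx) {
    next_label <<- next_label + 1L
    labels[idx] <<- next_label
  }
  # iterative top-down walk (explicit stack; dendrograms can be deep)
  stack <- list(list(id = m, attach = max(hmax, cut_h)))
  while (length(stack) > 0) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    id <- fr$id
    if (id < 0) next
    l <- hc$merge[id, 1]; r <- hc$merge[id, 2]
    h <- hc$height[id]
    if (h > cut_h) {  # severed merge: children are separate candidates
      stack <- c(stack, list(list(id = l, attach = h),
                             list(id = r, attach = h)))
      next
    }
    if (qualifies(id, fr$attach)) {
      if (qualifies(l, h) && qualifies(r, h)) {
        stack <- c(stack, list(list(id = l, attach = h),
                               list(id = r, attach = h)))
      } else assign_module(node_members(id))
    } else {
      stack <- c(stack, list(list(id = l, attach = h),
                             list(id = r, attach = h)))
    }
  }
  out <- rep("grey", n)
  if (next_label > 0) {
    sizes <- table(factor(labels, levels = seq_len(next_label)))
    ord <- order(-as.integer(sizes))
    colors <- module_color_labels(next_label)
    remap <- character(next_label)
    remap[ord] <- colors
    out[!is.na(labels)] <- remap[labels[!is.na(labels)]]
  }
  names(out) <- genes
  structure(out, class = "module_partition", dendrogram = hc)
}

#' Module eigengene
#'
#' First principal component of the standardized module submatrix
#' (genes scaled to zero mean, unit variance across samples), reported as a
#' unit-norm sample-length vector with its sign fixed so that its
#' correlation with the module's mean expression profile is non-negative.
#'
#' @param study an `expression_study` or matrix.
#' @param partition a gene -> module map.
#' @param module module label.
#' @return list of class `module_eigengene`: `module`, `eigengene`,
#'   `variance_explained`.
#' @export
module_eigengene <- function(study, partition, module) {
  mat <- if (inherits(study, "expression_study")) study$expr else study
  genes <- names(partition)[partition == module]
  if (length(genes) == 0) stop("module not in partition: ", module)
  sub <- mat[genes, , drop = FALSE]
  sub <- t(scale(t(sub)))
  sv <- svd(sub, nu = 0, nv = 1)
  eg <- drop(sv$v)
  ve <- sv$d[1]^2 / sum(sv$d^2)
  mean_prof <- colMeans(sub)
  if (stats::sd(mean_prof) > 0 && stats::cor(eg, mean_prof) < 0) eg <- -eg
  names(eg) <- colnames(mat)
  structure(list(module = module, eigengene = eg, variance_explained = ve),
            class = "module_eigengene")
}

#' Eigengenes for every non-grey module
#' @param study expression study or matrix.
#' @param partition module partition.
#' @param include_grey include the grey pseudo-module?
#' @return sample x module matrix of eigengenes, attribute
#'   `variance_explained`.
#' @export
module_eigengenes <- function(study, partition, include_grey = FALSE) {
  mods <- sort(unique(partition))
  if (!include_grey) mods <- setdiff(mods, "grey")
  mat <- if (inherits(study, "expression_study")) study$expr else study
  if (length(mods) == 0)
    return(structure(matrix(0, ncol(mat), 0,
                            dimnames = list(colnames(mat), NULL)),
                     variance_explained = numeric(0)))
  egs <- lapply(mods, function(mo) module_eigengene(study, partition, mo))
  out <- vapply(egs, `[[`, numeric(length(egs[[1]]$eigengene)), "eigengene")
  colnames(out) <- mods
  attr(out, "variance_explained") <-
    stats::setNames(vapply(egs, `[[`, numeric(1), "variance_explained"), mods)
  out
}

# preservation statistics of one module between a reference and test half:
# density (mean intramodular adjacency in test) and connectivity
# preservation (correlation of intramodular connectivity ref vs test)
preservation_stats <- function(adj_ref, adj_test, genes) {
  at <- adj_test[genes, genes, drop = FALSE]
  ar <- adj_ref[genes, genes, drop = FALSE]
  kd <- length(genes) - 1
  dens <- sum(at) / (length(genes) * kd)
  kr <- rowSums(ar); kt <- rowSums(at)
  conn <- if (stats::sd(kr) > 0 && stats::sd(kt) > 0) stats::cor(kr, kt) else 0
  c(density = dens, connectivity = conn)
}

#' Module robustness by repeated sample splitting
#'
#' For each of `n_splits` random half-splits of the samples, soft adjacency
#' is built on each half and every module's preservation statistics (test
#' density; train/test intramodular-connectivity correlation) are compared
#' against `n_label_perm` random gene sets of the same size.  Each
#' statistic's Z is `(observed - null mean) / null SD`; a module's split
#' score is the median over statistics, and the final Z averages over
#' splits.  Categories: `weak` (Z < 2), `moderate` (2 <= Z <= 10), `strong`
#' (Z > 10).
#'
#' @param study expression study or matrix.
#' @param partition module partition.
#' @param n_splits number of half-splits (>= 10).
#' @param seed integer seed.
#' @param beta soft power for the half networks.
#' @param n_label_perm random gene-label sets per split.
#' @return data frame: module, Z, category.
#' @export
module_robustness <- function(study, partition, n_splits = 20L, seed = 1L,
                              beta = 6L, n_label_perm = 50L) {
  mat <- if (inherits(study, "expression_study")) study$expr else study
  if (ncol(mat) < 8) stop("need at least 8 samples")
  n_splits <- check_count(n_splits, "n_splits", min = 10L)
  mods <- setdiff(sort(unique(partition)), "grey")
  sizes <- vapply(mods, function(mo) sum(partition == mo), integer(1))
  small <- sizes < 3
  if (any(small)) {
    warning("skipping module(s) smaller than 3: ",
            paste(mods[small], collapse = ", "))
    mods <- mods[!small]
  }
  if (length(mods) == 0)
    return(data.frame(module = character(0), Z = numeric(0),
                      category = character(0)))
  genes <- rownames(mat)
  with_seed(substream_seed(seed, "robustness"), {
    zmat <- matrix(0, length(mods), n_splits)
    for (s in seq_len(n_splits)) {
      idx <- sample(ncol(mat), floor(ncol(mat) / 2))
      adj_tr <- soft_adjacency(correlation_matrix(mat[, idx, drop = FALSE]), beta)
      adj_te <- soft_adjacency(correlation_matrix(mat[, -idx, drop = FALSE]), beta)
      for (mi in seq_along(mods)) {
        mg <- names(partition)[partition == mods[mi]]
        obs <- preservation_stats(adj_tr, adj_te, mg)
        # null gene sets exclude the evaluated module itself, so that a
        # genuinely preserved module cannot contaminate its own reference
        pool <- setdiff(genes, mg)
        if (length(pool) < length(mg)) pool <- genes
        null <- replicate(n_label_perm, preservation_stats(
          adj_tr, adj_te, sample(pool, length(mg))))
        mu <- rowMeans(null); sdv <- apply(null, 1, stats::sd)
        z <- (obs - mu) / pmax(sdv, 1e-12)
        zmat[mi, s] <- stats::median(z)
      }
    }
    Z <- rowMeans(zmat)
    data.frame(module = mods, Z = Z,
               category = robustness_category(Z),
               row.names = NULL)
  })
}

#' Robustness category from a quality Z score
#'
#' `weak` below 2, `moderate` between 2 and 10, `strong` above 10.
#'
#' @param Z numeric vector of quality scores.
#' @return character vector of categories.
#' @export
robustness_category <- function(Z) {
  ifelse(Z < 2, "weak", ifelse(Z > 10, "strong", "moderate"))
}
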