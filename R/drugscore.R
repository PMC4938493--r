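#' Merge replicate rankings into a prototype ranked list
#'
#' Borda aggregation: the mean rank of each gene over the replicates is
#' re-ranked into a full permutation of `1..G`, ties broken by gene id.
#'
#' @param replicates gene x replicate matrix of ranks (each column a
#'   permutation of `1..G` over the same gene universe).
#' @return named integer vector: gene -> prototype rank.
#' @export
merge_prototype_ranked_lists <- function(replicates) {
  replicates <- as.matrix(replicates)
  G <- nrow(replicates)
  if (is.null(rownames(replicates))) stop("replicates need gene ids")
  if (anyNA(replicates)) stop("replicate with missing genes rejected")
  for (j in seq_len(ncol(replicates)))
    if (!setequal(replicates[, j], seq_len(G)))
      stop("replicate column ", j, " is not a permutation of 1..G")
  mean_rank <- rowMeans(replicates)
  ord <- order(mean_rank, rownames(replicates))
  prl <- integer(G)
  prl[ord] <- seq_len(G)
  names(prl) <- rownames(replicates)
  prl
}

#' Modified KS connectivity score of a query set against a ranked list
#'
#' With the sorted query positions `V(1) < ... < V(t)` in a list of length
#' `n`: `a = max_j (j/t - V(j)/n)`, `b = max_j (V(j)/n - (j-1)/t)`; the
#' score is `a` if `a > b`, else `-b`.  Positive scores mean the query
#' concentrates at the top of the list.
#'
#' @param prl named rank vector (gene -> rank, a permutation of `1..n`).
#' @param query_set character vector of query genes, a proper non-empty
#'   subset of the universe.
#' @return the signed KS score in `[-1, 1]`.
#' @export
ks_connectivity_score <- function(prl, query_set) {
  query_set <- unique(query_set)
  if (length(query_set) == 0) stop("empty query")
  if (!all(query_set %in% names(prl)))
    stop("query gene(s) outside universe: ",
         paste(setdiff(query_set, names(prl)), collapse = ", "))
  n <- length(prl)
  t <- length(query_set)
  if (t >= n) stop("query must be a proper subset of the universe")
  V <- sort(unname(prl[query_set]))
  j <- seq_len(t)
  a <- max(j / t - V / n)
  b <- max(V / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Permutation significance of KS connectivity scores
#'
#' For each compound's prototype ranked list the null is the KS score of
#' random queries of the observed size; the two-sided empirical p is the
#' add-one fraction of null `|KS|` at least as large as the observed
#' `|KS|`, and q-values are BH across compounds.
#'
#' @param prls named list of prototype rank vectors, one per compound.
#' @param query_set character query gene set.
#' @param n_perm permutations (>= 100).
#' @param seed integer seed.
#' @return data frame of class in spirit of a drug score table: compound,
#'   ks, p_empirical, q_bh, n_perm.
#' @export
permutation_significance <- function(prls, query_set, n_perm = 1000L,
                                     seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  obs <- vapply(prls, ks_connectivity_score, numeric(1),
                query_set = query_set)
  with_seed(substream_seed(seed, "drug-perm"), {
    p <- vapply(seq_along(prls), function(ci) {
      prl <- prls[[ci]]
      genes <- names(prl)
      t <- length(unique(query_set))
      null <- vapply(seq_len(n_perm), function(b)
        ks_connectivity_score(prl, sample(genes, t)), numeric(1))
      (1 + sum(abs(null) >= abs(obs[ci]))) / (n_perm + 1)
    }, numeric(1))
    data.frame(compound = names(prls), ks = unname(obs), p_empirical = p,
               q_bh = adjust_p(p, "bh"), n_perm = n_perm, row.names = NULL)
  })
}

#' Score compounds from replicate rank profiles
#'
#' Convenience wrapper: merges each compound's replicates into a prototype
#' ranked list, then runs [permutation_significance()].
#'
#' @param profiles gene x replicate rank matrix.
#' @param compound factor/character assigning columns to compounds.
#' @param query_set query gene set.
#' @param n_perm,seed permutation controls.
#' @return the drug-score data frame, plus attribute `prls`.
#' @export
score_drug_profiles <- function(profiles, compound, query_set,
                                n_perm = 1000L, seed = 1L) {
  compound <- as.character(compound)
  prls <- lapply(split(seq_len(ncol(profiles)), compound), function(idx)
    merge_prototype_ranked_lists(profiles[, idx, drop = FALSE]))
  out <- permutation_significance(prls, query_set, n_perm = n_perm, seed = seed)
  attr(out, "prls") <- prls
  out
}
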