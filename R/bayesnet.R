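#' Detect cis-eQTLs
#'
#' For every gene, the best SNP within `window` bp (closed interval) is
#' chosen by the smallest linear-regression p-value of expression on allele
#' dosage; rows with p at most `alpha` are flagged cis.  Genes with no SNP
#' in the window are omitted.
#'
#' @param expr gene x sample matrix.
#' @param genotypes sample x SNP dosage matrix (0/1/2).
#' @param gene_pos,snp_pos named base-pair positions.
#' @param window cis window in bp.
#' @param alpha significance level for the cis flag.
#' @return data frame: gene, snp, beta, p, cis.
#' @export
detect_cis_eqtls <- function(expr, genotypes, gene_pos, snp_pos,
                             window = 1e6, alpha = 1e-3) {
  samples <- intersect(colnames(expr), rownames(genotypes))
  if (length(samples) < 4) stop("too few shared samples")
  expr <- expr[, samples, drop = FALSE]
  genotypes <- genotypes[samples, , drop = FALSE]
  rows <- list()
  for (g in rownames(expr)) {
    if (!g %in% names(gene_pos)) next
    near <- names(snp_pos)[abs(snp_pos - gene_pos[g]) <= window]
    near <- intersect(near, colnames(genotypes))
    if (length(near) == 0) next
    best <- NULL
    for (s in near) {
      dose <- genotypes[, s]
      if (stats::var(dose) == 0) next
      fit <- stats::summary.lm(stats::lm(expr[g, ] ~ dose))
      p <- fit$coefficients["dose", "Pr(>|t|)"]
      if (is.null(best) || p < best$p)
        best <- list(snp = s, beta = fit$coefficients["dose", "Estimate"], p = p)
    }
    if (is.null(best)) next
    rows[[length(rows) + 1]] <- data.frame(
      gene = g, snp = best$snp, beta = best$beta, p = best$p,
      cis = best$p <= alpha)
  }
  if (length(rows) == 0)
    return(data.frame(gene = character(0), snp = character(0),
                      beta = numeric(0), p = numeric(0), cis = logical(0)))
  do.call(rbind, rows)
}

# --- BIC-scored DAG machinery ----------------------------------------------
# Data is centered once; per-node Gaussian regression terms are computed
# from the precomputed crossproduct matrix, so score deltas cost O(p^3)
# with p <= max_parents, independent of the sample count.

make_bic_env <- function(data) {
  X <- scale(data, center = TRUE, scale = FALSE)
  n <- nrow(X)
  C <- crossprod(X)  # p x p, centered
  list(C = C, n = n, vars = colnames(data), p = ncol(data))
}

# Gaussian log-likelihood + BIC penalty of one node given parent index set
node_bic <- function(env, node, parents) {
  n <- env$n
  syy <- env$C[node, node]
  rss <- if (length(parents) == 0) syy else {
    Sxy <- env$C[parents, node]
    Sxx <- env$C[parents, parents, drop = FALSE]
    syy - drop(crossprod(Sxy, solve(Sxx, Sxy)))
  }
  rss <- max(rss, 1e-300)
  sigma2 <- rss / n
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  k <- length(parents) + 2  # coefficients + intercept + variance
  ll - k / 2 * log(n)
}

#' BIC score of a DAG
#'
#' Sum over nodes of the Gaussian linear-regression log-likelihood of the
#' node on its parents minus a `(k/2) log(n)` penalty with
#' `k = parents + 2`.  The score decomposes over nodes.
#'
#' @param dag adjacency: named list `child -> character vector of parents`,
#'   or a binary parent matrix (`[i, j] = 1` for edge i -> j).
#' @param data sample x gene matrix.
#' @return the total BIC-penalized log-likelihood (larger is better).
#' @export
bic_score <- function(dag, data) {
  env <- make_bic_env(data)
  pl <- as_parent_list(dag, env$vars)
  if (any(lengths(pl) > env$n - 2)) stop("more parents than samples - 2")
  sum(vapply(seq_along(env$vars), function(i)
    node_bic(env, i, match(pl[[env$vars[i]]], env$vars)), numeric(1)))
}

as_parent_list <- function(dag, vars) {
  if (is.matrix(dag)) {
    pl <- lapply(seq_along(vars), function(j) vars[dag[, j] != 0])
    names(pl) <- vars
    return(pl)
  }
  pl <- stats::setNames(vector("list", length(vars)), vars)
  for (v in vars) pl[[v]] <- as.character(dag[[v]])
  pl
}

# is there a directed path from a to b in the parent-index representation?
has_path <- function(children, a, b) {
  seen <- logical(length(children))
  stack <- a
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v == b) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, children[[v]])
  }
  FALSE
}

#' Sample an ensemble of DAGs by MCMC with a cis-eQTL orientation prior
#'
#' Metropolis-Hastings over add / delete / reverse single-edge moves
#' respecting acyclicity and the parent limit, targeting
#' `exp(BIC + log prior)` with Gaussian local models.  The structure prior
#' subtracts `lambda` for every edge pointing into a cis gene from a
#' non-cis gene, breaking Markov-equivalent orientations in favor of
#' genetics-anchored genes being upstream.  Samples are thinned and pooled
#' over independent restarts until `n_networks` DAGs are collected.
#'
#' @param data sample x gene matrix.
#' @param cis_genes character vector of genes with a cis-eQTL (the prior
#'   anchor); empty for a flat prior.
#' @param lambda prior penalty per counter-oriented edge.
#' @param n_networks ensemble size (>= 100).
#' @param n_restarts independent chains.
#' @param max_parents in-degree cap.
#' @param seed integer seed.
#' @param burnin,thin move counts; defaults `10 p^2` and `p^2`.
#' @return list of class `dag_ensemble`: `samples` (list of parent-index
#'   lists), `vars`, `edge_freq` matrix, `bic` per sample.
#' @export
mcmc_sample_dags <- function(data, cis_genes = character(0), lambda = 3,
                             n_networks = 1000L, n_restarts = 10L,
                             max_parents = 3L, seed = 1L,
                             burnin = NULL, thin = NULL) {
  n_networks <- check_count(n_networks, "n_networks", min = 100L)
  env <- make_bic_env(data)
  p <- env$p
  vars <- env$vars
  if (p == 1) {
    samples <- replicate(n_networks, list(rep(list(integer(0)), 1)))
    ef <- matrix(0, 1, 1, dimnames = list(vars, vars))
    return(structure(list(samples = samples, vars = vars, edge_freq = ef,
                          bic = rep(node_bic(env, 1, integer(0)), n_networks)),
                     class = "dag_ensemble"))
  }
  if (is.null(burnin)) burnin <- 10L * p^2
  if (is.null(thin)) thin <- p^2
  cis <- vars %in% cis_genes
  # log prior delta for adding edge i -> j
  prior_delta <- function(i, j) if (cis[j] && !cis[i]) -lambda else 0
  per_restart <- ceiling(n_networks / n_restarts)
  samples <- list()
  bics <- numeric(0)
  edge_count <- matrix(0, p, p, dimnames = list(vars, vars))
  with_seed(substream_seed(seed, "mcmc-dags"), {
    for (r in seq_len(n_restarts)) {
      parents <- rep(list(integer(0)), p)
      children <- rep(list(integer(0)), p)
      node_scores <- vapply(seq_len(p), function(i)
        node_bic(env, i, integer(0)), numeric(1))
      collected <- 0L
      move <- 0L
      total_moves <- burnin + per_restart * thin
      propose_move <- function() {
        i <- sample.int(p, 1); j <- sample.int(p, 1)
        if (i == j) return(invisible())
        if (i %in% parents[[j]]) {
          # delete or reverse, equal chance
          if (stats::runif(1) < 0.5) {
            new_pj <- setdiff(parents[[j]], i)
            delta <- node_bic(env, j, new_pj) - node_scores[j] - prior_delta(i, j)
            # delete is proposed half as often as its inverse add
            if (log(stats::runif(1)) < delta + log(2)) {
              parents[[j]] <<- new_pj
              children[[i]] <<- setdiff(children[[i]], j)
              node_scores[j] <<- node_scores[j] + delta + prior_delta(i, j)
            }
          } else {
            # reverse i -> j to j -> i
            if (length(parents[[i]]) >= max_parents) return(invisible())
            children_i <- setdiff(children[[i]], j)
            # cycle check: path i ~> j avoiding the reversed edge
            ch_tmp <- children; ch_tmp[[i]] <- children_i
            if (has_path(ch_tmp, i, j)) return(invisible())
            new_pj <- setdiff(parents[[j]], i)
            new_pi <- c(parents[[i]], j)
            dj <- node_bic(env, j, new_pj) - node_scores[j]
            di <- node_bic(env, i, new_pi) - node_scores[i]
            delta <- dj + di - prior_delta(i, j) + prior_delta(j, i)
            if (log(stats::runif(1)) < delta) {
              parents[[j]] <<- new_pj; parents[[i]] <<- new_pi
              children[[i]] <<- children_i
              children[[j]] <<- c(children[[j]], i)
              node_scores[j] <<- node_scores[j] + dj
              node_scores[i] <<- node_scores[i] + di
            }
          }
        } else {
          # add i -> j
          if (length(parents[[j]]) >= max_parents) return(invisible())
          if (has_path(children, j, i)) return(invisible())  # would close a cycle
          new_pj <- c(parents[[j]], i)
          delta <- node_bic(env, j, new_pj) - node_scores[j] + prior_delta(i, j)
          # add is proposed twice as often as its inverse delete
          if (log(stats::runif(1)) < delta - log(2)) {
            parents[[j]] <<- new_pj
            children[[i]] <<- c(children[[i]], j)
            node_scores[j] <<- node_scores[j] + delta - prior_delta(i, j)
          }
        }
        invisible()
      }
      while (move < total_moves) {
        move <- move + 1L
        propose_move()
        if (move > burnin && (move - burnin) %% thin == 0 &&
            collected < per_restart) {
          samples[[length(samples) + 1]] <- parents
          bics <- c(bics, sum(node_scores))
          collected <- collected + 1L
        }
      }
    }
  })
  samples <- samples[seq_len(min(length(samples), n_networks))]
  edge_count[] <- 0
  for (s in samples) for (jj in seq_len(p)) for (ii in s[[jj]])
    edge_count[ii, jj] <- edge_count[ii, jj] + 1
  structure(list(samples = samples, vars = vars,
                 edge_freq = edge_count / length(samples),
                 bic = bics[seq_along(samples)]),
            class = "dag_ensemble")
}

#' Consensus network from a DAG ensemble
#'
#' Edges whose ensemble frequency reaches `freq_threshold` are retained; if
#' the union contains a cycle, edges are removed greedily from the lowest
#' frequency upward until the graph is acyclic.
#'
#' @param ensemble a `dag_ensemble`.
#' @param freq_threshold retention threshold in (0, 1].
#' @return list of class `consensus_dag`: `edges` data frame (parent,
#'   child, frequency), `vars`, `graph` (igraph DAG).
#' @export
consensus_network <- function(ensemble, freq_threshold = 0.3) {
  stopifnot(inherits(ensemble, "dag_ensemble"))
  if (freq_threshold <= 0 || freq_threshold > 1)
    stop("freq_threshold must be in (0,1]")
  ef <- ensemble$edge_freq
  idx <- which(ef >= freq_threshold, arr.ind = TRUE)
  edges <- data.frame(parent = ensemble$vars[idx[, 1]],
                      child = ensemble$vars[idx[, 2]],
                      frequency = ef[idx])
  edges <- edges[order(-edges$frequency, edges$parent, edges$child), ]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges[, 1:2], vertices = ensemble$vars)
  while (nrow(edges) > 0 && !igraph::is_dag(g)) {
    # drop the lowest-frequency edge that sits inside a strongly connected
    # component (i.e. participates in some cycle)
    scc <- igraph::components(g, mode = "strong")$membership
    on_cycle <- which(scc[edges$parent] == scc[edges$child])
    drop <- on_cycle[which.min(edges$frequency[on_cycle])]
    edges <- edges[-drop, ]
    g <- igraph::graph_from_data_frame(edges[, 1:2], vertices = ensemble$vars)
  }
  structure(list(edges = edges, vars = ensemble$vars, graph = g,
                 threshold = freq_threshold),
            class = "consensus_dag")
}

#' Key-driver calling by downstream h-layer neighborhood size
#'
#' `hln_size` of a node is the number of distinct nodes reachable within
#' `h` directed steps downstream.  A node is a candidate causal regulator
#' when its HLN size strictly exceeds the mean plus one sample (n - 1)
#' standard deviation over all nodes.
#'
#' @param consensus a `consensus_dag` (or igraph DAG).
#' @param h neighborhood depth (>= 1).
#' @return data frame: node, hln_size, is_ccr; ordered by decreasing size.
#' @export
causal_regulators <- function(consensus, h = 3L) {
  h <- check_count(h, "h")
  g <- if (inherits(consensus, "consensus_dag")) consensus$graph else consensus
  vs <- igraph::V(g)$name
  hln <- vapply(vs, function(v)
    length(igraph::ego(g, order = h, nodes = v, mode = "out",
                       mindist = 1)[[1]]), integer(1))
  mu <- mean(hln)
  sdv <- stats::sd(hln)
  cutoff <- mu + ifelse(is.na(sdv), 0, sdv)
  out <- data.frame(node = vs, hln_size = as.integer(hln),
                    is_ccr = !is.na(sdv) & sdv > 0 & hln > cutoff,
                    row.names = NULL)
  out[order(-out$hln_size, out$node), ]
}
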