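test_that("cis-eQTL detection is powered, calibrated and boundary-correct", {
  hits <- 0L
  for (s in 1:20) {
    cfg <- simulation_config(cis_effect = 1, n_f2 = 100L, seed = s)
    gen <- generate_genetic_cohort(cfg)
    eq <- detect_cis_eqtls(gen$expr, gen$genotypes, gen$gene_pos, gen$snp_pos,
                           alpha = 1e-3)
    row <- eq[eq$gene == gen$driver_truth, ]
    if (nrow(row) == 1 && row$cis && row$snp == "snp001") hits <- hits + 1L
  }
  expect_gte(hits, 18L)
  # window 0 with a SNP exactly at the gene position is still eligible
  expr <- matrix(rnorm(20), 1, 20, dimnames = list("g", paste0("s", 1:20)))
  geno <- matrix(sample(0:2, 20, TRUE), 20, 1,
                 dimnames = list(paste0("s", 1:20), "snp"))
  eq0 <- detect_cis_eqtls(expr, geno, c(g = 500), c(snp = 500), window = 0)
  expect_equal(nrow(eq0), 1L)
})

test_that("null cis effects are detected at close to the nominal rate", {
  set.seed(1)
  fp <- 0L; n_tests <- 0L
  for (s in 1:200) {
    n <- 50
    expr <- matrix(rnorm(n), 1, n, dimnames = list("g", paste0("s", 1:n)))
    geno <- matrix(sample(0:2, n, TRUE, prob = c(.25, .5, .25)), n, 1,
                   dimnames = list(paste0("s", 1:n), "snp"))
    eq <- detect_cis_eqtls(expr, geno, c(g = 100), c(snp = 150),
                           window = 1000, alpha = 0.05)
    n_tests <- n_tests + nrow(eq)
    fp <- fp + sum(eq$cis)
  }
  expect_lte(fp / n_tests, 0.05 * 1.8)
})

test_that("the BIC of an empty graph matches the closed-form Gaussian score", {
  set.seed(2)
  n <- 150
  data <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  dag <- setNames(rep(list(character(0)), 4), paste0("v", 1:4))
  got <- bic_score(dag, data)
  # per node: ML Gaussian log-likelihood minus (2/2) log n
  closed <- sum(vapply(1:4, function(j) {
    s2 <- mean((data[, j] - mean(data[, j]))^2)
    -n / 2 * (log(2 * pi * s2) + 1) - log(n)
  }, numeric(1)))
  expect_equal(got, closed, tolerance = 1e-10)
})

test_that("BIC rewards true strong parents and decomposes over nodes", {
  set.seed(3)
  n <- 100
  x <- rnorm(n); y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(n); z <- rnorm(n)
  data <- cbind(x = x, y = y, z = z)
  empty <- list(x = character(0), y = character(0), z = character(0))
  with_parent <- list(x = character(0), y = "x", z = character(0))
  expect_gt(bic_score(with_parent, data), bic_score(empty, data))
  # decomposability: changing y's parents leaves the x and z terms unchanged
  env <- dcxnet:::make_bic_env(data)
  d1 <- bic_score(with_parent, data) - bic_score(empty, data)
  d2 <- dcxnet:::node_bic(env, 2, 1) - dcxnet:::node_bic(env, 2, integer(0))
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("a single gene yields an ensemble of empty graphs", {
  data <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "only"))
  ens <- mcmc_sample_dags(data, n_networks = 100, seed = 1)
  expect_equal(length(ens$samples), 100L)
  expect_true(all(ens$edge_freq == 0))
})

test_that("every sampled graph is acyclic and respects the parent cap", {
  set.seed(4)
  data <- matrix(rnorm(120 * 6), 120, 6, dimnames = list(NULL, paste0("v", 1:6)))
  ens <- mcmc_sample_dags(data, n_networks = 100, n_restarts = 2, seed = 2,
                          max_parents = 3)
  for (s in ens$samples[seq(1, 100, by = 10)]) {
    expect_true(all(lengths(s) <= 3))
    g <- igraph::graph_from_adjacency_matrix(
      t(vapply(seq_along(s), function(j) {
        row <- rep(0, 6); row[s[[j]]] <- 1; row
      }, numeric(6))))  # [j, i] = 1 means i is parent of j -> transpose
    expect_true(igraph::is_dag(g))
  }
})

test_that("the cis prior breaks Markov equivalence in the anchored direction", {
  set.seed(9)
  x <- rnorm(200); y <- 0.8 * x + 0.6 * rnorm(200)
  d <- cbind(x = x, y = y)
  e1 <- mcmc_sample_dags(d, cis_genes = "x", lambda = 3, n_networks = 500,
                         n_restarts = 5, seed = 1)
  expect_gt(e1$edge_freq["x", "y"], e1$edge_freq["y", "x"])
  e0 <- mcmc_sample_dags(d, cis_genes = character(0), lambda = 0,
                         n_networks = 1000, n_restarts = 5, seed = 2)
  expect_lt(abs(e0$edge_freq["x", "y"] - e0$edge_freq["y", "x"]), 0.1)
})

test_that("consensus thresholding and cycle repair behave exactly", {
  # hand-built ensemble: edge a->b in 40% of 10 graphs
  vars <- c("a", "b")
  mk <- function(with_edge) list(integer(0), if (with_edge) 1L else integer(0))
  samples <- c(replicate(4, mk(TRUE), simplify = FALSE),
               replicate(6, mk(FALSE), simplify = FALSE))
  ef <- matrix(c(0, 0.4, 0, 0), 2, byrow = TRUE,
               dimnames = list(vars, vars))
  ens <- structure(list(samples = samples, vars = vars, edge_freq = ef,
                        bic = numeric(10)), class = "dag_ensemble")
  expect_equal(nrow(consensus_network(ens, 0.3)$edges), 1L)
  expect_equal(nrow(consensus_network(ens, 0.5)$edges), 0L)
  expect_error(consensus_network(ens, 0), "freq_threshold")
  # an ensemble of identical DAGs is its own consensus at any threshold
  same <- structure(list(samples = replicate(5, mk(TRUE), simplify = FALSE),
                         vars = vars,
                         edge_freq = matrix(c(0, 1, 0, 0), 2, byrow = TRUE,
                                            dimnames = list(vars, vars)),
                         bic = numeric(5)), class = "dag_ensemble")
  expect_equal(consensus_network(same, 1)$edges$parent, "a")
  # cycle repair drops the weakest edge of the cycle
  ef2 <- matrix(c(0, 0.9, 0.4, 0), 2, byrow = TRUE,
                dimnames = list(vars, vars))
  ens2 <- structure(list(samples = samples, vars = vars, edge_freq = ef2,
                         bic = numeric(10)), class = "dag_ensemble")
  fixed <- consensus_network(ens2, 0.3)
  expect_true(igraph::is_dag(fixed$graph))
  expect_identical(fixed$edges$parent, "a")
})

test_that("a chain SEM is recovered with its genetics-anchored orientation", {
  set.seed(11)
  n <- 200
  x <- rnorm(n); y <- 0.8 * x + rnorm(n); z <- 0.8 * y + rnorm(n)
  d <- cbind(x = x, y = y, z = z)
  ens <- mcmc_sample_dags(d, cis_genes = "x", lambda = 3, n_networks = 1000,
                          n_restarts = 10, seed = 1)
  cons <- consensus_network(ens, 0.3)
  key <- paste(cons$edges$parent, cons$edges$child, sep = "->")
  expect_true("x->y" %in% key)
  expect_true("y->z" %in% key)
  expect_false("y->x" %in% key)
})

test_that("h-layer neighborhoods count reachable nodes exactly", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "c"), to = c("b", "c", "d")),
    vertices = letters[1:4])
  cr <- causal_regulators(g, h = 2)
  sizes <- setNames(cr$hln_size, cr$node)
  expect_equal(unname(sizes[c("a", "b", "c", "d")]), c(2L, 2L, 1L, 0L))
  # monotone non-decreasing in h
  cr3 <- causal_regulators(g, h = 3)
  expect_true(all(cr3$hln_size[match(cr$node, cr3$node)] >= cr$hln_size))
})

test_that("the CCR cutoff is mean plus one sample SD, strictly exceeded", {
  # star: one node with HLN 4, two with 1, two with 0
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("hub", "hub", "u", "v"), to = c("u", "v", "p", "q")),
    vertices = c("hub", "u", "v", "p", "q"))
  cr <- causal_regulators(g, h = 2)
  sizes <- sort(cr$hln_size, decreasing = TRUE)
  expect_equal(sizes, c(4L, 1L, 1L, 0L, 0L))
  cutoff <- mean(sizes) + sd(sizes)
  expect_equal(cutoff, 1.2 + sd(c(4, 1, 1, 0, 0)))
  expect_identical(cr$node[cr$is_ccr], "hub")
  # an edgeless graph flags nobody
  g0 <- igraph::make_empty_graph(3) |> igraph::set_vertex_attr("name", value = letters[1:3])
  expect_false(any(causal_regulators(g0, h = 1)$is_ccr))
})

test_that("a planted star driver is flagged as causal regulator", {
  set.seed(12)
  n <- 150
  driver <- rnorm(n)
  children <- sapply(1:8, function(i) 0.7 * driver + rnorm(n))
  d <- cbind(driver = driver, children)
  colnames(d) <- c("driver", paste0("ch", 1:8))
  ens <- mcmc_sample_dags(d, cis_genes = "driver", lambda = 3,
                          n_networks = 200, n_restarts = 4, seed = 3)
  cons <- consensus_network(ens, 0.3)
  cr <- causal_regulators(cons, h = 3)
  expect_true(cr$is_ccr[cr$node == "driver"])
  expect_identical(cr$node[1], "driver")
})
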