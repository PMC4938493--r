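test_that("generation is deterministic: same config and seed are bit-identical", {
  cfg <- simulation_config(seed = 7L)
  s1 <- generate_synthetic_study(cfg)
  s2 <- generate_synthetic_study(cfg)
  expect_identical(s1$cohort$expr, s2$cohort$expr)
  expect_identical(s1$genetic$genotypes, s2$genetic$genotypes)
  expect_identical(s1$drugs$profiles, s2$drugs$profiles)
  expect_identical(s1$motifs$target, s2$motifs$target)
  expect_identical(s1$ppi$edges, s2$ppi$edges)
  expect_identical(s1$traits, s2$traits)
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(module_sizes = c(200, 200), n_genes = 300),
               "exceeds")
  expect_error(simulation_config(intra_corr_case = c(1, 0.5, 0.5, 0.5)),
               "\\[0,1\\)")
  expect_error(simulation_config(
    chain_spec = data.frame(parent = c("a", "b"), child = c("b", "a"),
                            coef = c(1, 1))), "cycle")
})

test_that("planted intra-module correlations match their one-factor targets", {
  cfg <- simulation_config(seed = 1L)
  co <- generate_case_control(cfg)
  mean_corr <- function(genes, cols) {
    cc <- cor(t(co$expr[genes, cols]))
    mean(cc[upper.tri(cc)])
  }
  gained <- names(co$partition_truth)[co$partition_truth == "turquoise"]
  expect_lt(abs(mean_corr(gained, co$condition == "case") - 0.7), 0.08)
  expect_lt(abs(mean_corr(gained, co$condition == "control") - 0.3), 0.08)
  lost <- names(co$partition_truth)[co$partition_truth == "blue"]
  expect_lt(abs(mean_corr(lost, co$condition == "case") - 0.3), 0.08)
  expect_lt(abs(mean_corr(lost, co$condition == "control") - 0.7), 0.08)
})

test_that("equal case/control correlations imply an all-stable truth", {
  cfg <- simulation_config(intra_corr_ctrl = rep(0.5, 4),
                           intra_corr_case = rep(0.5, 4))
  co <- generate_case_control(cfg)
  expect_true(all(co$dc_truth == "stable"))
})

test_that("DE truth genes live in the designated module at the set fraction", {
  cfg <- simulation_config(seed = 3L)
  co <- generate_case_control(cfg)
  mod1 <- names(co$partition_truth)[co$partition_truth == "turquoise"]
  expect_true(all(co$de_truth %in% mod1))
  expect_equal(length(co$de_truth), round(0.5 * length(mod1)))
  shift <- rowMeans(co$expr[co$de_truth, co$condition == "case"]) -
    rowMeans(co$expr[co$de_truth, co$condition == "control"])
  expect_lt(abs(mean(shift) - cfg$de_delta), 0.15)
})

test_that("F2 genotypes take dosages 0/1/2 with 1:2:1 proportions", {
  cfg <- simulation_config(n_f2 = 4L, n_snps = 1L, seed = 2L)
  gen <- generate_genetic_cohort(cfg)
  expect_true(all(gen$genotypes %in% 0:2))
  big <- generate_genetic_cohort(simulation_config(n_f2 = 2000L, seed = 5L))
  tab <- table(big$genotypes) / length(big$genotypes)
  expect_lt(max(abs(tab - c(0.25, 0.5, 0.25))), 0.03)
})

test_that("a null cis effect leaves the driver independent of genotype", {
  covered <- 0L
  for (s in 1:100) {
    cfg <- simulation_config(cis_effect = 0, n_f2 = 100L, seed = s)
    gen <- generate_genetic_cohort(cfg)
    fit <- summary(lm(gen$expr[gen$driver_truth, ] ~ gen$genotypes[, 1]))
    est <- fit$coefficients[2, 1]; se <- fit$coefficients[2, 2]
    if (abs(est) <= qt(0.975, 98) * se) covered <- covered + 1L
  }
  expect_gte(covered, 90L)
})

test_that("chain path products reproduce the closed-form correlation", {
  cfg <- simulation_config(n_f2 = 200L, cis_effect = 0, seed = 1L)
  gen <- generate_genetic_cohort(cfg)
  # driver -> b -> c with coefficients 0.8, 0.8; unit innovations:
  # cov(driver, c) = 0.64 * var(driver); corr = 0.64 * sd(d)/sd(c)
  vd <- 1; vb <- 0.64 * vd + 1; vc <- 0.64 * vb + 1
  rho_pop <- 0.8 * 0.8 * vd / sqrt(vd * vc)
  rho_hat <- cor(gen$expr["g001", ], gen$expr["g003", ])
  expect_lt(abs(rho_hat - rho_pop), 0.1)
})

test_that("drug rank profiles are permutations with the planted placements", {
  cfg <- simulation_config(seed = 4L)
  dr <- generate_drug_rank_profiles(cfg)
  G <- nrow(dr$profiles)
  for (j in seq_len(ncol(dr$profiles)))
    expect_setequal(dr$profiles[, j], seq_len(G))
  up <- dr$profiles[, dr$compound == "cmpd_up", drop = FALSE]
  expect_true(all(up[dr$query_truth, ] <= floor(0.05 * G)))
  down <- dr$profiles[, dr$compound == "cmpd_down", drop = FALSE]
  expect_true(all(down[dr$query_truth, ] > G - floor(0.05 * G)))
  # null compounds put the designated genes near the middle on average
  null <- dr$profiles[, grepl("null", colnames(dr$profiles)), drop = FALSE]
  mr <- mean(null[dr$query_truth, ])
  se <- sqrt(G^2 / 12 / length(null[dr$query_truth, ]))
  expect_lt(abs(mr - (G + 1) / 2), 3 * se)
})

test_that("motif dataset plants exactly the recorded consensus sites", {
  cfg <- simulation_config(seed = 6L)
  mo <- generate_motif_dataset(cfg)
  tg <- mo$sites[mo$sites$set == "target", ]
  expect_equal(nrow(tg), 40L)
  L <- nchar(mo$consensus)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(mo$consensus)))
  for (i in seq_len(nrow(tg))) {
    s <- unname(substr(mo$target[tg$seq[i]], tg$start0[i] + 1, tg$start0[i] + L))
    expect_identical(s, if (tg$strand[i] == "+") mo$consensus else rc)
  }
  # zero planted sites yield an empty site list
  cfg0 <- simulation_config(seed = 6L)
  cfg0$motif_spec$sites_target <- 0L
  cfg0$motif_spec$sites_background <- 0L
  expect_equal(nrow(generate_motif_dataset(cfg0)$sites), 0L)
})

test_that("promoter background composition matches the configured frequencies", {
  cfg <- simulation_config(seed = 1L)
  cfg$motif_spec$sites_target <- 0L
  cfg$motif_spec$sites_background <- 0L
  cfg$motif_spec$n_background <- 500L
  mo <- generate_motif_dataset(cfg)
  bases <- table(strsplit(paste(mo$background, collapse = ""), "")[[1]])
  freq <- bases / sum(bases)
  target <- cfg$motif_spec$base_freq / sum(cfg$motif_spec$base_freq)
  expect_lt(max(abs(freq[names(target)] - target)), 0.02)
})

test_that("all truth references resolve to existing entities", {
  st <- generate_synthetic_study(simulation_config(seed = 11L))
  expect_true(all(st$cohort$de_truth %in% rownames(st$cohort$expr)))
  expect_true(all(names(st$cohort$dc_truth) %in% st$cohort$partition_truth))
  expect_true(st$genetic$driver_truth %in% rownames(st$genetic$expr))
  expect_true(all(st$drugs$query_truth %in% rownames(st$drugs$profiles)))
  expect_true(all(st$ppi$annotation %in% st$ppi$universe))
  expect_true(all(st$motifs$sites$seq %in%
                    c(names(st$motifs$target), names(st$motifs$background))))
})

test_that("written study files round-trip and re-write identically", {
  st <- generate_synthetic_study(simulation_config(seed = 8L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic_study(st, d1)
  write_synthetic_study(st, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  back <- read_expression(file.path(d1, "expression.tsv"))
  expect_equal(back$expr, st$cohort$expr, tolerance = 1e-12)
})
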