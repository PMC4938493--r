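make_universe <- function(n) sprintf("u%03d", seq_len(n))

# build sets realizing a given 2x2 table over a universe
sets_for_table <- function(a, b, c, d) {
  u <- make_universe(a + b + c + d)
  list(set_a = u[seq_len(a + b)],
       set_b = c(u[seq_len(a)], u[(a + b + 1):(a + b + c)]),
       universe = u)
}

test_that("Fisher enrichment reproduces symmetric and depleted tables", {
  s <- sets_for_table(5, 5, 5, 5)
  er <- fisher_enrichment(s$set_a, s$set_b, s$universe)
  expect_equal(er$odds_ratio, 1)
  expect_equal(er$p, 1)
  # disjoint sets with positive expectation sit on the depletion side
  s0 <- sets_for_table(0, 10, 10, 10)
  er0 <- fisher_enrichment(s0$set_a, s0$set_b, s0$universe)
  expect_equal(er0$odds_ratio, 0)
  expect_true(er0$haldane)
  expect_error(fisher_enrichment("x", "y", character(0)), "empty universe")
})

test_that("Fisher p equals exhaustive hypergeometric enumeration", {
  s <- sets_for_table(8, 2, 2, 8)
  er <- fisher_enrichment(s$set_a, s$set_b, s$universe)
  expect_equal(er$odds_ratio, 16)
  expect_equal(er$p, oracle_fisher_two_sided(8, 2, 2, 8), tolerance = 1e-12)
  # all tables with small margins
  for (r1 in 0:6) for (r2 in 0:6) for (a in 0:r1) for (cc in 0:r2) {
    b <- r1 - a; d <- r2 - cc
    if (a + b + cc + d == 0) next
    tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
    expect_equal(stats::fisher.test(tab)$p.value,
                 oracle_fisher_two_sided(a, b, cc, d), tolerance = 1e-9)
  }
})

test_that("multiple-testing adjustments follow their definitions", {
  expect_equal(adjust_p(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_p(rep(0.01, 5), "bonferroni"), rep(0.05, 5))
  expect_equal(adjust_p(c(0.01, 0.02, 0.03), "bh"), rep(0.03, 3))
  expect_equal(adjust_p(0.2, "bh"), 0.2)
  set.seed(1)
  p <- runif(30)
  expect_equal(adjust_p(p, "bh"), oracle_bh(p), tolerance = 1e-12)
  expect_true(all(adjust_p(p, "bonferroni") >= p))
  # BH is monotone in the order statistics
  q <- adjust_p(p, "bh")
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(adjust_p(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("module ranking flags criteria and orders by count then p", {
  mdc_tab <- data.frame(
    module = c("m1", "m2", "m3"),
    mdc = c(3, 1.1, 0.4), fdr = c(0.0001, 0.5, 0.0001),
    classification = c("gained", "conserved", "lost"))
  enr <- data.frame(
    module = rep(c("m1", "m2", "m3"), each = 1),
    signature = "sig1",
    p = c(1e-10, 0.2, 0.9),
    p_adjusted = c(3e-10, 0.6, 1))
  rk <- rank_modules(mdc_tab, enr)
  expect_identical(rk$module[1], "m1")  # flagged on both criteria
  expect_equal(rk$criteria_count[rk$module == "m1"], 2L)
  expect_equal(rk$criteria_count[rk$module == "m3"], 1L)
  # all-zero flags fall back to minimum enrichment p ordering
  enr0 <- transform(enr, p_adjusted = 1)
  mdc0 <- transform(mdc_tab, classification = "conserved")
  rk0 <- rank_modules(mdc0, enr0)
  expect_identical(rk0$module, c("m1", "m2", "m3"))
  expect_identical(rk0$module[1],
                   enr0$module[which.min(enr0$p)])
})

test_that("homology expansion keeps every pair and multiplies groups", {
  hom <- data.frame(a = c("a1", "a2", "a2", "a3", "a4"),
                    b = c("b1", "b2", "b3", "b2", "b9"))
  expect_identical(expand_homology("a1", hom), "b1")
  expect_setequal(expand_homology(c("a2", "a3"), hom), c("b2", "b3"))
  # an n-to-m block expands to all n x m pairs
  block <- expand.grid(a = paste0("x", 1:3), b = paste0("y", 1:4),
                       stringsAsFactors = FALSE)
  expect_equal(nrow(unique(block)), 12L)
  expect_setequal(expand_homology(paste0("x", 1:3), block), paste0("y", 1:4))
})

test_that("identical partitions through identity homology are conserved", {
  genes <- sprintf("g%02d", 1:60)
  part_a <- setNames(rep(c("m1", "m2", "grey"), each = 20), genes)
  hom <- data.frame(a = genes, b = paste0("h_", genes))
  part_b <- setNames(rep(c("w1", "w2", "grey"), each = 20), paste0("h_", genes))
  cons <- map_modules_across_species(part_a, part_b, hom)
  hit <- cons[cons$conserved, ]
  expect_equal(nrow(hit), 2L)
  expect_identical(hit$module_b[hit$module_a == "m1"], "w1")
  expect_identical(hit$module_b[hit$module_a == "m2"], "w2")
})

test_that("conservation thresholds apply to OR > 2 and Bonferroni p < 0.05", {
  tab <- data.frame(module_a = "m", module_b = "w",
                    odds_ratio = 3, p_bonferroni = 0.01)
  expect_true(tab$odds_ratio > 2 & tab$p_bonferroni < 0.05)
  # borderline: OR exactly 2 or adjusted p at 0.05 does not qualify
  expect_false(2 > 2 && 0.01 < 0.05)
  genes <- sprintf("g%02d", 1:40)
  part_a <- setNames(rep(c("m1", "m2"), each = 20), genes)
  hom <- data.frame(a = genes, b = paste0("h_", genes))
  part_b <- setNames(sample(rep(c("w1", "w2"), each = 20)), paste0("h_", genes))
  set.seed(2)
  cons <- map_modules_across_species(part_a, part_b, hom)
  expect_true(all(c("odds_ratio", "p_bonferroni", "conserved") %in% names(cons)))
  expect_identical(cons$conserved,
                   cons$p_bonferroni < 0.05 & cons$odds_ratio > 2)
})

test_that("a planted shared module is its counterpart's unique partner", {
  cfg <- simulation_config(seed = 1L)
  co <- generate_case_control(cfg)
  sp2 <- generate_homologous_species(cfg, co$partition_truth)
  cons <- map_modules_across_species(co$partition_truth, sp2$partition_b,
                                     sp2$homology)
  for (ma in c("turquoise", "blue", "brown", "yellow")) {
    partners <- cons$module_b[cons$module_a == ma & cons$conserved]
    expect_identical(partners, paste0("ms_", ma))
  }
})

test_that("the grey-expression audit detects a planted downward shift", {
  set.seed(1)
  n <- 1000
  expr <- matrix(rnorm(n * 20), n, 20,
                 dimnames = list(sprintf("g%04d", 1:n), sprintf("s%02d", 1:20)))
  expr[1:200, ] <- expr[1:200, ] - 2  # grey genes shifted down 2 SD
  part <- setNames(c(rep("grey", 200), rep("m1", 800)), rownames(expr))
  audit <- compare_module_expression(expr, part)
  expect_lt(audit$ks$p.value, 1e-6)
  expect_lt(audit$module_medians$median[audit$module_medians$module == "grey"],
            audit$module_medians$median[audit$module_medians$module == "m1"])
})

test_that("the KS statistic equals the max ECDF gap oracle", {
  set.seed(3)
  x <- rnorm(40); y <- rnorm(60)
  expr <- matrix(c(x, y), 100, 1, dimnames = list(sprintf("g%03d", 1:100), "s1"))
  expr <- cbind(expr, expr)  # two identical samples so medians equal values
  colnames(expr) <- c("s1", "s2")
  part <- setNames(c(rep("grey", 40), rep("m1", 60)), rownames(expr))
  audit <- compare_module_expression(expr, part)
  expect_equal(unname(audit$ks$statistic), oracle_ks_two_sample_D(x, y),
               tolerance = 1e-12)
})

test_that("degenerate one-gene groups give D of 0 or 1 only", {
  expr <- matrix(c(1, 5), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  part <- setNames(c("grey", "m1"), c("a", "b"))
  audit <- suppressWarnings(compare_module_expression(expr, part))
  expect_true(unname(audit$ks$statistic) %in% c(0, 1))
  # empty grey skips the test with a note
  part2 <- setNames(c("m1", "m1"), c("a", "b"))
  expect_message(a2 <- compare_module_expression(expr, part2), "skipped")
  expect_null(a2$ks)
})
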