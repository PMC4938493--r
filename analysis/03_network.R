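#!/usr/bin/env Rscript
# Build the weighted coexpression network on the corrected expression:
# Pearson correlation -> soft-threshold adjacency (beta = 6) -> topological
# overlap -> average-linkage dendrogram with adaptive branch cutting
# (min module size 30) -> module eigengenes -> resampling robustness Z.

library(dcxnet)

seed <- as.integer(Sys.getenv("DCXNET_SEED", "1"))
study <- generate_synthetic_study(simulation_config(seed = seed))
co <- study$cohort
es <- adjust_covariates(
  expression_study(co$expr, co$condition, co$covariates[, c("age", "sex")]),
  c("age", "sex"))

tom <- topological_overlap(soft_adjacency(correlation_matrix(es), 6))
partition <- detect_modules(tom, min_size = 30, deep_split = 2)
egs <- module_eigengenes(es, partition)
rob <- module_robustness(es, partition, n_splits = 10,
                         seed = substream_seed(seed, "robust"),
                         n_label_perm = 30)
audit <- compare_module_expression(es, partition)

dir.create("results", showWarnings = FALSE)
utils::write.table(data.frame(gene = names(partition), module = partition),
                   "results/modules.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(data.frame(sample = rownames(egs), egs, check.names = FALSE),
                   "results/eigengenes.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(rob, "results/module_robustness.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

tab <- table(partition, co$partition_truth)
cat("Detected", length(setdiff(unique(partition), "grey")),
    "modules;", sum(partition == "grey"), "genes grey.\n")
cat("Planted-module recovery (majority overlap):\n")
for (pl in setdiff(colnames(tab), "grey"))
  cat(sprintf("  %-10s -> %-10s %.0f%%\n", pl,
              rownames(tab)[which.max(tab[, pl])],
              100 * max(tab[, pl]) / sum(tab[, pl])))
cat("Robustness Z (planted modules should sit well above the weak band;\n",
    "the rho = 0.5 modules land moderate on half-sample splits, the\n",
    "stronger-correlation module strong):\n")
print(rob)
if (!is.null(audit$ks))
  cat("Grey vs assigned median-expression KS p:", audit$ks$p.value,
      "(no planted expression shift, so a large p is expected)\n")
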