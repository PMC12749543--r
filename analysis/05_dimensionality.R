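#!/usr/bin/env Rscript

## Stage 5 — dimensionality of regional change.
##
## Cross-region correlation of yearly change, PCA of the correlation matrix
## (global-decline factor), Monte-Carlo reference consensus clustering with
## the K = 1 test, and cluster-score models of memory change controlling
## for the reference cluster, the PC1 score, and the other clusters.

library(longchange)

ct <- read_panel("results/change_table.tsv")
regs <- region_cols(ct)

cc <- change_correlation(ct, regs)
cat(sprintf("change correlations: mean r = %.2f (SD %.2f), range %.2f..%.2f\n",
            cc$summary["mean"], cc$summary["sd"], cc$summary["min"],
            cc$summary["max"]))

pc <- pca_summary(cc$matrix)
cat(sprintf("PC1 accounts for %.1f%% of variance; loadings all %s\n",
            100 * pc$var_fraction[1],
            if (all(pc$loadings > 0)) "positive" else "mixed-sign"))

sol <- consensus_cluster(ct, regs, K_max = 5, reps = 100, null_reps = 100,
                         seed = 55)
print(sol)
write_panel(sol$stats, "results/cluster_stats.tsv", provenance = c(stage = "dimred"))
write_panel(data.frame(region = names(sol$assignments),
                       cluster = sol$assignments),
            "results/clusters.tsv", provenance = c(stage = "dimred"))

if (sol$K_star > 1) {
  cm <- cluster_memory_models(ct, sol, B = 199, seed = 56)
  write_panel(cm$per_cluster, "results/cluster_models.tsv",
              provenance = c(stage = "dimred"))
  cat("cluster-memory models:\n")
  print(cm$per_cluster, digits = 3)
  cat(sprintf("joint clusters vs PC1-only partial R2: %.4f\n", cm$joint_vs_pc1))
} else {
  cat("no clustering beyond K = 1 supported; skipping cluster models\n")
}
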