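#!/usr/bin/env Rscript

## Stage 2 — preprocessing to analysis scale.
##
## Memory: baseline z-scoring per dataset and test, a PC1 composite per
## dataset with frozen baseline loadings (low-rank imputation for missing
## cells), then residualization on a smooth of age, sex, practice dummies
## and subject intercepts. Brain: per-region GAMM deviation scores (sex +
## smooth age + dataset and subject intercepts), standardized per region.

library(longchange)

mem <- read_panel("results/memory_panel.tsv")
brain <- read_panel("results/brain_panel.tsv")

mem <- baseline_zscore(mem)
tests <- grep("^test_", names(mem), value = TRUE)
mem$memory <- NA_real_
for (d in unique(mem$dataset_id)) {
  in_d <- mem$dataset_id == d
  cm <- pca_composite(mem[in_d & mem$visit_index == 1, tests])
  mem$memory[in_d] <- predict_composite(cm, mem[in_d, tests])
  cat(sprintf("dataset %s: PC1 explains %.1f%% of baseline test variance\n",
              d, 100 * cm$var_explained))
}
mem_adj <- residualize_memory(mem)
for (d in names(attr(mem_adj, "models"))) {
  m <- attr(mem_adj, "models")[[d]]
  cat(sprintf("dataset %s: retest bumps %.2f (visit 2) %.2f (visit 3+)\n",
              d, m$retest1, m$retest2))
}

devs <- brain_deviation_scores(brain)
write_panel(mem_adj, "results/memory_adjusted.tsv",
            provenance = c(stage = "harmonize"))
write_panel(devs, "results/brain_deviations.tsv",
            provenance = c(stage = "harmonize"))
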