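# subjects x regions change tables with planted correlation structure
factor_table <- function(n = 2000, p = 8, lambda = 0.5, blocks = NULL,
                         within_r = 0.7, seed = 1, memory_a = 0) {
  set.seed(seed)
  if (is.null(blocks)) {
    f <- rnorm(n)
    X <- lambda * matrix(f, n, p) +
      sqrt(1 - lambda^2) * matrix(rnorm(n * p), n, p)
  } else {
    X <- matrix(NA_real_, n, p)
    for (b in unique(blocks)) {
      ix <- which(blocks == b)
      fb <- rnorm(n)
      X[, ix] <- sqrt(within_r) * matrix(fb, n, length(ix)) +
        sqrt(1 - within_r) * matrix(rnorm(n * length(ix)), n, length(ix))
    }
  }
  tab <- data.frame(subject_id = sprintf("s%04d", 1:n),
                    dataset_id = sprintf("ds%02d", 1 + (1:n) %% 3),
                    baseline_age = runif(n, 40, 85),
                    d_memory = memory_a * rowMeans(X) + rnorm(n),
                    w_memory = 1)
  for (j in 1:p) {
    tab[[paste0("d_region_", j)]] <- X[, j]
    tab[[paste0("w_region_", j)]] <- 1
  }
  tab
}

test_that("change correlation matrix matches one-factor algebra", {
  tab <- factor_table(n = 5000, p = 8, lambda = 0.5, seed = 2)
  cc <- change_correlation(tab)
  C <- cc$matrix
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, 8))
  ## off-diagonal ~ lambda^2 = 0.25
  expect_lt(abs(cc$summary["mean"] - 0.25), 0.02)

  ## two independent blocks: near-zero between-block correlation
  tb <- factor_table(n = 4000, p = 6, blocks = rep(1:2, each = 3), seed = 3)
  Cb <- change_correlation(tb)$matrix
  between <- Cb[1:3, 4:6]
  expect_lt(mean(abs(between)), 0.05)

  tab$d_region_1 <- 0
  expect_error(change_correlation(tab), "zero variance")
})

test_that("PCA summary satisfies spectral identities and sign convention", {
  ## identity correlation: equal fractions
  p0 <- pca_summary(diag(5))
  expect_equal(p0$var_fraction, rep(0.2, 5))

  ## planted single factor with share s: PC1 fraction ~ s
  s <- 0.4
  p_reg <- 10
  lam <- sqrt((s * p_reg - 1) / (p_reg - 1))  # one-factor loading whose top
                                              # eigen-share equals s
  tab <- factor_table(n = 5000, p = p_reg, lambda = lam, seed = 4)
  ps <- pca_summary(tab)
  expect_lt(abs(ps$var_fraction[1] - s), 0.03)
  ## all loadings share the PC1 sign under an all-positive factor model
  expect_true(all(ps$loadings > 0))
  expect_equal(sum(ps$var_fraction), 1, tolerance = 1e-10)
  expect_gte(min(ps$eigenvalues), -1e-8)
})

test_that("consensus clustering recovers planted partitions and is deterministic", {
  blocks <- rep(1:3, each = 4)
  tab <- factor_table(n = 2000, p = 12, blocks = blocks, within_r = 0.7, seed = 5)
  sol <- consensus_cluster(tab, K_max = 5, reps = 50, null_reps = 50, seed = 9)
  expect_equal(sol$K_star, 3L)
  expect_lt(sol$stats$p[sol$stats$K == 3], 0.05)
  ## assignments reproduce the planted blocks up to label permutation
  asg <- sol$assignments
  expect_equal(length(unique(paste(blocks, asg))), 3)
  ## consensus stats are complete and PAC is a proportion
  expect_true(all(sol$stats$pac >= 0 & sol$stats$pac <= 1))
  ## determinism under the same seed
  sol2 <- consensus_cluster(tab, K_max = 5, reps = 50, null_reps = 50, seed = 9)
  expect_identical(sol$stats, sol2$stats)
  expect_identical(sol$assignments, sol2$assignments)
})

test_that("clustering is equivariant to region order for clear structure", {
  blocks <- rep(1:3, each = 4)
  tab <- factor_table(n = 1500, p = 12, blocks = blocks, within_r = 0.7, seed = 6)
  regs <- paste0("region_", 1:12)
  sol1 <- consensus_cluster(tab, regs, K_max = 4, reps = 30, null_reps = 30, seed = 3)
  perm <- c(7:12, 1:6)
  sol2 <- consensus_cluster(tab, regs[perm], K_max = 4, reps = 30, null_reps = 30,
                            seed = 3)
  ## the partition (not the labels) is identical after permutation
  part1 <- split(names(sol1$assignments), sol1$assignments)
  part2 <- split(names(sol2$assignments), sol2$assignments)
  norm <- function(p) unname(sort(vapply(p, function(g)
    paste(sort(g), collapse = "+"), "")))
  expect_identical(norm(part1), norm(part2))
})

test_that("guards: too few regions, K_max too large", {
  tab <- factor_table(n = 200, p = 3, seed = 7)
  expect_error(consensus_cluster(tab, K_max = 2), ">= 4 regions")
  tab8 <- factor_table(n = 200, p = 5, seed = 7)
  expect_error(consensus_cluster(tab8, K_max = 5), "K_max")
})

test_that("cluster-memory models recover joint contributions and shrink under control", {
  set.seed(8)
  n <- 2500
  f1 <- rnorm(n); f2 <- rnorm(n)
  tab <- data.frame(subject_id = sprintf("s%04d", 1:n),
                    dataset_id = sprintf("ds%02d", 1 + (1:n) %% 3),
                    baseline_age = runif(n, 40, 85),
                    d_memory = 0.3 * f1 + 0.2 * f2 + rnorm(n, 0, 0.8),
                    w_memory = 1)
  for (j in 1:3) { tab[[paste0("d_hc_", j)]] <- f1 + rnorm(n, 0, .5)
                   tab[[paste0("w_hc_", j)]] <- 1 }
  for (j in 1:3) { tab[[paste0("d_ot_", j)]] <- f2 + rnorm(n, 0, .5)
                   tab[[paste0("w_ot_", j)]] <- 1 }
  asg <- setNames(rep(1:2, each = 3), c(paste0("hc_", 1:3), paste0("ot_", 1:3)))
  cm <- cluster_memory_models(tab, asg, reference_cluster = 1, B = 99, seed = 10)
  joint <- cm$per_cluster[cm$per_cluster$family == "joint", ]
  ## both clusters contribute in the joint model
  expect_true(all(joint$p_boot < 0.05))
  expect_true(all(joint$beta_w > 0.05))
  ## controlling for the reference cluster keeps the second cluster's effect
  vsref <- cm$per_cluster[cm$per_cluster$family == "vs_reference", ]
  expect_lt(vsref$p_boot, 0.05)
  ## joint clusters explain at least as much as PC1 alone (up to tolerance)
  expect_gte(cm$joint_vs_pc1, -1e-3)
})

test_that("duplicate cluster scores are rejected as collinear", {
  tab <- factor_table(n = 500, p = 4, lambda = 0.4, seed = 11)
  ## two clusters with identical membership-driven scores
  tab$d_copy_1 <- tab$d_region_1; tab$w_copy_1 <- 1
  asg <- setNames(c(1, 2), c("region_1", "copy_1"))
  expect_error(cluster_memory_models(tab, asg), "collinear|>= 2 clusters|identical")
})

test_that("one-factor cohorts: PC1 control shrinks cluster effects", {
  tab <- factor_table(n = 2500, p = 8, lambda = 0.6, seed = 12, memory_a = 0.4)
  asg <- setNames(rep(1:2, each = 4), paste0("region_", 1:8))
  cm <- cluster_memory_models(tab, asg, reference_cluster = 1, B = 99, seed = 13)
  pc1_rows <- cm$per_cluster[cm$per_cluster$family == "vs_pc1", ]
  joint_rows <- cm$per_cluster[cm$per_cluster$family == "joint", ]
  ## with a single global factor, PC1 absorbs the signal
  expect_lt(mean(abs(pc1_rows$beta_w)), mean(abs(joint_rows$beta_w)) + 0.05)
})
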