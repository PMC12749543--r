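make_panel <- function(df) {
  defaults <- data.frame(sex = "F", baseline_age = 60)
  cbind(df, defaults[rep(1, nrow(df)), , drop = FALSE], row.names = NULL)
}

test_that("baseline z-scoring uses first-visit parameters for all visits", {
  p <- make_panel(data.frame(
    subject_id = c("a", "b", "c", "a"), dataset_id = "d1",
    time = c(0, 0, 0, 2), visit_index = c(1, 1, 1, 2),
    score = c(1, 2, 3, 2)))
  z <- baseline_zscore(p, "score")
  expect_equal(z$score[1:3], c(-1, 0, 1))
  expect_equal(z$score[4], 0)  # follow-up equal to baseline mean

  p$score <- c(5, 5, 5, 7)
  expect_error(baseline_zscore(p, "score"), "degenerate.*score.*d1")
})

test_that("pca composite handles perfect correlation, bypass, and low-rank completion", {
  ## two perfectly correlated tests: PC1 explains everything
  s <- rnorm(40)
  cm <- pca_composite(cbind(t1 = s, t2 = 2 * s))
  expect_equal(cm$var_explained, 1, tolerance = 1e-10)
  expect_equal(abs(cor(cm$scores, s)), 1, tolerance = 1e-10)

  ## single test bypasses PCA: scores are its z-scores
  one <- pca_composite(cbind(t1 = s))
  expect_equal(one$scores, as.numeric(scale(s)), tolerance = 1e-12)

  ## exact rank-1 completion: X = s_i * l_j with one masked cell
  set.seed(4)
  sc <- rnorm(30); l <- c(1, 0.8, 0.6)
  X <- outer(sc, l)
  truth <- X[7, 2]
  X[7, 2] <- NA
  cm1 <- pca_composite(X, rank = 1)
  ## reconstruct the imputed cell from the model's completed scores/loadings
  rec <- cm1$scores[7] * cm1$loadings[2] + cm1$center[2]
  expect_equal(unname(rec), truth, tolerance = 1e-4)

  expect_error(pca_composite(rbind(c(NA, NA), c(1, 2))), "all-missing")
})

test_that("composite loadings follow the positive-mean sign convention", {
  set.seed(5)
  f <- rnorm(200)
  X <- cbind(a = f + rnorm(200, 0, .3), b = f + rnorm(200, 0, .3),
             c = f + rnorm(200, 0, .3))
  cm <- pca_composite(X)
  expect_gt(mean(cm$loadings), 0)
  expect_equal(sum(cm$loadings^2), 1, tolerance = 1e-10)
  ## frozen loadings reused for new visits; missing test contributes its mean
  sc <- predict_composite(cm, X[1:5, ])
  expect_equal(sc, cm$scores[1:5], tolerance = 1e-10)
})

sim_memory_panel <- function(n_subj = 800, waves = 3, retest = c(0.3, 0.1),
                             age_beta = 0, sex_beta = 0, noise = 0.3,
                             n_datasets = 1, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_subj)) {
    tt <- c(0, sort(runif(waves - 1, 1.5, 8)))
    age0 <- runif(1, 40, 80)
    sex <- sample(c("F", "M"), 1)
    lev <- rnorm(1)
    v <- seq_len(waves)
    score <- lev + age_beta * (age0 + tt - 60) + sex_beta * (sex == "M") +
      retest[1] * (v >= 2) + retest[2] * (v >= 3) + rnorm(waves, 0, noise)
    rows[[i]] <- data.frame(subject_id = sprintf("s%04d", i),
                            dataset_id = sprintf("d%d", 1 + i %% n_datasets),
                            sex = sex, baseline_age = age0, time = tt,
                            visit_index = v, memory = score)
  }
  do.call(rbind, rows)
}

test_that("memory residualization recovers planted retest effects", {
  p <- sim_memory_panel(n_subj = 2000, retest = c(0.3, 0.1), seed = 2)
  adj <- residualize_memory(p)
  m <- attr(adj, "models")[[1]]
  expect_lt(abs(m$retest1 - 0.3), 0.05)
  expect_lt(abs(m$retest2 - 0.1), 0.05)
  ## residual mean ~ 0 and no age correlation
  expect_lt(abs(mean(adj$memory_adj)), 1e-6)
  expect_lt(abs(cor(adj$memory_adj, adj$baseline_age + adj$time)), 0.05)
})

test_that("null-model limit: adjustment approximates within-subject demeaning", {
  p <- sim_memory_panel(n_subj = 500, retest = c(0, 0), age_beta = 0,
                        sex_beta = 0, seed = 3)
  adj <- residualize_memory(p)
  demeaned <- p$memory - ave(p$memory, p$subject_id)
  expect_lt(max(abs(adj$memory_adj - demeaned)), 0.05)
})

test_that("re-residualizing changes adjusted scores only marginally", {
  p <- sim_memory_panel(n_subj = 1000, retest = c(0.3, 0.1), age_beta = -0.01,
                        sex_beta = 0.2, seed = 4)
  adj <- residualize_memory(p)
  p2 <- adj
  p2$memory <- adj$memory_adj
  adj2 <- residualize_memory(p2)
  rms <- sqrt(mean((adj2$memory_adj - p2$memory)^2))
  expect_lt(rms, 0.05)
})

test_that("single-wave datasets are rejected", {
  p <- sim_memory_panel(n_subj = 30, waves = 3, seed = 5)
  p1 <- p[p$visit_index == 1, ]
  expect_error(residualize_memory(p1), "single wave")
})

test_that("brain deviations remove a known quadratic age trend", {
  ## trend-removal null: little subject heterogeneity, strong age curvature
  cfg <- cohort_config(n_subjects = 600, n_regions = 1, n_datasets = 2,
                       brain_aging = skew_normal_params(0, 0.05, 0),
                       subject_level_sd = 0.2, obs_noise_sd = 0.3,
                       age_trend = c(-0.03, -8e-4), sex_effect = 0.4,
                       dataset_offset_sd = 1, seed = 8)
  coh <- generate_cohort(cfg)
  devs <- brain_deviation_scores(coh$brain_panel)
  age <- devs$baseline_age + devs$time
  expect_equal(sd(devs$region_01), 1, tolerance = 1e-9)
  expect_lt(abs(cor(devs$region_01, age)), 0.05)
  expect_lt(abs(cor(devs$region_01, (age - 60)^2)), 0.05)
})

test_that("deviation scores agree with a two-stage cross-sectional oracle", {
  cfg <- cohort_config(n_subjects = 300, n_regions = 1, n_datasets = 2,
                       age_trend = c(-0.03, -8e-4), sex_effect = 0.4,
                       dataset_offset_sd = 1, seed = 8)
  coh <- generate_cohort(cfg)
  devs <- brain_deviation_scores(coh$brain_panel)
  oracle <- two_stage_deviation_oracle(coh$brain_panel, "region_01")
  expect_gt(cor(devs$region_01, oracle), 0.95)
})

test_that("identical datasets offset by a constant give identical deviations", {
  cfg <- cohort_config(n_subjects = 150, n_regions = 1, n_datasets = 1,
                       dataset_offset_sd = 0, age_trend = c(-0.01, 0), seed = 9)
  coh <- generate_cohort(cfg)
  p1 <- coh$brain_panel
  p2 <- p1
  p2$subject_id <- paste0(p1$subject_id, "_b")
  p2$dataset_id <- "ds99"
  p2$region_01 <- p1$region_01 + 5
  both <- rbind(p1, p2)
  devs <- brain_deviation_scores(both)
  d1 <- devs$region_01[devs$dataset_id != "ds99"]
  d2 <- devs$region_01[devs$dataset_id == "ds99"]
  expect_lt(max(abs(d1 - d2)), 1e-6)
  expect_error(brain_deviation_scores(transform(p1, region_01 = 1)), "zero variance")
})
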