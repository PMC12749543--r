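test_that("individual slopes match hand values and a brute-force minimizer", {
  s <- individual_slope(c(0, 2), c(0, 1))
  expect_equal(s$delta, 0.5)
  expect_equal(s$residual_var, 0)

  ## exactly collinear points
  s3 <- individual_slope(c(0, 1, 3), 2 - 0.4 * c(0, 1, 3))
  expect_equal(s3$delta, -0.4, tolerance = 1e-12)
  expect_equal(s3$residual_var, 0, tolerance = 1e-12)

  ## random 6-point panels vs grid-refined least-squares oracle
  set.seed(31)
  for (i in 1:20) {
    tt <- sort(runif(6, 0, 10))
    vv <- rnorm(6, 1 - 0.3 * tt, 0.5)
    expect_lt(abs(individual_slope(tt, vv)$delta -
                    ols_grid_oracle(tt, vv)["b"]), 1e-8)
  }
  expect_error(individual_slope(c(1, 1), c(0, 1)), "times")
  expect_error(individual_slope(3, 5), "2 observations")
})

test_that("growth-rate reliability follows the variance-ratio formula", {
  expect_equal(slope_reliability(c(0, 1, 2), 0, 0.04), 1)
  expect_equal(slope_reliability(c(0, 1, 2), 0.16, 0), 0)
  ## hand-evaluated: Sxx for times 0..3 is 5
  expect_equal(slope_reliability(c(0, 1, 2, 3), 0.16, 0.04),
               0.04 / (0.04 + 0.16 / 5), tolerance = 1e-12)
  expect_error(slope_reliability(c(0, 1), -1, 0.1), "non-negative")
})

test_that("weights are squared reliabilities floored at 0.09", {
  expect_equal(reliability_weight(1), 1)
  expect_equal(reliability_weight(0.3), 0.09)
  expect_equal(reliability_weight(0.2), 0.09)   # below the floor
  expect_equal(reliability_weight(0.5), 0.25)
  expect_error(reliability_weight(1.2), "\\[0, 1\\]")
  ## monotone non-decreasing in reliability, bounded in [0.09, 1]
  r <- seq(0, 1, by = 0.01)
  w <- reliability_weight(r)
  expect_true(all(diff(w) >= 0))
  expect_gte(min(w), 0.09)
  expect_lte(max(w), 1)
})

make_adj_panels <- function(coh) {
  mem <- coh$memory_panel
  mem$memory_adj <- ave(mem$test_1, mem$subject_id,
                        FUN = function(x) x - mean(x))
  brain <- coh$brain_panel
  list(brain = brain, mem = mem)
}

test_that("noiseless cohorts give exact slopes and full reliability", {
  coh <- generate_cohort(noiseless_config(n_subjects = 60, seed = 13))
  pp <- make_adj_panels(coh)
  ct <- build_change_table(pp$brain, pp$mem, subjects = coh$truth)
  tr <- coh$truth[match(ct$subject_id, coh$truth$subject_id), ]
  ## z-standardized within dataset, so compare via correlation per dataset
  for (d in unique(ct$dataset_id)) {
    in_d <- ct$dataset_id == d
    expect_equal(cor(ct$d_region_01[in_d], tr$slope_region_01[in_d]), 1,
                 tolerance = 1e-8)
  }
  expect_equal(unname(ct$w_region_01), rep(1, nrow(ct)), tolerance = 1e-8)
})

test_that("short-span subjects are dropped and outliers removed cell-wise", {
  set.seed(41)
  n <- 400
  mk <- function(id, times, vals) {
    data.frame(subject_id = id, dataset_id = "d1", sex = "F",
               baseline_age = 60, time = times,
               visit_index = seq_along(times), m = vals)
  }
  rows <- list()
  for (i in seq_len(n)) {
    tt <- c(0, 2, 4)
    rows[[i]] <- mk(sprintf("s%03d", i), tt, rnorm(1) - 0.1 * tt + rnorm(3, 0, .2))
  }
  ## one short-span subject
  rows[[n + 1]] <- mk("short", c(0, 1.0), c(0, 0))
  brain <- do.call(rbind, rows)
  mem <- brain
  mem$memory_adj <- mem$m + rnorm(nrow(mem), 0, .1)
  mem$m <- NULL
  ct <- build_change_table(brain, mem)
  expect_false("short" %in% ct$subject_id)
  expect_equal(nrow(ct), n)

  ## inject a 10-SD change value: exactly one cell removed
  brain2 <- brain
  fast <- brain2$subject_id == "s001"
  brain2$m[fast] <- 10 * sd(tapply(brain2$m, brain2$subject_id, function(x) x[1])) *
    c(0, 2, 4) * 3
  ct2 <- build_change_table(brain2, mem)
  expect_equal(sum(is.na(ct2$d_m)) - sum(is.na(ct$d_m)), 1)
  expect_true(is.na(ct2$d_m[ct2$subject_id == "s001"]))
})

test_that("ventricle sign reversal flips the change direction", {
  coh <- generate_cohort(cohort_config(n_subjects = 80, n_regions = 2,
                                       n_datasets = 2, seed = 17))
  pp <- make_adj_panels(coh)
  pp$brain$region_02 <- -pp$brain$region_01  # a 'ventricle' mirror
  ct <- build_change_table(pp$brain, pp$mem,
                           ventricle_measures = "region_02")
  expect_equal(cor(ct$d_region_01, ct$d_region_02, use = "complete.obs"), 1,
               tolerance = 1e-8)
})

test_that("change columns are standardized within dataset", {
  coh <- generate_cohort(cohort_config(n_subjects = 150, n_regions = 2,
                                       n_datasets = 3, seed = 19))
  pp <- make_adj_panels(coh)
  ct <- build_change_table(pp$brain, pp$mem)
  for (d in unique(ct$dataset_id)) {
    z <- ct$d_region_01[ct$dataset_id == d]
    expect_lt(abs(mean(z, na.rm = TRUE)), 1e-8)
    expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-8)
  }
  expect_true(all(abs(ct$d_region_01) <= 4.5 + 1e-8, na.rm = TRUE))
})

test_that("overlap rule excludes subjects with > 10 year modality gaps", {
  mk <- function(id, age, times, col, vals) {
    out <- data.frame(subject_id = id, dataset_id = "d1", sex = "F",
                      baseline_age = age, time = times,
                      visit_index = seq_along(times))
    out[[col]] <- vals
    out
  }
  brain <- do.call(rbind, lapply(1:30, function(i)
    mk(paste0("s", i), 50, c(0, 2, 4), "m", rnorm(3))))
  mem <- do.call(rbind, lapply(1:30, function(i)
    mk(paste0("s", i), 50, c(0, 2, 4), "memory_adj", rnorm(3))))
  ## one subject whose memory window sits 15 years after the brain window
  mem$baseline_age[mem$subject_id == "s1"] <- 50 + 4 + 15
  ct <- build_change_table(brain, mem)
  expect_false("s1" %in% ct$subject_id)
  expect_equal(nrow(ct), 29)
})

test_that("estimated weights rise with planted follow-up span and visit count", {
  spans <- c(2, 5, 8); visits <- c(3, 5, 9)
  mean_w <- matrix(NA_real_, 3, 3)
  seed <- 53
  for (a in 1:3) for (b in 1:3) {
    set.seed(seed + 10 * a + b)
    tt <- seq(0, spans[a], length.out = visits[b])
    n <- 200
    rows <- lapply(seq_len(n), function(i) {
      out <- data.frame(subject_id = sprintf("s%03d", i), dataset_id = "d1",
                        sex = "F", baseline_age = 60, time = tt,
                        visit_index = seq_along(tt))
      sl <- rnorm(1, 0, 0.2)
      out$m <- rnorm(1) + sl * tt + rnorm(length(tt), 0, 0.3)
      out$memory_adj <- rnorm(1) + sl * tt + rnorm(length(tt), 0, 0.3)
      out
    })
    panel <- do.call(rbind, rows)
    ct <- build_change_table(panel[, setdiff(names(panel), "memory_adj")],
                             panel[, setdiff(names(panel), "m")])
    mean_w[a, b] <- mean(ct$w_m, na.rm = TRUE)
  }
  expect_true(all(apply(mean_w, 2, diff) > 0))  # longer span -> larger weight
  expect_true(all(apply(mean_w, 1, diff) > 0))  # more visits -> larger weight
})
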