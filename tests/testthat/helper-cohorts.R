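# shared fixture builders (all generated in code at test time)

noiseless_config <- function(n_subjects = 40, seed = 11) {
  cohort_config(n_subjects = n_subjects, n_datasets = 2, n_regions = 3,
                obs_noise_sd = 0, mem_noise_sd = 0, retest_effects = c(0, 0),
                age_trend = c(0, 0), sex_effect = 0, dataset_offset_sd = 0,
                visits_range = c(3, 5), span_range = c(2, 8), seed = seed)
}

# change-table-level cohort: latent slope + observation noise -> change
# scores directly, for estimand-layer tests (assoc / moderation / APOE)
direct_change_table <- function(n = 1000, a = 0.3, sn = skew_normal_params(0.16, 0.3, -4),
                                noise_sd = 0.3, mem_noise_sd = 0.15,
                                n_datasets = 4, age_range = c(40, 85),
                                age_dispersion_slope = 0, carrier_fraction = 0,
                                carrier_shift = 0, weights = "reliability",
                                seed = 1, standardize = TRUE) {
  set.seed(seed)
  age <- runif(n, age_range[1], age_range[2])
  om <- sn$omega * pmax(1 + age_dispersion_slope * (age - 60), 0.05)
  d <- sn$delta
  true <- sn$xi + om * (d * abs(rnorm(n)) + sqrt(1 - d^2) * rnorm(n))
  carrier <- runif(n) < carrier_fraction
  true <- true + carrier_shift * carrier
  obs <- true + rnorm(n, 0, noise_sd)
  mem <- a * true + rnorm(n, 0, mem_noise_sd)
  w <- if (identical(weights, "reliability")) {
    rel <- runif(n, 0.4, 1)
    reliability_weight(rel)
  } else rep(1, n)
  tab <- data.frame(subject_id = sprintf("s%04d", seq_len(n)),
                    dataset_id = sprintf("ds%02d", 1 + (seq_len(n) - 1) %% n_datasets),
                    baseline_age = age, sex = sample(c("F", "M"), n, TRUE),
                    apoe = carrier,
                    d_memory = if (standardize) as.numeric(scale(mem)) else mem,
                    w_memory = w,
                    d_region = if (standardize) as.numeric(scale(obs)) else obs,
                    w_region = w, stringsAsFactors = FALSE)
  attr(tab, "true") <- true
  tab
}
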