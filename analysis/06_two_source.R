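#!/usr/bin/env Rscript

## Stage 6 — the two-source explanation of the nonlinear pattern.
##
## Observed brain change = skew-normal latent aging + Gaussian noise;
## memory change linearly coupled to the latent component. Reproduces the
## flattening of the observed association among brain maintainers and the
## moment sweeps: dispersion strengthens the association, mean and
## (moment-matched) skewness do not, despite steeper mean decline.

library(longchange)

base <- two_source_params(n = 1000, reps = 200)  # reps: 1000 in a full run

sim <- simulate_two_source(base, seed = 66)
fc <- fit_observed_curve(sim)
lo <- mean(fc$derivative_mean[fc$grid < median(sim$obs_brain)], na.rm = TRUE)
hi <- mean(fc$derivative_mean[fc$grid >= median(sim$obs_brain)], na.rm = TRUE)
cat(sprintf("mean association below / above median observed change: %.3f / %.3f\n",
            lo, hi))
curve_tab <- data.frame(obs_brain = fc$grid, derivative = fc$derivative_mean,
                        lo = fc$derivative_band[1, ], hi = fc$derivative_band[2, ],
                        fitted = fc$fitted_mean)
write_panel(curve_tab, "results/two_source_curve.tsv",
            provenance = c(stage = "twosource"))

sweeps <- rbind(
  moment_sweep(base, "dispersion", c(0.15, 0.30, 0.60), seed = 67),
  moment_sweep(base, "mean", base$brain_aging$xi + c(-0.15, 0, 0.15), seed = 68),
  moment_sweep(base, "skewness", c(0, -3, -6), seed = 69))
write_panel(sweeps, "results/sweep_summary.tsv", provenance = c(stage = "twosource"))
print(sweeps[, c("moment", "value", "beta_decliner", "beta_maintainer",
                 "mean_obs", "mean_memory")], digits = 3)
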