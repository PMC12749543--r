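#' Configuration for the synthetic multi-cohort generator
#'
#' Describes a stated world with the statistical structure the change-change
#' analysis assumes: per-subject linear latent decline with a negatively
#' skewed cross-subject distribution, a shared global decline factor plus
#' regional cluster factors, linear coupling of latent brain decline to
#' memory change, Gaussian observation noise, practice (retest) effects on
#' memory, site offsets, variable follow-up (>= 2 visits spanning >= 1.5
#' years) and optional APOE-e4 carrier shifts in decline parameters.
#'
#' Default magnitudes (documented in the methods vignette): latent global
#' decline with mean about -0.05 z/yr, SD about 0.20 z/yr and strong negative
#' skew; observation noise 0.3 z per visit; retest bumps +0.25 z at the
#' second visit and a further +0.10 z from the third; 27.8% APOE-e4 carriers.
#'
#' @param n_subjects number of subjects.
#' @param n_datasets number of datasets (sites); subjects are spread evenly.
#' @param age_range baseline age range in years, `c(min, max)`.
#' @param n_regions number of brain regions.
#' @param region_names optional region names (default `region_01`, ...).
#' @param cluster_map region -> cluster labels, length `n_regions`. Default
#'   splits the regions into two clusters.
#' @param global_loading loading of each region on the global decline factor
#'   (scalar or length `n_regions`).
#' @param cluster_sd SD (z/yr) of the per-subject cluster factors.
#' @param region_sd SD (z/yr) of the region-specific slope deviations.
#' @param brain_aging [skew_normal_params()] for the global latent yearly
#'   decline factor.
#' @param coupling_a linear coupling of latent memory slope to the global
#'   decline factor (memory z per brain z).
#' @param mem_noise_sd SD (z/yr) of the memory-slope noise.
#' @param obs_noise_sd SD (z) of per-visit observation noise, both modalities.
#' @param retest_effects length-2 numeric: memory practice bump at visit 2,
#'   and the additional bump from visit 3 onwards.
#' @param n_memory_tests number of memory tests observed per visit.
#' @param test_loadings loadings of each test on the latent memory trait.
#' @param visits_range integer range of visits per subject (min >= 2).
#' @param span_range follow-up span range in years (min >= 1.5).
#' @param apoe list with `carrier_fraction` in [0,1], `xi_shift` (z/yr),
#'   `omega_factor` (> 0), `alpha_shift`, and `regions` (names of regions
#'   whose slope deviations are shifted in carriers).
#' @param age_dispersion_slope per-year multiplier on the global factor's
#'   scale: `omega(age) = omega * (1 + age_dispersion_slope * (age - 60))`.
#' @param age_trend length-2 numeric `c(linear, quadratic)` normative age
#'   effect (z per year, z per year^2 around age 60) added to observed values.
#' @param sex_effect additive offset for males (z).
#' @param dataset_offset_sd SD of per-(dataset, measure) additive offsets.
#' @param subject_level_sd SD of subject baseline levels.
#' @param seed integer seed; all randomness flows from it via per-subject
#'   streams indexed by subject ordinal.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_subjects = 1000,
                          n_datasets = 4,
                          age_range = c(30, 89),
                          n_regions = 8,
                          region_names = NULL,
                          cluster_map = NULL,
                          global_loading = 0.6,
                          cluster_sd = 0.08,
                          region_sd = 0.1,
                          brain_aging = skew_normal_params(0.18, 0.30, -3),
                          coupling_a = 0.3,
                          mem_noise_sd = 0.15,
                          obs_noise_sd = 0.3,
                          retest_effects = c(0.25, 0.10),
                          n_memory_tests = 3,
                          test_loadings = NULL,
                          visits_range = c(2, 6),
                          span_range = c(1.5, 11),
                          apoe = list(carrier_fraction = 0.278, xi_shift = 0,
                                      omega_factor = 1, alpha_shift = 0,
                                      regions = character(0)),
                          age_dispersion_slope = 0,
                          age_trend = c(-0.015, -3e-4),
                          sex_effect = 0.2,
                          dataset_offset_sd = 0.5,
                          subject_level_sd = 1,
                          seed = 1) {
  stopifnot(n_subjects >= 1, n_datasets >= 1, n_regions >= 1,
            length(age_range) == 2, age_range[1] < age_range[2],
            length(visits_range) == 2, length(span_range) == 2,
            length(retest_effects) == 2, n_memory_tests >= 1)
  if (visits_range[1] < 2) stop("`visits_range` minimum must be >= 2", call. = FALSE)
  if (span_range[1] < 1.5) stop("`span_range` minimum must be >= 1.5 years", call. = FALSE)
  if (is.null(region_names))
    region_names <- sprintf("region_%02d", seq_len(n_regions))
  stopifnot(length(region_names) == n_regions, !anyDuplicated(region_names))
  if (is.null(cluster_map))
    cluster_map <- paste0("c", 1 + (seq_len(n_regions) - 1) %/% ceiling(n_regions / 2))
  if (length(cluster_map) != n_regions)
    stop("`cluster_map` must have one entry per region", call. = FALSE)
  global_loading <- rep_len(global_loading, n_regions)
  if (!all(is.finite(global_loading))) stop("loadings must be finite", call. = FALSE)
  if (is.null(test_loadings))
    test_loadings <- seq(0.9, 0.7, length.out = n_memory_tests)
  test_loadings <- rep_len(test_loadings, n_memory_tests)
  apoe <- utils::modifyList(list(carrier_fraction = 0, xi_shift = 0,
                                 omega_factor = 1, alpha_shift = 0,
                                 regions = character(0)), as.list(apoe))
  if (apoe$carrier_fraction < 0 || apoe$carrier_fraction > 1)
    stop("`apoe$carrier_fraction` must be in [0, 1]", call. = FALSE)
  if (!all(apoe$regions %in% region_names))
    stop("`apoe$regions` must name regions in `region_names`", call. = FALSE)
  cfg <- list(n_subjects = as.integer(n_subjects), n_datasets = as.integer(n_datasets),
              age_range = age_range, n_regions = as.integer(n_regions),
              region_names = region_names, cluster_map = as.character(cluster_map),
              global_loading = global_loading, cluster_sd = cluster_sd,
              region_sd = region_sd, brain_aging = as_skewnorm_params(brain_aging),
              coupling_a = coupling_a, mem_noise_sd = mem_noise_sd,
              obs_noise_sd = obs_noise_sd, retest_effects = retest_effects,
              n_memory_tests = as.integer(n_memory_tests), test_loadings = test_loadings,
              visits_range = as.integer(visits_range), span_range = span_range,
              apoe = apoe, age_dispersion_slope = age_dispersion_slope,
              age_trend = age_trend, sex_effect = sex_effect,
              dataset_offset_sd = dataset_offset_sd, subject_level_sd = subject_level_sd,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

## deterministic per-subject stream: independent of how many draws other
## subjects consume, so generation is reproducible under parallel evaluation
subject_seed <- function(seed, i, salt = 0L) {
  as.integer((as.numeric(seed) * 48271 + i * 131 + salt * 7907) %% 2147483629)
}

draw_schedule <- function(visits_range, span_range) {
  vv <- seq(visits_range[1], visits_range[2])
  nv <- if (length(vv) == 1L) vv else sample(vv, 1L)
  span <- stats::runif(1, span_range[1], span_range[2])
  if (nv == 2L) return(c(0, span))
  c(0, sort(stats::runif(nv - 2L, 0.05, 0.95)) * span, span)
}

#' Draw per-subject visit schedules
#'
#' Each schedule starts at time 0, is strictly increasing, has between
#' `visits_range[1]` and `visits_range[2]` visits and spans between
#' `span_range[1]` (>= 1.5 years, the minimum follow-up the analysis
#' retains) and `span_range[2]` years.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return List of numeric vectors of visit times (years from baseline).
#' @export
assign_visit_schedule <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$span_range[1] < 1.5)
    stop("`span_range` minimum must be >= 1.5 years", call. = FALSE)
  lapply(seq_len(config$n_subjects), function(i) {
    set.seed(subject_seed(seed, i, salt = 1L))
    draw_schedule(config$visits_range, config$span_range)
  })
}

norm_age_trend <- function(age, age_trend) {
  a <- age - 60
  age_trend[1] * a + age_trend[2] * a^2
}

#' Generate a synthetic multi-cohort longitudinal panel pair
#'
#' Simulates the generative structure the downstream analysis assumes. Per
#' subject i, a global latent yearly decline `g_i` is drawn skew-normal (scale
#' optionally widening with baseline age); region slopes are
#' `loading_r * g_i + cluster factor + region deviation`; the latent memory
#' slope is `coupling_a * g_i + noise`. Observations are
#' `normative age trend + sex offset + dataset offset + subject level +
#' slope * time + Gaussian noise`, with practice bumps added to memory tests
#' at visit 2 and from visit 3 onwards. APOE-e4 carriers optionally have the
#' region deviation of listed regions drawn from a shifted skew-normal.
#'
#' @param config a [cohort_config()].
#' @return List with `brain_panel` and `memory_panel` (long-format data
#'   frames: `subject_id`, `dataset_id`, `sex`, `baseline_age`, `time`,
#'   `visit_index`, one column per measure) and `truth` (per-subject latent
#'   table: global factor `g`, per-region slopes, `memory_slope`,
#'   `mem_noise` with `memory_slope = coupling_a * g + mem_noise` exactly,
#'   and `apoe_carrier`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  n <- cfg$n_subjects
  clusters <- unique(cfg$cluster_map)

  ## dataset x measure offsets drawn from the root seed
  set.seed(subject_seed(cfg$seed, 0L, salt = 2L))
  meas <- c(cfg$region_names, paste0("test_", seq_len(cfg$n_memory_tests)))
  ds_off <- matrix(stats::rnorm(cfg$n_datasets * length(meas), 0, cfg$dataset_offset_sd),
                   nrow = cfg$n_datasets, dimnames = list(NULL, meas))

  sn_g <- cfg$brain_aging
  R <- cfg$n_regions
  J <- cfg$n_memory_tests
  test_names <- paste0("test_", seq_len(J))

  ## pass 1: subject-level latents and schedules
  sid <- sprintf("s%05d", seq_len(n))
  ds_i <- 1L + (seq_len(n) - 1L) %% cfg$n_datasets
  sex_i <- character(n); age0_i <- numeric(n); carrier_i <- logical(n)
  g_i <- numeric(n); mslope_i <- numeric(n); mnoise_i <- numeric(n)
  slopes <- matrix(NA_real_, n, R, dimnames = list(NULL, cfg$region_names))
  lev_b <- matrix(NA_real_, n, R); lev_m <- numeric(n)
  t_brain <- vector("list", n); t_mem <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(subject_seed(cfg$seed, i, salt = 3L))
    sex_i[i] <- sample(c("F", "M"), 1L)
    age0_i[i] <- stats::runif(1, cfg$age_range[1], cfg$age_range[2])
    carrier_i[i] <- stats::runif(1) < cfg$apoe$carrier_fraction

    om_i <- sn_g$omega * max(1 + cfg$age_dispersion_slope * (age0_i[i] - 60), 0.05)
    g_i[i] <- sample_skew_normal(skew_normal_params(sn_g$xi, om_i, sn_g$alpha), 1L)
    cl_f <- stats::setNames(stats::rnorm(length(clusters), 0, cfg$cluster_sd), clusters)
    shifted <- carrier_i[i] & cfg$region_names %in% cfg$apoe$regions
    e_r <- numeric(R)
    for (r in seq_len(R)) {
      e_r[r] <- if (shifted[r]) {
        sample_skew_normal(skew_normal_params(cfg$apoe$xi_shift,
                                              max(cfg$region_sd * cfg$apoe$omega_factor, 1e-12),
                                              cfg$apoe$alpha_shift), 1L)
      } else stats::rnorm(1, 0, cfg$region_sd)
    }
    slopes[i, ] <- cfg$global_loading * g_i[i] + cl_f[cfg$cluster_map] + e_r
    mnoise_i[i] <- stats::rnorm(1, 0, cfg$mem_noise_sd)
    mslope_i[i] <- cfg$coupling_a * g_i[i] + mnoise_i[i]

    set.seed(subject_seed(cfg$seed, i, salt = 1L))
    t_brain[[i]] <- draw_schedule(cfg$visits_range, cfg$span_range)
    t_mem[[i]] <- draw_schedule(cfg$visits_range, cfg$span_range)

    set.seed(subject_seed(cfg$seed, i, salt = 4L))
    lev_b[i, ] <- stats::rnorm(R, 0, cfg$subject_level_sd)
    lev_m[i] <- stats::rnorm(1, 0, cfg$subject_level_sd)
  }
  sexoff_i <- ifelse(sex_i == "M", cfg$sex_effect, 0)

  ## pass 2: fill observation panels
  build_panel <- function(times, fill) {
    nv <- lengths(times)
    idx <- rep.int(seq_len(n), nv)
    v <- sequence(nv)
    tt <- unlist(times, use.names = FALSE)
    out <- data.frame(subject_id = sid[idx], dataset_id = sprintf("ds%02d", ds_i[idx]),
                      sex = sex_i[idx], baseline_age = age0_i[idx], time = tt,
                      visit_index = v, stringsAsFactors = FALSE)
    base <- norm_age_trend(out$baseline_age + tt, cfg$age_trend) + sexoff_i[idx]
    fill(out, idx, tt, v, base)
  }

  brain_panel <- build_panel(t_brain, function(out, idx, tt, v, base) {
    for (r in seq_len(R)) {
      set.seed(subject_seed(cfg$seed, r, salt = 5L))
      out[[cfg$region_names[r]]] <- base + ds_off[ds_i[idx], cfg$region_names[r]] +
        lev_b[idx, r] + slopes[idx, r] * tt +
        stats::rnorm(length(tt), 0, cfg$obs_noise_sd)
    }
    out
  })
  memory_panel <- build_panel(t_mem, function(out, idx, tt, v, base) {
    retest <- cfg$retest_effects[1] * (v >= 2) + cfg$retest_effects[2] * (v >= 3)
    latent <- lev_m[idx] + mslope_i[idx] * tt
    for (j in seq_len(J)) {
      set.seed(subject_seed(cfg$seed, j, salt = 6L))
      out[[test_names[j]]] <- base + ds_off[ds_i[idx], test_names[j]] +
        cfg$test_loadings[j] * latent + retest +
        stats::rnorm(length(tt), 0, cfg$obs_noise_sd)
    }
    out
  })

  truth <- data.frame(subject_id = sid, dataset_id = sprintf("ds%02d", ds_i),
                      sex = sex_i, baseline_age = age0_i, apoe_carrier = carrier_i,
                      g = g_i, memory_slope = mslope_i, mem_noise = mnoise_i,
                      stringsAsFactors = FALSE)
  truth[paste0("slope_", cfg$region_names)] <-
    lapply(seq_len(R), function(r) slopes[, r])

  list(brain_panel = brain_panel, memory_panel = memory_panel, truth = truth)
}

#' Write / read long-format panels as TSV
#'
#' Tab-separated, header row, UTF-8, "." decimal, missing cells empty.
#' An optional provenance comment line ("# key=value ...") is written first
#' and skipped on read.
#'
#' @param panel data frame to write.
#' @param path file path.
#' @param provenance optional named character vector recorded as a comment.
#' @return `write_panel` returns `path` invisibly; `read_panel` the data frame.
#' @export
write_panel <- function(panel, path, provenance = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", paste(names(provenance), provenance,
                                  sep = "=", collapse = " ")), con)
  utils::write.table(panel, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#", na.strings = c("", "NA"),
                    stringsAsFactors = FALSE)
}
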