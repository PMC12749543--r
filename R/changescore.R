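#' Per-subject yearly change by ordinary least squares
#'
#' Regresses a subject's observations on follow-up time and returns the
#' slope (z-units/year) and the residual variance `RSS / max(n - 2, 1)`.
#'
#' @param times visit times in years (>= 2 distinct values).
#' @param values observed values (same length).
#' @return List with `delta`, `residual_var`, `n_obs`, `span` and `sxx`
#'   (`sum((t - mean(t))^2)`, the slope's design information).
#' @export
individual_slope <- function(times, values) {
  keep <- !is.na(times) & !is.na(values)
  times <- times[keep]; values <- values[keep]
  n <- length(times)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  if (length(unique(times)) < 2) stop("all times equal; slope undefined", call. = FALSE)
  tc <- times - mean(times)
  sxx <- sum(tc^2)
  b <- sum(tc * values) / sxx
  a <- mean(values) - b * mean(times)
  rss <- sum((values - a - b * times)^2)
  list(delta = b, residual_var = rss / max(n - 2, 1), n_obs = n,
       span = max(times) - min(times), sxx = sxx)
}

#' Growth-rate reliability of an individual slope
#'
#' `reliability = between_slope_var / (between_slope_var +
#' residual_var / sum((t - mean(t))^2))`, clipped to `[0, 1]`: the share of
#' between-person slope variance attributable to true slope differences
#' rather than sampling error. Longer and denser follow-up increases
#' `sum((t - mean(t))^2)` and hence reliability.
#'
#' @param times visit times in years (>= 2 distinct).
#' @param residual_var within-person residual variance around the line
#'   (>= 0); typically pooled over subjects within dataset x measure.
#' @param between_slope_var between-person variance of true slopes (>= 0).
#' @return Reliability in `[0, 1]`.
#' @export
slope_reliability <- function(times, residual_var, between_slope_var) {
  if (residual_var < 0 || between_slope_var < 0)
    stop("variances must be non-negative", call. = FALSE)
  times <- times[!is.na(times)]
  if (length(unique(times)) < 2) stop("need >= 2 distinct times", call. = FALSE)
  sxx <- sum((times - mean(times))^2)
  samp <- residual_var / sxx
  if (between_slope_var == 0) return(0)
  min(max(between_slope_var / (between_slope_var + samp), 0), 1)
}

#' Analysis weight from reliability
#'
#' The analysis weight is the squared reliability, floored at 0.09 (the
#' weight corresponding to a longitudinal reliability of 0.3).
#'
#' @param reliability value in `[0, 1]`.
#' @return Weight in `[0.09, 1]`.
#' @export
reliability_weight <- function(reliability) {
  if (any(!is.finite(reliability)) || any(reliability < 0) || any(reliability > 1))
    stop("reliability must be in [0, 1]", call. = FALSE)
  pmax(reliability^2, 0.09)
}

slopes_by_subject <- function(panel, measure, min_obs = 2, min_span = 1.5) {
  keep <- !is.na(panel[[measure]])
  sp <- split(seq_len(nrow(panel))[keep], panel$subject_id[keep])
  out <- lapply(sp, function(ix) {
    tt <- panel$time[ix]
    if (length(ix) < min_obs || length(unique(tt)) < 2 ||
        (max(tt) - min(tt)) < min_span) return(NULL)
    individual_slope(tt, panel[[measure]][ix])
  })
  out[!vapply(out, is.null, logical(1))]
}

## method-of-moments growth-rate reliability for a set of subjects sharing a
## (dataset, measure) cell: residual variance pooled over subjects with >= 3
## observations (a 2-visit subject has zero residual by construction), and
## between-subject slope variance = max(0, var(delta) - mean sampling var)
grr_for_cell <- function(slopes) {
  deltas <- vapply(slopes, `[[`, 0, "delta")
  sxx <- vapply(slopes, `[[`, 0, "sxx")
  nobs <- vapply(slopes, `[[`, 0, "n_obs")
  rv <- vapply(slopes, `[[`, 0, "residual_var")
  df <- pmax(nobs - 2, 0)
  pooled_rv <- if (sum(df) > 0) sum(rv * df) / sum(df) else mean(rv)
  samp <- pooled_rv / sxx
  between <- max(0, stats::var(deltas) - mean(samp))
  rel <- if (between == 0) rep(0, length(deltas)) else
    pmin(pmax(between / (between + samp), 0), 1)
  list(delta = deltas, reliability = rel, weight = reliability_weight(rel),
       pooled_rv = pooled_rv, between = between)
}

std_within <- function(x, g) {
  mu <- stats::ave(x, g, FUN = function(v) mean(v, na.rm = TRUE))
  s <- stats::ave(x, g, FUN = function(v) stats::sd(v, na.rm = TRUE))
  (x - mu) / s
}

#' Build the one-row-per-subject change table
#'
#' Applies, in order: (1) keep subjects with >= `min_obs` observations
#' spanning >= `min_span` years in each modality; (2) require overlapping
#' brain/memory follow-up windows, excluding gaps > `max_gap` years;
#' (3) compute per-subject yearly-change slopes with growth-rate-reliability
#' weights (reliability pooled per dataset x measure); (4) sign-reverse
#' measures flagged as ventricles so that, for every measure, negative
#' change means decline; (5) z-standardize each change column within
#' dataset; (6) remove cells beyond `outlier_z` SD (set missing) and
#' re-standardize once. Missing cells propagate as row-wise missing for the
#' affected models only.
#'
#' @param brain_devs brain deviation panel (from [brain_deviation_scores()]).
#' @param memory_adj memory panel with a `memory_adj` column (from
#'   [residualize_memory()]).
#' @param subjects optional per-subject table with `subject_id` and
#'   `apoe_carrier` columns.
#' @param ventricle_measures names of measures to sign-reverse.
#' @param min_obs,min_span,max_gap,outlier_z filtering parameters (defaults:
#'   2 observations, 1.5 years, 10 years, 4.5 SD).
#' @return Data frame of class `change_table`: `subject_id`, `dataset_id`,
#'   `baseline_age`, `sex`, optional `apoe`, `d_memory`, `w_memory`, and
#'   `d_<region>` / `w_<region>` per region.
#' @export
build_change_table <- function(brain_devs, memory_adj, subjects = NULL,
                               ventricle_measures = character(0),
                               min_obs = 2, min_span = 1.5, max_gap = 10,
                               outlier_z = 4.5) {
  regions <- panel_measures(brain_devs)
  stopifnot("memory_adj" %in% names(memory_adj))

  mem_slopes <- slopes_by_subject(memory_adj, "memory_adj", min_obs, min_span)
  brain_sl <- lapply(regions, function(r) slopes_by_subject(brain_devs, r, min_obs, min_span))
  names(brain_sl) <- regions
  ## modality-level retention: a subject needs memory and >= 1 region
  brain_ids <- unique(unlist(lapply(brain_sl, names)))
  ids <- intersect(names(mem_slopes), brain_ids)

  ## overlap of follow-up windows (absolute age), two-clause rule
  win <- function(panel, id_set) {
    sp <- split(panel$baseline_age + panel$time, panel$subject_id)
    sp <- sp[id_set]
    cbind(lo = vapply(sp, min, 0), hi = vapply(sp, max, 0))
  }
  if (length(ids)) {
    wb <- win(brain_devs, ids); wm <- win(memory_adj, ids)
    gap <- pmax(wb[, "lo"] - wm[, "hi"], wm[, "lo"] - wb[, "hi"], 0)
    ids <- ids[gap <= max_gap]
  }
  if (!length(ids)) stop("no subjects survive the change-table filters", call. = FALSE)

  meta <- brain_devs[!duplicated(brain_devs$subject_id),
                     c("subject_id", "dataset_id", "sex", "baseline_age")]
  tab <- meta[match(ids, meta$subject_id), ]
  rownames(tab) <- NULL
  if (!is.null(subjects) && "apoe_carrier" %in% names(subjects))
    tab$apoe <- subjects$apoe_carrier[match(ids, subjects$subject_id)]

  add_measure <- function(tab, slopes, col) {
    d <- rep(NA_real_, nrow(tab)); w <- rep(NA_real_, nrow(tab))
    have <- intersect(names(slopes), ids)
    for (dset in unique(tab$dataset_id)) {
      cell_ids <- intersect(have, tab$subject_id[tab$dataset_id == dset])
      if (length(cell_ids) < 2) next
      cell <- grr_for_cell(slopes[cell_ids])
      ix <- match(cell_ids, tab$subject_id)
      d[ix] <- cell$delta
      w[ix] <- cell$weight
    }
    tab[[paste0("d_", col)]] <- d
    tab[[paste0("w_", col)]] <- w
    tab
  }
  tab <- add_measure(tab, mem_slopes, "memory")
  for (r in regions) tab <- add_measure(tab, brain_sl[[r]], r)

  dcols <- paste0("d_", c("memory", regions))
  for (r in intersect(ventricle_measures, regions))
    tab[[paste0("d_", r)]] <- -tab[[paste0("d_", r)]]
  for (cc in dcols) {
    z <- std_within(tab[[cc]], tab$dataset_id)
    z[abs(z) > outlier_z] <- NA_real_
    tab[[cc]] <- std_within(z, tab$dataset_id)
  }
  class(tab) <- c("change_table", class(tab))
  tab
}
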