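#' Region names present in a change table
#'
#' @param table a change table with `d_<region>` columns.
#' @return Character vector of region names (excluding memory).
#' @export
region_cols <- function(table) {
  sub("^d_", "", grep("^d_", names(table), value = TRUE)) |>
    setdiff("memory")
}

assoc_frame <- function(table, region, extra = character(0)) {
  dcol <- paste0("d_", region); wcol <- paste0("w_", region)
  stopifnot(dcol %in% names(table), wcol %in% names(table))
  dd <- data.frame(d_memory = table$d_memory, x = table[[dcol]],
                   w = table[[wcol]], dataset_id = factor(table$dataset_id),
                   baseline_age = table$baseline_age,
                   stringsAsFactors = FALSE)
  for (e in extra) dd[[e]] <- table[[e]]
  dd[stats::complete.cases(dd), , drop = FALSE]
}

#' Change-change association for one region
#'
#' Weighted penalized-spline model `d_memory ~ s(d_region) + dataset offset`,
#' with the region's reliability weights (predictor reliability drives
#' attenuation, so each region uses its own weight column). Returns the
#' density-weighted beta over the declining range (`d_region < 0`), the
#' smooth's effective degrees of freedom, the wild-bootstrap p-value against
#' a dataset-only null, and the partial variance explained.
#'
#' @param table a change table (see [build_change_table()]).
#' @param region region name (without the `d_` prefix).
#' @param B,seed wild-bootstrap replicates and seed.
#' @param min_n minimum complete cases (default 50).
#' @return One-row data frame: `region`, `beta_w`, `edf`, `p_boot`,
#'   `partial_r2`, `n`.
#' @export
regional_association <- function(table, region, B = 199, seed = 1, min_n = 50) {
  dd <- assoc_frame(table, region)
  if (nrow(dd) < min_n)
    stop(sprintf("region '%s': only %d complete cases (need >= %d)",
                 region, nrow(dd), min_n), call. = FALSE)
  full <- fit_wgam(stats::reformulate(c(smooth_term("x"), offset_term("dataset_id")),
                                      response = "d_memory"), dd, weights = "w")
  null <- fit_wgam(stats::reformulate(offset_term("dataset_id"),
                                      response = "d_memory"), dd, weights = "w")
  bt <- wild_bootstrap_p(full, null, B = B, seed = seed)
  data.frame(region = region,
             beta_w = density_weighted_beta(full, "x"),
             edf = term_edf(full, "s(x)"),
             p_boot = bt$p,
             partial_r2 = partial_r2(full, null),
             n = nrow(dd), stringsAsFactors = FALSE)
}

#' Change-change associations across regions with FDR correction
#'
#' Runs [regional_association()] for each region (complete cases per region,
#' so per-region n may differ) and adds Benjamini-Hochberg adjusted
#' p-values.
#'
#' @inheritParams regional_association
#' @param regions region names (default: all regions in the table).
#' @return Data frame with one row per region including `p_fdr`.
#' @export
regional_associations <- function(table, regions = region_cols(table),
                                  B = 199, seed = 1, min_n = 50) {
  res <- do.call(rbind, lapply(seq_along(regions), function(i)
    regional_association(table, regions[i], B = B, seed = seed + i, min_n = min_n)))
  res$p_fdr <- bh_fdr(res$p_boot)
  res
}

#' Age moderation of a change-change association
#'
#' Adds a `ti(d_region, baseline_age)` tensor interaction (plus a marginal
#' age smooth) to the regional model and tests it by wild bootstrap against
#' the additive null. The conditional association is summarized by the
#' density-weighted beta along `d_region` at fixed ages 40, 50, 60, 70 and
#' 80 years; ages outside the observed age support are reported missing
#' rather than extrapolated.
#'
#' @inheritParams regional_association
#' @param ages evaluation ages (years).
#' @return List with `result` (one-row data frame: `region`, `edf`,
#'   `p_boot`, `partial_r2`, `n`), `beta_by_age` (named vector) and the
#'   fitted `wgam`.
#' @export
age_moderation <- function(table, region, ages = c(40, 50, 60, 70, 80),
                           B = 199, seed = 1, min_n = 50) {
  dd <- assoc_frame(table, region)
  if (nrow(dd) < min_n) stop("insufficient complete cases for ", region, call. = FALSE)
  if (diff(range(dd$baseline_age)) < 20)
    warning("baseline age spread below 20 years; moderation weakly identified")
  full <- fit_tensor(dd, "d_memory", "x", "baseline_age", weights = "w",
                     offset_factor = "dataset_id")
  null <- fit_wgam(stats::reformulate(c(smooth_term("x"), smooth_term("baseline_age"),
                                        offset_term("dataset_id")),
                                      response = "d_memory"), dd, weights = "w")
  bt <- wild_bootstrap_p(full, null, B = B, seed = seed)
  sup <- range(dd$baseline_age)
  beta_by_age <- vapply(ages, function(a) {
    if (a < sup[1] || a > sup[2]) return(NA_real_)
    density_weighted_beta(full, "x", fixed = list(baseline_age = a))
  }, numeric(1))
  names(beta_by_age) <- paste0("age_", ages)
  list(result = data.frame(region = region,
                           edf = term_edf(full, "ti(x,baseline_age)"),
                           p_boot = bt$p,
                           partial_r2 = partial_r2(full, null),
                           n = nrow(dd), stringsAsFactors = FALSE),
       beta_by_age = beta_by_age, fit = full)
}

## mean derivative of the carrier-difference term over the observed domain,
## density weighted; for an effectively linear term (edf ~ 1) this is its
## slope over the full domain
diff_smooth_estimate <- function(full, edf, fixed_carrier) {
  dom <- if (edf <= 1.1) "full" else "negative"
  density_weighted_beta(full, "x", fixed = fixed_carrier, domain = dom)
}

#' APOE-e4 models: main effects and moderation
#'
#' Four weighted model families with dataset offsets throughout, carriers
#' coded 1:
#' \describe{
#' \item{main}{`d_region ~ apoe + dataset offset`: the carrier contrast on
#'   yearly brain change, with parametric 95% CI, t and p.}
#' \item{by_age}{`d_region ~ apoe + s(age) + s(age, by = ordered(apoe)) +
#'   dataset offset`: the carrier-difference smooth of age, tested by wild
#'   bootstrap.}
#' \item{by_dbrain}{`d_memory ~ apoe + s(d_region) + s(d_region, by =
#'   ordered(apoe)) + dataset offset`: does carrying e4 change the
#'   change-change coupling?}
#' \item{triple}{adds the marginal age terms and tests the carrier
#'   difference-tensor `ti(d_region, age, by = ordered(apoe))` as a block.}
#' }
#' For the smooth families the reported estimate is the mean derivative of
#' the carrier-difference term (its slope when effectively linear, edf = 1).
#'
#' @param table change table with an `apoe` column (logical or 0/1).
#' @param region region name.
#' @param B,seed wild-bootstrap settings for the smooth families.
#' @param min_carriers minimum carrier count (default 30).
#' @param families which model families to fit (default all four).
#' @return Data frame with one row per requested family: `family`,
#'   `estimate`, `ci_lo`, `ci_hi`, `t`, `p`, `edf`, `n`.
#' @export
apoe_models <- function(table, region, B = 199, seed = 1, min_carriers = 30,
                        families = c("main", "by_age", "by_dbrain", "triple")) {
  families <- match.arg(families, several.ok = TRUE)
  if (!"apoe" %in% names(table)) stop("no `apoe` column", call. = FALSE)
  dd <- assoc_frame(table, region, extra = "apoe")
  dd <- dd[!is.na(dd$apoe), , drop = FALSE]
  carr <- as.logical(dd$apoe)
  if (length(unique(carr)) < 2) stop("APOE has a single level", call. = FALSE)
  if (sum(carr) < min_carriers) stop("fewer than ", min_carriers, " carriers", call. = FALSE)
  dd$apoe_f <- factor(ifelse(carr, "carrier", "noncarrier"),
                      levels = c("noncarrier", "carrier"))
  dd$apoe_o <- as.ordered(dd$apoe_f)
  rows <- list()

  ## main: carrier contrast on yearly brain change
  if ("main" %in% families) {
    mfit <- fit_wgam(stats::reformulate(c("apoe_f", offset_term("dataset_id")),
                                        response = "x"), dd, weights = "w")
    ix <- which(names(stats::coef(mfit$fit)) == "apoe_fcarrier")
    cf <- stats::coef(mfit$fit)[ix]
    se <- sqrt(mfit$fit$Vp[ix, ix])
    tval <- cf / se
    rows$main <- data.frame(family = "main", estimate = unname(cf),
                            ci_lo = unname(cf - 1.96 * se),
                            ci_hi = unname(cf + 1.96 * se),
                            t = unname(tval),
                            p = 2 * stats::pnorm(-abs(unname(tval))),
                            edf = 1, n = nrow(dd))
  }

  smooth_family <- function(name, response, xvar, rhs_full, rhs_null, diff_label,
                            sd_off) {
    full <- fit_wgam(stats::reformulate(rhs_full, response = response), dd, weights = "w")
    null <- fit_wgam(stats::reformulate(rhs_null, response = response), dd, weights = "w")
    bt <- wild_bootstrap_p(full, null, B = B, seed = seed + sd_off)
    edf <- term_edf(full, diff_label)
    lv <- c("noncarrier", "carrier")
    fx <- function(level) list(apoe_o = factor(level, levels = lv, ordered = TRUE),
                               apoe_f = factor(level, levels = lv))
    dom <- if (edf <= 1.1) "full" else "negative"
    sup <- model_support(full, xvar)
    gr <- seq(sup[1], sup[1] + 0.999 * diff(sup), length.out = 200)
    eps <- 1e-3 * stats::sd(full$data[[xvar]])
    lp <- function(vals, fixed) stats::predict(
      full$fit, build_newdata(full, xvar, vals, fixed), type = "lpmatrix",
      newdata.guaranteed = TRUE)
    ## derivative of the carrier-minus-reference difference, as one linear
    ## functional of the coefficients: exact CI by covariance propagation
    D <- ((lp(gr + eps, fx("carrier")) - lp(gr - eps, fx("carrier"))) -
          (lp(gr + eps, fx("noncarrier")) - lp(gr - eps, fx("noncarrier")))) /
      (2 * eps)
    keep <- if (dom == "negative" && any(gr < 0)) gr < 0 else rep(TRUE, length(gr))
    dens <- stats::density(full$data[[xvar]], bw = "nrd0")
    K <- stats::approx(dens$x, dens$y, xout = gr[keep], rule = 2)$y
    cvec <- colSums(D[keep, , drop = FALSE] * K) / sum(K)
    est <- sum(cvec * stats::coef(full$fit))
    se <- sqrt(max(as.numeric(cvec %*% full$fit$Vp %*% cvec), 0))
    data.frame(family = name, estimate = est, ci_lo = est - 1.96 * se,
               ci_hi = est + 1.96 * se, t = est / se, p = bt$p, edf = edf,
               n = nrow(dd))
  }

  if ("by_age" %in% families) rows$by_age <- smooth_family(
    "by_age", "x", "baseline_age",
    c("apoe_f", smooth_term("baseline_age"),
      smooth_term("baseline_age", by = "apoe_o"), offset_term("dataset_id")),
    c("apoe_f", smooth_term("baseline_age"), offset_term("dataset_id")),
    "s(baseline_age):apoe_o", sd_off = 1)

  if ("by_dbrain" %in% families) rows$by_dbrain <- smooth_family(
    "by_dbrain", "d_memory", "x",
    c("apoe_f", smooth_term("x"), smooth_term("x", by = "apoe_o"),
      offset_term("dataset_id")),
    c("apoe_f", smooth_term("x"), offset_term("dataset_id")),
    "s(x):apoe_o", sd_off = 2)

  if ("triple" %in% families) rows$triple <- smooth_family(
    "triple", "d_memory", "x",
    c("apoe_f", smooth_term("x"), smooth_term("baseline_age"),
      tensor_term("x", "baseline_age"),
      smooth_term("x", by = "apoe_o"), smooth_term("baseline_age", by = "apoe_o"),
      tensor_term("x", "baseline_age", by = "apoe_o"), offset_term("dataset_id")),
    c("apoe_f", smooth_term("x"), smooth_term("baseline_age"),
      tensor_term("x", "baseline_age"),
      smooth_term("x", by = "apoe_o"), smooth_term("baseline_age", by = "apoe_o"),
      offset_term("dataset_id")),
    "ti(x,baseline_age):apoe_o", sd_off = 3)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-sample t-test of per-region effects against zero
#'
#' Used to ask whether an effect (e.g. the APOE-e4 carrier contrast on
#' yearly change) is globally non-zero across regions.
#'
#' @param effects one value per region (>= 3 values with positive SD).
#' @return List with `t`, `df`, `p` (two-sided) and `mean`.
#' @export
cross_region_effect_test <- function(effects) {
  x <- effects[is.finite(effects)]
  n <- length(x)
  if (n < 3) stop("need at least 3 region effects", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("effects are constant; t undefined", call. = FALSE)
  tval <- mean(x) / (s / sqrt(n))
  list(t = tval, df = n - 1, p = 2 * stats::pt(-abs(tval), n - 1), mean = mean(x))
}
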