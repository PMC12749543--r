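panel_measures <- function(panel) {
  setdiff(names(panel), c("subject_id", "dataset_id", "sex", "baseline_age",
                          "time", "visit_index"))
}

#' Z-score a panel on its baseline visits
#'
#' Per dataset and measure, the mean and SD of the first-visit values define
#' the transformation; all visits (baseline and follow-up) are transformed
#' with those baseline parameters, so baseline visits end up with mean 0 and
#' SD 1 and later visits are expressed on the baseline scale.
#'
#' @param panel long-format panel with a `visit_index` column.
#' @param measures measure columns to transform (default: all).
#' @return The panel with transformed measure columns.
#' @export
baseline_zscore <- function(panel, measures = panel_measures(panel)) {
  stopifnot(all(c("dataset_id", "visit_index") %in% names(panel)))
  for (d in unique(panel$dataset_id)) {
    in_d <- panel$dataset_id == d
    at_base <- in_d & panel$visit_index == 1L
    for (m in measures) {
      b <- panel[[m]][at_base]
      b <- b[!is.na(b)]
      if (length(b) < 2 || stats::sd(b) == 0)
        stop(sprintf("degenerate baseline for measure '%s' in dataset '%s'", m, d),
             call. = FALSE)
      panel[[m]][in_d] <- (panel[[m]][in_d] - mean(b)) / stats::sd(b)
    }
  }
  panel
}

#' First-principal-component composite with low-rank imputation
#'
#' Builds a single memory composite from a subjects x tests baseline table.
#' Missing cells are imputed EM-style: initialize at column means, then
#' alternate a rank-`rank` SVD reconstruction of the centered matrix with
#' re-imputation of the missing cells, until the largest cell change is
#' below `tol` (or `max_iter`, with a convergence warning). Scores are the
#' projection on the first principal axis, oriented so the mean loading is
#' positive. A single-test table bypasses the PCA: scores are that test's
#' z-scores.
#'
#' @param baseline_tests numeric matrix or data frame, subjects x tests,
#'   possibly with missing cells (rows must not be all-missing).
#' @param rank reconstruction rank for the imputation (default 1, the
#'   retained component).
#' @param tol,max_iter convergence control for the imputation.
#' @return List of class `composite_model` with `loadings` (unit norm),
#'   `center`, `rank`, `var_explained`, and `scores` (one per subject).
#' @export
pca_composite <- function(baseline_tests, rank = 1, tol = 1e-6, max_iter = 500) {
  X <- as.matrix(baseline_tests)
  storage.mode(X) <- "double"
  if (any(rowSums(!is.na(X)) == 0)) stop("all-missing row in test table", call. = FALSE)
  if (ncol(X) == 1) {
    z <- as.numeric(scale(X[, 1]))
    return(structure(list(loadings = stats::setNames(1, colnames(X)),
                          center = mean(X[, 1]), rank = 0L, var_explained = 1,
                          scores = z), class = "composite_model"))
  }
  if (any(colMeans(is.na(X)) >= 0.5))
    stop("a test has >= 50% missing baseline values", call. = FALSE)
  miss <- is.na(X)
  ctr <- colMeans(X, na.rm = TRUE)
  Xi <- X
  Xi[miss] <- matrix(ctr, nrow(X), ncol(X), byrow = TRUE)[miss]
  if (any(miss)) {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      ctr <- colMeans(Xi)
      Xc <- sweep(Xi, 2, ctr)
      sv <- svd(Xc, nu = rank, nv = rank)
      rec <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v)) +
        matrix(ctr, nrow(X), ncol(X), byrow = TRUE)
      delta <- max(abs(rec[miss] - Xi[miss]))
      Xi[miss] <- rec[miss]
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged) warning("imputation did not converge; returning last iterate")
  }
  ctr <- colMeans(Xi)
  pc <- stats::prcomp(Xi, center = TRUE, scale. = FALSE)
  l <- pc$rotation[, 1]
  if (mean(l) < 0) l <- -l
  scores <- as.numeric(sweep(Xi, 2, ctr) %*% l)
  structure(list(loadings = l, center = ctr, rank = as.integer(rank),
                 var_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
                 scores = scores), class = "composite_model")
}

#' Composite scores for new visits with frozen baseline loadings
#'
#' Projects (possibly incomplete) test values onto a fitted
#' [pca_composite()] model; missing tests are set to their baseline mean
#' (i.e. contribute 0 after centering).
#'
#' @param model a `composite_model`.
#' @param tests matrix or data frame with the model's test columns.
#' @return Numeric score per row.
#' @export
predict_composite <- function(model, tests) {
  stopifnot(inherits(model, "composite_model"))
  X <- as.matrix(tests[, names(model$loadings), drop = FALSE])
  Xc <- sweep(X, 2, model$center)
  Xc[is.na(Xc)] <- 0
  as.numeric(Xc %*% model$loadings)
}

n_waves <- function(visit_index) max(visit_index)

## norm-model fitter shared by memory residualization and brain deviations;
## subject random intercepts make gam() expensive past a few hundred levels,
## so large fits go through bam(discrete = TRUE)
fit_norm_gam <- function(form, dd) {
  n_subj <- length(unique(dd$subject_id))
  if (nrow(dd) > 400 || n_subj > 60) {
    mgcv::bam(form, data = dd, method = "fREML", discrete = TRUE)
  } else {
    mgcv::gam(form, data = dd, method = "REML")
  }
}

#' Adjust memory scores for age, sex, practice and subject level
#'
#' Per dataset, fits a penalized additive model
#' `score ~ s(age) + sex + retest dummies + subject random intercept`
#' and returns the residuals: within-person deviations around the subject's
#' own level, adjusted for the normative age trend, sex and test-retest
#' (practice) effects. One retest dummy (`visit >= 2`) is used when the
#' dataset has two waves, and a second (`visit >= 3`) when it has three or
#' more.
#'
#' @param panel long-format panel carrying the composite score.
#' @param score_col name of the score column (default `"memory"`).
#' @return The panel with an added `memory_adj` column. Attribute `"models"`
#'   holds, per dataset, the estimated retest coefficients and the fitted
#'   model summary used by recovery tests.
#' @export
residualize_memory <- function(panel, score_col = "memory") {
  stopifnot(score_col %in% names(panel))
  panel$memory_adj <- NA_real_
  models <- list()
  for (d in unique(panel$dataset_id)) {
    in_d <- which(panel$dataset_id == d)
    dd <- panel[in_d, ]
    waves <- n_waves(dd$visit_index)
    if (waves < 2)
      stop(sprintf("dataset '%s' has a single wave; change is undefined", d),
           call. = FALSE)
    dd$.score <- dd[[score_col]]
    dd$.age <- dd$baseline_age + dd$time
    dd$.retest1 <- as.numeric(dd$visit_index >= 2)
    dd$.retest2 <- as.numeric(dd$visit_index >= 3)
    dd$subject_id <- factor(dd$subject_id)
    two_sex <- length(unique(dd$sex)) > 1
    rhs <- c("s(.age, bs = 'ps', k = 10, m = c(2, 2))",
             if (two_sex) "sex", ".retest1",
             if (waves >= 3) ".retest2",
             "s(subject_id, bs = 're')")
    form <- stats::reformulate(rhs, response = ".score")
    keep <- !is.na(dd$.score)
    fit <- fit_norm_gam(form, dd[keep, ])
    res <- dd$.score[keep] - stats::fitted(fit)
    ## penalized subject intercepts are shrunk; exact within-person centering
    ## completes their removal (only change matters downstream)
    res <- res - stats::ave(res, dd$subject_id[keep])
    panel$memory_adj[in_d[keep]] <- res
    cf <- stats::coef(fit)
    models[[d]] <- list(retest1 = unname(cf[".retest1"]),
                        retest2 = if (waves >= 3) unname(cf[".retest2"]) else NA_real_,
                        waves = waves, n = sum(keep))
  }
  attr(panel, "models") <- models
  panel
}

#' Age/sex/site deviation scores for brain measures
#'
#' Per region, fits a penalized additive norm
#' `value ~ sex + s(age) + dataset random intercept + subject random
#' intercept` across all visits, and returns the observed value minus the
#' predicted sex- and age-specific norm with dataset offsets removed
#' (subject intercepts are left in: they carry the subject's deviation and
#' drop out of any within-person change). Deviations are exactly recentered
#' within dataset (penalized dataset offsets are shrunk and would otherwise
#' leave small residual site means) and standardized to unit SD per region
#' over the fitting sample.
#'
#' @param panel long-format brain panel.
#' @param measures region columns (default: all measure columns).
#' @return The panel with measure columns replaced by deviation z-scores;
#'   attribute `"scale"` records the per-region SD that was divided out.
#' @export
brain_deviation_scores <- function(panel, measures = panel_measures(panel)) {
  dd <- panel
  dd$.age <- dd$baseline_age + dd$time
  dd$subject_id <- factor(dd$subject_id)
  dd$dataset_id <- factor(dd$dataset_id)
  multi_ds <- nlevels(dd$dataset_id) > 1
  two_sex <- length(unique(dd$sex)) > 1
  scales <- stats::setNames(numeric(length(measures)), measures)
  for (m in measures) {
    y <- dd[[m]]
    keep <- !is.na(y)
    if (stats::sd(y[keep]) == 0)
      stop(sprintf("region '%s' has zero variance", m), call. = FALSE)
    rhs <- c(if (two_sex) "sex",
             "s(.age, bs = 'ps', k = 10, m = c(2, 2))",
             if (multi_ds) "s(dataset_id, bs = 're')",
             "s(subject_id, bs = 're')")
    dd$.y <- y
    fit <- fit_norm_gam(stats::reformulate(rhs, response = ".y"), dd[keep, ])
    pred <- stats::predict(fit, newdata = dd[keep, ], exclude = "s(subject_id)",
                           newdata.guaranteed = TRUE, discrete = FALSE)
    dev <- y[keep] - as.numeric(pred)
    ## exact site recentering, then unit-SD standardization
    dev <- dev - stats::ave(dev, dd$dataset_id[keep])
    s <- stats::sd(dev)
    scales[m] <- s
    out <- rep(NA_real_, nrow(dd))
    out[keep] <- dev / s
    panel[[m]] <- out
  }
  attr(panel, "scale") <- scales
  panel
}
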