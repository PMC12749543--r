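#' Fit a weighted penalized-spline additive model
#'
#' Thin wrapper around [mgcv::gam()] that fixes the conventions used
#' throughout the package: Gaussian response, weighted penalized least
#' squares, smoothing parameters by generalized cross-validation
#' (`method = "GCV.Cp"`), cubic P-spline smooths (`bs = "ps"`, `k = 10`,
#' second-order difference penalties) written explicitly in the formula, and
#' dataset "random intercepts" as ridge-penalized `s(., bs = "re")` blocks
#' whose penalty is selected jointly with the smooths. The prefit design is
#' retained so wild-bootstrap replicates can re-estimate smoothing
#' parameters cheaply via [mgcv::magic()].
#'
#' @param formula an mgcv model formula (use [smooth_term()] /
#'   [offset_term()] helpers or write `s()` / `ti()` directly).
#' @param data data frame with the model variables.
#' @param weights analysis weights: a numeric vector, or the name of a
#'   column of `data`. `NULL` means unit weights.
#' @param sp optional fixed smoothing parameter vector (`sp = Inf`-like
#'   large values force each smooth onto its penalty null space).
#' @param method smoothing-parameter criterion (default `"GCV.Cp"`).
#' @return Object of class `wgam`: list with the `mgcv` fit (`$fit`), the
#'   prefit design (`$G`), the weight vector, and bookkeeping fields.
#' @export
fit_wgam <- function(formula, data, weights = NULL, sp = NULL,
                     method = "GCV.Cp") {
  dd <- as.data.frame(data)
  w <- if (is.null(weights)) rep(1, nrow(dd)) else
    if (is.character(weights)) dd[[weights]] else as.numeric(weights)
  if (length(w) != nrow(dd)) stop("weights length mismatch", call. = FALSE)
  vars <- all.vars(formula)
  keep <- stats::complete.cases(dd[, intersect(vars, names(dd)), drop = FALSE]) &
    is.finite(w)
  dd <- dd[keep, , drop = FALSE]
  w <- w[keep]
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  ## analysis weights are relative; normalizing makes every downstream
  ## statistic exactly invariant to rescaling all weights by a constant
  w <- w / mean(w)
  for (v in vars) if (is.character(dd[[v]])) dd[[v]] <- factor(dd[[v]])
  dd <- droplevels(dd)
  if (nrow(dd) < 10) stop("fewer than 10 complete rows", call. = FALSE)
  dd$.wgam_w <- w
  fit <- try(mgcv::gam(formula, data = dd, weights = .wgam_w, sp = sp,
                       method = method), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("singular or failed fit: ", attr(fit, "condition")$message, call. = FALSE)
  G <- mgcv::gam(formula, data = dd, weights = .wgam_w, sp = sp,
                 method = method, fit = FALSE)
  structure(list(fit = fit, G = G, data = dd, weights = w,
                 formula = formula, response = as.character(formula[[2]]),
                 sp = sp),
            class = "wgam")
}

#' @export
print.wgam <- function(x, ...) {
  cat("Weighted penalized-spline model:", deparse(x$formula), "\n")
  cat("  n =", nrow(x$data), " total edf =", round(sum(x$fit$edf), 2),
      " deviance explained =", round(summary(x$fit)$dev.expl, 4), "\n")
  invisible(x)
}

#' Formula helpers for the package's standard terms
#'
#' `smooth_term(x)` renders the package's default P-spline smooth,
#' `tensor_term(x1, x2)` the centered tensor-product interaction basis, and
#' `offset_term(f)` the ridge-penalized factor-offset ("random intercept")
#' block.
#'
#' @param x,x1,x2 variable names (character).
#' @param k basis size.
#' @param by optional `by=` variable name (ordered factor gives a
#'   difference smooth).
#' @return A character term, to be combined with [stats::reformulate()].
#' @export
smooth_term <- function(x, k = 10, by = NULL) {
  sprintf("s(%s%s, bs = 'ps', k = %d, m = c(2, 2))", x,
          if (is.null(by)) "" else paste0(", by = ", by), k)
}

#' @rdname smooth_term
#' @export
tensor_term <- function(x1, x2, k = 5, by = NULL) {
  sprintf("ti(%s, %s%s, bs = 'ps', k = c(%d, %d), m = c(2, 2))", x1, x2,
          if (is.null(by)) "" else paste0(", by = ", by), k, k)
}

#' @rdname smooth_term
#' @export
offset_term <- function(x) sprintf("s(%s, bs = 're')", x)

#' Effective degrees of freedom of a named smooth term
#'
#' @param wg a `wgam` fit.
#' @param label smooth label as reported by mgcv (e.g. `"s(d_region)"`);
#'   partial matching on the leading variable is attempted.
#' @return Summed edf of the term's coefficients.
#' @export
term_edf <- function(wg, label) {
  labs <- vapply(wg$fit$smooth, function(s) s$label, "")
  j <- which(labs == label)
  if (!length(j)) j <- grep(label, labs, fixed = TRUE)
  if (length(j) != 1) stop("term not found uniquely: ", label, call. = FALSE)
  sm <- wg$fit$smooth[[j]]
  sum(wg$fit$edf[sm$first.para:sm$last.para])
}

## weighted residual sum of squares of a wgam (or of coefficients b on
## design X): the workhorse statistic for bootstrap inference
wgam_wrss <- function(wg, y = NULL, b = NULL) {
  if (is.null(y)) y <- wg$G$y
  mu <- if (is.null(b)) stats::fitted(wg$fit) else as.numeric(wg$G$X %*% b)
  sum(wg$weights * (y - mu)^2)
}

## re-estimate a wgam on a new response with smoothing parameters re-selected
## by GCV, without rebuilding bases; returns the weighted RSS and the
## minimized GCV score (the complexity-penalized goodness of fit)
refit_wgam_scores <- function(wg, ystar) {
  G <- wg$G
  n <- length(ystar)
  if (length(G$S) == 0) {
    b <- stats::lm.wfit(G$X * sqrt(wg$weights), ystar * sqrt(wg$weights),
                        rep(1, n))$coefficients
    b[!is.finite(b)] <- 0
    wrss <- sum(wg$weights * (ystar - as.numeric(G$X %*% b))^2)
    list(wrss = wrss, gcv = n * wrss / (n - ncol(G$X))^2)
  } else {
    sp <- if (is.null(wg$sp)) rep(-1, length(G$S)) else wg$sp
    mg <- mgcv::magic(ystar, G$X, sp = sp, S = G$S, off = G$off,
                      w = sqrt(wg$weights), gcv = TRUE)
    list(wrss = sum(wg$weights * (ystar - as.numeric(G$X %*% mg$b))^2),
         gcv = mg$score)
  }
}

refit_wrss <- function(wg, ystar) refit_wgam_scores(wg, ystar)$wrss

model_support <- function(wg, var) range(wg$data[[var]], na.rm = TRUE)

build_newdata <- function(wg, var, values, fixed = list()) {
  vars <- setdiff(all.vars(wg$formula)[-1], ".wgam_w")
  nd <- data.frame(row.names = seq_along(values))
  for (v in vars) {
    col <- wg$data[[v]]
    nd[[v]] <- if (v == var) values
    else if (v %in% names(fixed)) fixed[[v]]
    else if (is.factor(col)) factor(rep(levels(col)[1], length(values)),
                                    levels = levels(col), ordered = is.ordered(col))
    else rep(stats::median(col, na.rm = TRUE), length(values))
  }
  nd
}

#' Finite-difference derivative of a fitted smooth association
#'
#' Central differences `(f(x + eps) - f(x - eps)) / (2 eps)` of the model
#' prediction along one variable, with pointwise 95% intervals obtained by
#' propagating the coefficient covariance through the difference operator.
#' Additive terms in other variables cancel in the difference; interaction
#' (tensor) surfaces are evaluated at the values supplied in `fixed` (e.g. a
#' specific age).
#'
#' @param wg a `wgam` fit.
#' @param along variable to differentiate along.
#' @param at evaluation grid (must lie inside the observed support;
#'   extrapolation is an error). Default: 200 equally spaced points.
#' @param eps finite-difference step (default `1e-3 * SD(along)`). Results
#'   should be step-insensitive; [density_weighted_beta()] enforces this.
#' @param fixed named list of values for other variables (used by tensor
#'   terms).
#' @param level confidence level for the intervals.
#' @return Data frame `x`, `derivative`, `se`, `lower`, `upper`.
#' @export
fd_derivative <- function(wg, along, at = NULL, eps = NULL, fixed = list(),
                          level = 0.95) {
  sup <- model_support(wg, along)
  if (is.null(at)) at <- seq(sup[1], sup[2], length.out = 200)
  if (any(at < sup[1] - 1e-9 | at > sup[2] + 1e-9))
    stop("derivative grid outside the observed support of ", along, call. = FALSE)
  if (is.null(eps)) eps <- 1e-3 * stats::sd(wg$data[[along]], na.rm = TRUE)
  if (eps <= 0) stop("eps must be positive", call. = FALSE)
  Xp <- stats::predict(wg$fit, build_newdata(wg, along, at + eps, fixed),
                       type = "lpmatrix", newdata.guaranteed = TRUE)
  Xm <- stats::predict(wg$fit, build_newdata(wg, along, at - eps, fixed),
                       type = "lpmatrix", newdata.guaranteed = TRUE)
  D <- (Xp - Xm) / (2 * eps)
  d <- as.numeric(D %*% stats::coef(wg$fit))
  se <- sqrt(pmax(rowSums((D %*% wg$fit$Vp) * D), 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(x = at, derivative = d, se = se,
             lower = d - zq * se, upper = d + zq * se)
}

#' Density-weighted association over the declining range
#'
#' The density-weighted beta summarizes the smooth association as the mean
#' finite-difference derivative over the declining domain (`x < 0`),
#' weighted by the Gaussian kernel density (Silverman bandwidth) of the
#' observed predictor values. The grid spans the 1st percentile of the
#' observed values (trimming ~1% of extreme observations) up to 0. A runtime
#' step-halving check warns when the result is not finite-difference-step
#' insensitive within 1%.
#'
#' @param wg a `wgam` fit.
#' @param along predictor variable.
#' @param x_values observed predictor values for the density weighting
#'   (default: the model's own data).
#' @param fixed named list fixing other variables (e.g. `list(age = 60)` for
#'   tensor models).
#' @param ngrid grid resolution (default 200).
#' @param domain `"negative"` (default) restricts to `x < 0`, the declining
#'   range; `"full"` averages over the whole trimmed support (the convention
#'   for effectively linear, edf = 1 terms).
#' @param eps optional finite-difference step.
#' @return The density-weighted mean derivative (scalar).
#' @export
density_weighted_beta <- function(wg, along, x_values = NULL, fixed = list(),
                                  ngrid = 200, domain = c("negative", "full"),
                                  eps = NULL) {
  domain <- match.arg(domain)
  if (is.null(x_values)) x_values <- wg$data[[along]]
  x_values <- x_values[is.finite(x_values)]
  lo <- stats::quantile(x_values, 0.01, names = FALSE)
  hi <- if (domain == "negative") 0 else stats::quantile(x_values, 0.99, names = FALSE)
  if (domain == "negative") {
    if (mean(x_values < 0) < 0.05)
      stop("fewer than 5% of observations in the declining (x < 0) domain",
           call. = FALSE)
    hi <- min(hi, max(x_values))
  }
  sup <- model_support(wg, along)
  lo <- max(lo, sup[1]); hi <- min(hi, sup[2])
  if (!(hi > lo)) stop("empty derivative domain", call. = FALSE)
  grid <- seq(lo, hi - 1e-9 * (hi - lo), length.out = ngrid)
  dens <- stats::density(x_values, bw = "nrd0")
  K <- stats::approx(dens$x, dens$y, xout = grid, rule = 2)$y
  if (is.null(eps)) eps <- 1e-3 * stats::sd(wg$data[[along]], na.rm = TRUE)
  bw_at <- function(e) {
    d <- fd_derivative(wg, along, at = grid, eps = e, fixed = fixed)$derivative
    sum(d * K) / sum(K)
  }
  beta <- bw_at(eps)
  beta_half <- bw_at(eps / 2)
  if (abs(beta) > 1e-8 && abs(beta - beta_half) > 0.01 * abs(beta))
    warning("density-weighted beta is sensitive to the finite-difference step")
  beta
}

#' Partial variance explained by the terms dropped in a null model
#'
#' Difference in weighted variance explained, `1 - wRSS/wTSS`, between a
#' full model and a null model fitted to the same rows with the same
#' weights, floored at 0.
#'
#' @param full,null `wgam` fits; the null's terms should be a subset of the
#'   full's (set `check_nested = FALSE` for non-nested descriptive
#'   comparisons).
#' @param check_nested verify term nesting (default `TRUE`).
#' @return Partial R^2 in `[0, 1]`.
#' @export
partial_r2 <- function(full, null, check_nested = TRUE) {
  if (nrow(full$data) != nrow(null$data))
    stop("full and null models use different rows", call. = FALSE)
  if (max(abs(full$weights - null$weights)) > 1e-12)
    stop("full and null models use different weights", call. = FALSE)
  if (check_nested) {
    tf <- attr(stats::terms(full$formula), "term.labels")
    tn <- attr(stats::terms(null$formula), "term.labels")
    if (!all(tn %in% tf)) stop("null model is not nested in the full model",
                               call. = FALSE)
  }
  r2 <- function(wg) {
    y <- wg$G$y; w <- wg$weights
    tss <- sum(w * (y - sum(w * y) / sum(w))^2)
    1 - wgam_wrss(wg) / tss
  }
  max(0, r2(full) - r2(null))
}

#' Weighted smooth + tensor-interaction (moderation) model
#'
#' Fits `response ~ s(x1) + s(x2) + ti(x1, x2)` (plus an optional dataset
#' offset block), the model used to test whether a smooth association varies
#' with a moderator: the `ti()` interaction basis is the row-wise Kronecker
#' product of the marginal bases, centered so it is identifiable against the
#' marginals, with separate penalties per direction.
#'
#' @param data data frame.
#' @param response,x1,x2 variable names (`x1` the association variable,
#'   `x2` the moderator).
#' @param weights as in [fit_wgam()].
#' @param offset_factor optional factor column fitted as a penalized offset
#'   block (e.g. `"dataset_id"`).
#' @param k_marginal,k_tensor basis sizes for marginal and tensor smooths.
#' @param sp,method passed to [fit_wgam()].
#' @return A `wgam` fit.
#' @export
fit_tensor <- function(data, response, x1, x2, weights = NULL,
                       offset_factor = NULL, k_marginal = 10, k_tensor = 5,
                       sp = NULL, method = "GCV.Cp") {
  for (v in c(x1, x2))
    if (length(unique(stats::na.omit(data[[v]]))) < 4)
      stop("marginal '", v, "' needs >= 4 distinct values", call. = FALSE)
  rhs <- c(smooth_term(x1, k_marginal), smooth_term(x2, k_marginal),
           tensor_term(x1, x2, k_tensor),
           if (!is.null(offset_factor)) offset_term(offset_factor))
  fit_wgam(stats::reformulate(rhs, response = response), data,
           weights = weights, sp = sp, method = method)
}
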