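#' Skew-normal parameter set
#'
#' Container for the three-parameter skew-normal distribution used to model
#' the cross-subject distribution of latent yearly brain decline: location
#' `xi` (z-units/year), scale `omega` (z-units/year, > 0) and shape `alpha`
#' (dimensionless). Negative `alpha` gives the heavy lower tail of
#' accelerated decliners.
#'
#' @param xi location, in z-units/year.
#' @param omega scale, in z-units/year; must be strictly positive.
#' @param alpha shape; `alpha = 0` recovers the normal distribution.
#' @return An object of class `skewnorm_params` with fields `xi`, `omega`,
#'   `alpha` and the derived `delta = alpha / sqrt(1 + alpha^2)`.
#' @examples
#' skew_normal_params(xi = 0.16, omega = 0.3, alpha = -4)
#' @export
skew_normal_params <- function(xi = 0, omega = 1, alpha = 0) {
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) || omega <= 0)
    stop("`omega` must be a single positive number", call. = FALSE)
  stopifnot(is.numeric(xi), length(xi) == 1L, is.finite(xi),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  structure(list(xi = xi, omega = omega, alpha = alpha,
                 delta = alpha / sqrt(1 + alpha^2)),
            class = "skewnorm_params")
}

as_skewnorm_params <- function(x) {
  if (inherits(x, "skewnorm_params")) return(x)
  if (is.list(x) && all(c("xi", "omega", "alpha") %in% names(x)))
    return(skew_normal_params(x$xi, x$omega, x$alpha))
  stop("cannot interpret `x` as skew-normal parameters", call. = FALSE)
}

#' Draw skew-normal deviates
#'
#' Samples i.i.d. values from the skew-normal distribution via the
#' convolution representation `Z = delta*|U0| + sqrt(1 - delta^2)*U1` with
#' `U0, U1` independent standard normal and `X = xi + omega * Z`. This is
#' exact and dependency-free, and matches the standard (xi, omega, alpha)
#' parameterization: mean `xi + omega*delta*sqrt(2/pi)`, variance
#' `omega^2 * (1 - 2*delta^2/pi)`.
#'
#' @param params a [skew_normal_params()] object (or a list with fields
#'   `xi`, `omega`, `alpha`).
#' @param n number of draws, >= 1.
#' @param seed optional integer; when given the draw is deterministic and the
#'   caller's RNG state is restored afterwards.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- sample_skew_normal(skew_normal_params(0, 1, -4), 1000, seed = 1)
#' mean(x) # close to -0.776 = delta * sqrt(2/pi) with delta = -4/sqrt(17)
#' @export
sample_skew_normal <- function(params, n, seed = NULL) {
  params <- as_skewnorm_params(params)
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  d <- params$delta
  u0 <- abs(stats::rnorm(n))
  u1 <- stats::rnorm(n)
  params$xi + params$omega * (d * u0 + sqrt(1 - d^2) * u1)
}

#' Skew-normal density
#'
#' @param x numeric vector of evaluation points.
#' @param params a [skew_normal_params()] object.
#' @return Density values `2/omega * phi(z) * Phi(alpha * z)` with
#'   `z = (x - xi)/omega`.
#' @export
dskew_normal <- function(x, params) {
  params <- as_skewnorm_params(params)
  z <- (x - params$xi) / params$omega
  2 / params$omega * stats::dnorm(z) * stats::pnorm(params$alpha * z)
}

#' Closed-form skew-normal moments
#'
#' @param params a [skew_normal_params()] object.
#' @return List with `mean`, `sd` and `skewness` of the distribution.
#' @export
skew_normal_moments <- function(params) {
  params <- as_skewnorm_params(params)
  d <- params$delta
  mu_z <- d * sqrt(2 / pi)
  v_z <- 1 - 2 * d^2 / pi
  skew <- (4 - pi) / 2 * mu_z^3 / v_z^(3 / 2)
  list(mean = params$xi + params$omega * mu_z,
       sd = params$omega * sqrt(v_z),
       skewness = skew)
}

#' Solve (xi, omega) for target mean and SD at a given shape
#'
#' Inverts the closed-form moment expressions so that sweeps over skewness can
#' hold the first two moments of the latent distribution fixed.
#'
#' @param mean,sd target mean and standard deviation (`sd > 0`).
#' @param alpha shape parameter to keep.
#' @return A [skew_normal_params()] object with the requested moments.
#' @export
skew_normal_match_moments <- function(mean, sd, alpha) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0, is.finite(alpha))
  d <- alpha / sqrt(1 + alpha^2)
  omega <- sd / sqrt(1 - 2 * d^2 / pi)
  xi <- mean - omega * d * sqrt(2 / pi)
  skew_normal_params(xi, omega, alpha)
}
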