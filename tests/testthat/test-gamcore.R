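lin_data <- function(n = 500, slope = 2, noise = 0.1, seed = 1) {
  set.seed(seed)
  dd <- data.frame(x = runif(n, -2, 2),
                   ds = factor(sample(letters[1:5], n, TRUE)))
  dd$y <- slope * dd$x + rnorm(n, 0, noise)
  dd$w <- runif(n, 0.2, 1)
  dd
}

test_that("linear truth is recovered with near-linear edf", {
  dd <- lin_data(noise = 0.1)
  fit <- fit_wgam(y ~ s(x, bs = "ps", k = 10, m = c(2, 2)), dd, weights = "w")
  gr <- seq(quantile(dd$x, 0.05), quantile(dd$x, 0.95), length.out = 50)
  pr <- predict(fit$fit, newdata = data.frame(x = gr))
  expect_lt(max(abs(pr - 2 * gr)), 0.05)
  expect_lt(term_edf(fit, "s(x)"), 1.5)
  expect_gte(term_edf(fit, "s(x)"), 1)
})

test_that("fits are invariant to rescaling all weights", {
  dd <- lin_data(noise = 0.3, seed = 2)
  f1 <- fit_wgam(y ~ s(x, bs = "ps", k = 10, m = c(2, 2)) + s(ds, bs = "re"),
                 dd, weights = dd$w)
  f2 <- fit_wgam(y ~ s(x, bs = "ps", k = 10, m = c(2, 2)) + s(ds, bs = "re"),
                 dd, weights = dd$w * 13.7)
  expect_lt(max(abs(coef(f1$fit) - coef(f2$fit))), 1e-8)
})

test_that("infinite smoothing collapses the smooth onto the weighted OLS line", {
  dd <- lin_data(noise = 0.4, seed = 3)
  fit <- fit_wgam(y ~ s(x, bs = "ps", k = 10, m = c(2, 2)), dd,
                  weights = "w", sp = 1e12)
  X <- cbind(1, dd$x)
  bo <- wols_oracle(X, dd$y, dd$w)
  gr <- c(-1.5, -0.5, 0, 0.5, 1.5)
  pr <- predict(fit$fit, newdata = data.frame(x = gr))
  expect_lt(max(abs(pr - (bo[1] + bo[2] * gr))), 1e-6)
  ## beta_w of the forced-linear fit equals the weighted OLS slope
  bw <- density_weighted_beta(fit, "x")
  expect_lt(abs(bw - bo[2]), 0.01)
})

test_that("GCV selection beats a fixed smoothing-parameter grid", {
  dd <- lin_data(n = 300, noise = 0.3, seed = 4)
  dd$y <- sin(1.5 * dd$x) + rnorm(300, 0, 0.3)
  fit <- fit_wgam(y ~ s(x, bs = "ps", k = 10, m = c(2, 2)), dd)
  gcv <- fit$fit$gcv.ubre
  grid_gcv <- vapply(10^seq(-6, 6, length.out = 20), function(lam) {
    fit_wgam(y ~ s(x, bs = "ps", k = 10, m = c(2, 2)), dd, sp = lam)$fit$gcv.ubre
  }, numeric(1))
  expect_lte(gcv, min(grid_gcv) + 1e-8)
})

test_that("edf decreases monotonically in the smoothing parameter", {
  dd <- lin_data(n = 300, noise = 0.3, seed = 5)
  dd$y <- sin(1.5 * dd$x) + rnorm(300, 0, 0.3)
  edfs <- vapply(10^seq(-4, 6, by = 1), function(lam)
    sum(fit_wgam(y ~ s(x, bs = "ps", k = 10, m = c(2, 2)), dd,
                 sp = lam)$fit$edf) , numeric(1))
  expect_true(all(diff(edfs) < 1e-6))
})

test_that("tensor interactions stay out of additive truths but fit products", {
  set.seed(6)
  n <- 2000
  dd <- data.frame(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2))
  ## additive truth: interaction stays near zero complexity
  dd$y <- sin(dd$x1) + 0.5 * dd$x2^2 + rnorm(n, 0, 0.2)
  fa <- fit_tensor(dd, "y", "x1", "x2")
  expect_lt(term_edf(fa, "ti(x1,x2)"), 1.5)

  ## product truth: fitted surface tracks x1*x2 over the central region
  dd$y <- dd$x1 * dd$x2 + rnorm(n, 0, 0.2)
  fp <- fit_tensor(dd, "y", "x1", "x2")
  g <- expand.grid(x1 = seq(-1, 1, length.out = 11),
                   x2 = seq(-1, 1, length.out = 11))
  pr <- predict(fp$fit, newdata = g)
  expect_lt(sqrt(mean((pr - g$x1 * g$x2)^2)), 0.1)
})

test_that("tensor predictions are symmetric under symmetric truth", {
  set.seed(7)
  n <- 1500
  dd <- data.frame(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2))
  dd$y <- dd$x1 * dd$x2 + rnorm(n, 0, 0.1)
  f1 <- fit_tensor(dd, "y", "x1", "x2")
  dd2 <- data.frame(x1 = dd$x2, x2 = dd$x1, y = dd$y)
  f2 <- fit_tensor(dd2, "y", "x1", "x2")
  g <- expand.grid(x1 = seq(-1, 1, length.out = 5), x2 = seq(-1, 1, length.out = 5))
  p1 <- predict(f1$fit, newdata = g)
  p2 <- predict(f2$fit, newdata = data.frame(x1 = g$x2, x2 = g$x1))
  expect_lt(max(abs(p1 - p2)), 1e-3)
})

test_that("finite-difference derivatives match analytic truths", {
  dd <- lin_data(n = 400, slope = 1.3, noise = 0.05, seed = 8)
  fit <- fit_wgam(y ~ s(x, bs = "ps", k = 10, m = c(2, 2)), dd, weights = "w",
                  sp = 1e12)
  der <- fd_derivative(fit, "x", at = seq(-1.5, 1.5, length.out = 20))
  expect_lt(max(abs(der$derivative - der$derivative[1])), 1e-6)

  ## y = x^2: derivative at 1 close to 2
  set.seed(9)
  dq <- data.frame(x = runif(2000, -2, 2))
  dq$y <- dq$x^2 + rnorm(2000, 0, 0.05)
  fq <- fit_wgam(y ~ s(x, bs = "ps", k = 10, m = c(2, 2)), dq)
  d1 <- fd_derivative(fq, "x", at = 1)
  expect_lt(abs(d1$derivative - 2), 0.1)

  ## constant response: derivative 0, interval covers 0
  dc <- data.frame(x = runif(200, -1, 1))
  dc$y <- 1 + rnorm(200, 0, 0.01)
  fc <- fit_wgam(y ~ s(x, bs = "ps", k = 10, m = c(2, 2)), dc)
  d0 <- fd_derivative(fc, "x", at = c(-0.5, 0, 0.5))
  expect_true(all(abs(d0$derivative) < 0.05))
  expect_true(all(d0$lower <= 0 & d0$upper >= 0))

  expect_error(fd_derivative(fc, "x", at = 5), "support")
})

test_that("density-weighted beta equals the slope for linear relations", {
  set.seed(10)
  n <- 3000
  dd <- data.frame(x = rnorm(n, -0.2, 1))
  dd$y <- 0.4 * dd$x + rnorm(n, 0, 0.1)
  fit <- fit_wgam(y ~ s(x, bs = "ps", k = 10, m = c(2, 2)), dd)
  expect_lt(abs(density_weighted_beta(fit, "x") - 0.4), 0.01)

  ## flat fit
  dd$y2 <- rnorm(n, 0, 0.1)
  f0 <- fit_wgam(y2 ~ s(x, bs = "ps", k = 10, m = c(2, 2)), dd)
  expect_lt(abs(density_weighted_beta(f0, "x")), 0.02)
})

test_that("density-weighted beta matches a quadrature oracle for a kinked truth", {
  ## derivative is 1 below -1 and 0 on (-1, 0): beta_w should equal the
  ## density-weighted share of the domain below -1
  set.seed(11)
  n <- 6000
  x <- rnorm(n, -0.5, 0.8)
  y <- pmin(x + 1, 0) + rnorm(n, 0, 0.02)
  dd <- data.frame(x = x, y = y)
  fit <- fit_wgam(y ~ s(x, bs = "ps", k = 20, m = c(2, 2)), dd)
  bw <- density_weighted_beta(fit, "x")
  ## quadrature oracle on the same grid construction: true derivative
  ## weighted by the kernel density of x
  lo <- quantile(x, 0.01); grid <- seq(lo, 0, length.out = 200)
  dens <- density(x, bw = "nrd0")
  K <- approx(dens$x, dens$y, xout = grid, rule = 2)$y
  oracle <- sum((grid < -1) * K) / sum(K)
  expect_lt(abs(bw - oracle), 0.02)
})

test_that("partial R2 behaves like a nested variance-explained difference", {
  set.seed(12)
  n <- 6000
  dd <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                   ds = factor(sample(letters[1:4], n, TRUE)))
  dd$y <- 0.5 * dd$x1 + 0.3 * dd$x2 + rnorm(n, 0, 1)
  full <- fit_wgam(y ~ x1 + x2, dd)
  null <- fit_wgam(y ~ x2, dd)
  expect_equal(partial_r2(full, full), 0)
  ## orthogonal predictors: partial R2 ~ squared semi-partial correlation
  r2_expected <- 0.25 / (0.25 + 0.09 + 1)
  expect_lt(abs(partial_r2(full, null) - r2_expected), 0.02)
  ## bounded by the full model's variance explained
  expect_lte(partial_r2(full, null), summary(full$fit)$dev.expl + 1e-10)
  expect_error(partial_r2(full, fit_wgam(y ~ x2, dd[1:400, ])), "rows")
  expect_error(partial_r2(fit_wgam(y ~ x1, dd), fit_wgam(y ~ x2, dd)), "nested")
})
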