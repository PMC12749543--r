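# Independent oracles used to freeze expected values. These deliberately do
# not share code with the package implementation.

# brute-force least squares: iteratively refined grid search over (a, b)
ols_grid_oracle <- function(times, values, passes = 24, width = 10, ngrid = 31) {
  ## grid over (c, b) with c the intercept at the mean time: the SSE factorizes
  ## there, so the refinement cannot get trapped in a diagonal valley
  tc <- times - mean(times)
  c0 <- mean(values); b0 <- 0
  wc <- wb <- width
  for (p in seq_len(passes)) {
    cs <- seq(c0 - wc, c0 + wc, length.out = ngrid)
    bs <- seq(b0 - wb, b0 + wb, length.out = ngrid)
    sse <- outer(cs, bs, Vectorize(function(cc, b) sum((values - cc - b * tc)^2)))
    ix <- which(sse == min(sse), arr.ind = TRUE)[1, ]
    c0 <- cs[ix[1]]; b0 <- bs[ix[2]]
    ## new window (w/5 = 3 grid spacings) covers the half-spacing recentering error
    wc <- wc / 5; wb <- wb / 5
  }
  c(a = c0 - b0 * mean(times), b = b0)
}

# literal Benjamini-Hochberg step-up: adj_(i) = min_{j >= i} p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(ps[i:m] * m / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# two-stage deviation oracle: fit the age/sex norm on one observation per
# subject (quasi cross-section), predict all rows, subtract, demean by site
two_stage_deviation_oracle <- function(panel, measure) {
  first <- panel[panel$visit_index == 1, ]
  first$.age <- first$baseline_age + first$time
  fit <- mgcv::gam(stats::reformulate(c("sex", "s(.age, k = 10)"),
                                      response = measure), data = first)
  nd <- panel
  nd$.age <- nd$baseline_age + nd$time
  dev <- panel[[measure]] - as.numeric(predict(fit, newdata = nd))
  dev - stats::ave(dev, panel$dataset_id)
}

# weighted OLS via normal equations (closed form)
wols_oracle <- function(X, y, w) {
  XtW <- t(X * w)
  solve(XtW %*% X, XtW %*% y)
}
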