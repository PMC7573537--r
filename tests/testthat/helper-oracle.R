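# Independent Monte-Carlo oracle for the JZS Bayes factor: the numerator
# integral is estimated as the average of the noncentral-t likelihood over
# Cauchy prior draws. It shares no code with the quadrature path in the
# package.
#
# The noncentral-t density as a function of the noncentrality parameter is
# smooth, so it is tabulated once on a dense grid (log scale, spacing ~0.01)
# and evaluated for the 1e7 draws by cubic-spline interpolation; the
# tabulation error is orders of magnitude below the Monte-Carlo noise.
# Draws falling outside the tabulated support contribute a density that
# underflows double precision and are counted as zero.
mc_jzs_bf <- function(t, df, n_eff, scale = sqrt(0.5), draws = 1e7,
                      seed = 42) {
  set.seed(seed)
  delta <- stats::rcauchy(draws, location = 0, scale = scale)
  ncp <- delta * sqrt(n_eff)
  lo <- min(-50, t - 60)
  hi <- max(50, t + 60)
  grid <- seq(lo, hi, by = 0.01)
  logf <- suppressWarnings(stats::dt(t, df, ncp = grid, log = TRUE))
  keep <- is.finite(logf) & logf > max(logf) - 690
  spl <- stats::splinefun(grid[keep], logf[keep], method = "natural")
  inside <- ncp >= min(grid[keep]) & ncp <= max(grid[keep])
  lik <- numeric(draws)
  lik[inside] <- exp(spl(ncp[inside]))
  mean(lik) / stats::dt(t, df)
}

# closed-form intercept t-statistic of a simple linear regression via the
# normal equations, independent of lm()
normal_equations_intercept_t <- function(y, x) {
  n <- length(y)
  X <- cbind(1, x)
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (n - 2)
  se0 <- sqrt(s2 * XtX_inv[1, 1])
  as.numeric(beta[1] / se0)
}
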