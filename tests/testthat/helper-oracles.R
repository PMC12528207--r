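# Brute-force simple-OLS oracle via the normal equations, kept deliberately
# independent of the fitting code under test (no lm, no package internals).
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- as.vector(y - X %*% beta)
  sst <- sum((y - mean(y))^2)
  list(
    intercept = unname(beta[1, 1]),
    slope = unname(beta[2, 1]),
    residuals = res,
    r2 = if (sst == 0) 1 else 1 - sum(res^2) / sst
  )
}

# Random small regression instance (3-20 points, >= 2 distinct x).
random_ols_instance <- function() {
  n <- sample(3:20, 1)
  repeat {
    x <- round(runif(n, 0, 100), 3)
    if (length(unique(x)) >= 2) break
  }
  list(x = x, y = -5 + 0.07 * x + rnorm(n, 0, 0.5))
}
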