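# Independent brute-force oracle for the model-averaged multivariable MR:
# scores every subset by the full multivariate-normal marginal likelihood
# density (n x n covariance), a different route from the package's
# Cholesky/Woodbury evaluation.
bma_oracle <- function(beta_outcome, se_outcome, beta_exposures,
                       prior_prob, prior_variance) {
  y <- beta_outcome / se_outcome
  X <- as.matrix(beta_exposures) / se_outcome
  p <- ncol(X)
  n <- length(y)
  subsets <- list(integer(0))
  for (k in 1:p) {
    cmb <- combn(p, k)
    subsets <- c(subsets, lapply(seq_len(ncol(cmb)), function(i) cmb[, i]))
  }
  log_ml <- vapply(subsets, function(s) {
    V <- diag(n)
    if (length(s) > 0) {
      Xs <- X[, s, drop = FALSE]
      V <- V + prior_variance * Xs %*% t(Xs)
    }
    -0.5 * (t(y) %*% solve(V, y) + determinant(V)$modulus + n * log(2 * pi))
  }, numeric(1))
  log_prior <- vapply(subsets, function(s) {
    length(s) * log(prior_prob) + (p - length(s)) * log(1 - prior_prob)
  }, numeric(1))
  w <- exp(log_ml + log_prior - max(log_ml + log_prior))
  w <- w / sum(w)
  mip <- mace <- numeric(p)
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    if (length(s) == 0) next
    Xs <- X[, s, drop = FALSE]
    theta <- solve(crossprod(Xs) + diag(1 / prior_variance, length(s)),
                   crossprod(Xs, y))
    mip[s] <- mip[s] + w[i]
    mace[s] <- mace[s] + w[i] * theta
  }
  list(mip = mip, mace = mace, posterior = w)
}
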