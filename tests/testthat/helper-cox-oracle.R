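# Independent proportional-hazards oracle: direct Newton-Raphson
# maximization of the Efron partial likelihood, written from the likelihood
# definition and sharing no code path with the package (which delegates to
# the survival package). Suitable for small fixtures (few covariates).

cox_oracle <- function(X, time, event, tol = 1e-12, max_iter = 100) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  ord <- order(time)
  X <- X[ord, , drop = FALSE]; time <- time[ord]; event <- event[ord]
  beta <- rep(0, p)
  event_times <- unique(time[event == 1])
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    w <- exp(eta)
    grad <- rep(0, p); hess <- matrix(0, p, p); ll <- 0
    for (t in event_times) {
      R <- which(time >= t)                 # risk set
      D <- which(time == t & event == 1)    # failures at t
      d <- length(D)
      S0R <- sum(w[R]); S1R <- colSums(w[R] * X[R, , drop = FALSE])
      S2R <- crossprod(sqrt(w[R]) * X[R, , drop = FALSE])
      S0D <- sum(w[D]); S1D <- colSums(w[D] * X[D, , drop = FALSE])
      S2D <- crossprod(sqrt(w[D]) * X[D, , drop = FALSE])
      ll <- ll + sum(eta[D])
      for (l in seq_len(d) - 1) {
        f <- l / d
        S0 <- S0R - f * S0D
        S1 <- S1R - f * S1D
        S2 <- S2R - f * S2D
        ll <- ll - log(S0)
        grad <- grad - S1 / S0
        hess <- hess - (S2 / S0 - tcrossprod(S1) / S0^2)
      }
    }
    # event-side gradient: sum of covariates over all failures
    grad <- grad + colSums(X[event == 1, , drop = FALSE])
    step <- solve(-hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  info <- -hess
  list(coef = beta, se = sqrt(diag(solve(info))), loglik = ll, iter = iter)
}
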