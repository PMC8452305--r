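## Exact (non-Barnes-Hut) t-SNE on Euclidean distances.
## Population sizes here are O(10^2) cells in 6 dimensions, where the
## quadratic exact gradient is cheap and avoids an external dependency.
## Standard algorithm: per-point Gaussian bandwidths calibrated to a fixed
## perplexity by bisection, symmetrized input affinities, Student-t
## low-dimensional kernel, gradient descent with momentum, early
## exaggeration and per-parameter gain adaptation.

tsne_exact <- function(X, perplexity = 30, n_dims = 2L, max_iter = 500L,
                       eta = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  P <- tsne_input_affinities(X, perplexity)
  P <- (P + t(P)) / (2 * n)
  P[P < .Machine$double.eps] <- .Machine$double.eps
  P <- P / sum(P)
  Y <- matrix(rnorm(n * n_dims, sd = 1e-4), nrow = n)
  dY <- matrix(0, n, n_dims)
  gains <- matrix(1, n, n_dims)
  exaggeration <- 4
  stop_exagg <- 100L
  P_run <- P * exaggeration
  momentum <- 0.5
  for (iter in seq_len(max_iter)) {
    if (iter == stop_exagg) P_run <- P
    if (iter == 250L) momentum <- 0.8
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < .Machine$double.eps] <- .Machine$double.eps
    L <- (P_run - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}

## Row-stochastic Gaussian affinities with per-point bandwidth chosen by
## bisection so that the conditional distribution's perplexity matches.
tsne_input_affinities <- function(X, perplexity, tol = 1e-5, max_tries = 50L) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    beta_min <- -Inf
    beta_max <- Inf
    di <- D2[i, -i]
    for (try in seq_len(max_tries)) {
      p <- exp(-di * beta)
      sump <- sum(p)
      if (sump == 0) { H <- 0; p[] <- 0 }
      else {
        H <- log(sump) + beta * sum(di * p) / sump
        p <- p / sump
      }
      diff <- H - target
      if (abs(diff) < tol) break
      if (diff > 0) {
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P
}
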