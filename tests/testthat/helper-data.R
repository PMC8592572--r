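# shared fixture builders (all generated in code; no stored data)

# a small, fast synthetic experiment
tiny_config <- function(seed = 1, ...) {
  experiment_config(n_fef = 3, n_vertex = 3, n_trials = 40,
                    n_items = 40, seed = seed, ...)
}

# repeat aDDM trials, re-drawing the rare driftless timeouts
sim_trials <- function(n, design, params, fs, max_ms = 20000) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- NULL
    for (k in 1:10) {
      s <- tryCatch(simulate_trial(design, params, fs, max_ms),
                    error = function(e) NULL)
      if (!is.null(s)) break
    }
    if (is.null(s)) stop("persistent simulation timeout in fixture")
    out[[i]] <- s
  }
  out
}

# printed toy logistic fixture (8 rows, 2 clusters, not separable)
toy_logistic <- function() {
  data.frame(
    y = c(0, 1, 1, 0, 1, 0, 0, 1),
    x = c(-1.2, 0.8, -0.5, 1.5, 0.3, 2.0, -2.0, 0.9),
    cluster = c(1, 1, 1, 1, 2, 2, 2, 2))
}

# independent IRLS oracle for logistic regression
irls_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    zvar <- eta + (y - mu) / w
    beta_new <- solve(t(X) %*% (w * X), t(X) %*% (w * zvar))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new)
      break
    }
    beta <- drop(beta_new)
  }
  beta
}

# independent CR1 cluster-sandwich oracle for a glm
sandwich_cluster_oracle <- function(fit, cluster) {
  X <- model.matrix(fit)
  res <- residuals(fit, type = "working") * fit$weights
  scores <- X * res
  G <- length(unique(cluster))
  n <- nrow(X); k <- ncol(X)
  meat <- matrix(0, k, k)
  for (g in unique(cluster)) {
    sg <- colSums(scores[cluster == g, , drop = FALSE])
    meat <- meat + sg %o% sg
  }
  bread <- solve(t(X) %*% (fit$weights * X))
  adj <- G / (G - 1) * (n - 1) / (n - k)
  adj * bread %*% meat %*% bread
}
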