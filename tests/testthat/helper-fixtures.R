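# Shared fixtures and independent test-side oracles.

# Small printed dataset: 3 clusters (sizes 3, 3, 2), both arms represented,
# used to check the GEE machinery against direct matrix evaluation.
fixture_dataset <- function() {
  trial_dataset(
    cluster_id = c(1, 1, 1, 2, 2, 2, 3, 3),
    arm        = c(1, 1, 0, 0, 0, 1, 1, 0),
    y          = c(1.20, 0.80, -0.30, -0.50, 0.10, 0.90, 1.50, 0.20))
}

fixture_binary_dataset <- function() {
  trial_dataset(
    cluster_id = c(1, 1, 1, 2, 2, 2, 3, 3, 4, 4, 5, 6, 7, 8),
    arm        = c(1, 1, 1, 0, 0, 0, 1, 0, 0, 1, 1, 0, 1, 0),
    y          = c(0, 1, 0, 1, 0, 0, 0, 1, 1, 1, 0, 1, 0, 1))
}

# Direct evaluation of the sandwich covariance from per-cluster matrices,
# written independently of the package internals: bread and meat are
# assembled with dense matrix algebra at the supplied parameter values.
oracle_sandwich <- function(data, link, beta, rho_w) {
  sp <- split(seq_along(data$y), cumsum(c(1, diff(as.numeric(
    factor(data$cluster_id, levels = unique(data$cluster_id)))) != 0)))
  bread <- meat <- matrix(0, 2, 2)
  for (idx in sp) {
    X <- cbind(1, data$arm[idx])
    eta <- X %*% beta
    mu <- switch(link, identity = eta, logit = plogis(eta), log = exp(eta))
    vv <- switch(link, identity = rep(1, length(eta)), mu * (1 - mu))
    dd <- switch(link, identity = rep(1, length(eta)),
                 logit = mu * (1 - mu), log = mu)
    D <- as.vector(dd) * X
    n <- length(idx)
    R <- matrix(rho_w, n, n); diag(R) <- 1
    V <- sqrt(as.vector(vv)) * R * rep(sqrt(as.vector(vv)), each = n)
    Vi <- solve(V)
    e <- data$y[idx] - as.vector(mu)
    bread <- bread + t(D) %*% Vi %*% D
    g <- t(D) %*% Vi %*% e
    meat <- meat + g %*% t(g)
  }
  solve(bread) %*% meat %*% solve(bread)
}

# paper-reported simulation tables (observed / expected columns) ------------

# columns: randomization, N, distribution, rho, working, value
grid_rows <- function(randomization, N, dist, rho, ind, exch) {
  rbind(
    data.frame(randomization = randomization, N = N, distribution = dist,
               rho = rho, working = "independence", value = ind),
    data.frame(randomization = randomization, N = N, distribution = dist,
               rho = rho, working = "exchangeable", value = exch))
}

delta_unequal <- c(0.70, 0.15, 0.10, 0.05)
delta_equal <- c(0.25, 0.25, 0.25, 0.25)
gamma_unequal <- gamma_from_delta(delta_unequal)
gamma_equal <- gamma_from_delta(delta_equal)

design_for <- function(N, dist) {
  delta <- if (dist == "unequal") delta_unequal else delta_equal
  g <- gamma_from_delta(delta)
  cluster_size_dist(M_k = round(N * g / seq_along(g)))
}
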