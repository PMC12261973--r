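#' Cluster-size distributions
#'
#' A partially clustered design is summarised by the mix of cluster sizes
#' k = 1, ..., K. Two equivalent parameterisations are used: `gamma[k]`, the
#' proportion of observational units (cluster members) that belong to a
#' cluster of size k, and `delta[k]`, the proportion of clusters that are of
#' size k. Realized counts may be attached: `M_k` clusters of size k, hence
#' `N_k = k * M_k` units in size-k clusters.
#'
#' Exactly one of `gamma`, `delta` or `M_k` must be supplied; the other
#' representations are derived. Proportion vectors must be non-negative and
#' sum to 1 (tolerance 1e-8; they are renormalized to machine precision).
#' Interior zeros are allowed; the last entry (size K) must be positive.
#'
#' @param gamma numeric vector of observation-level proportions.
#' @param delta numeric vector of cluster-level proportions.
#' @param M_k integer vector of realized cluster counts per size.
#' @return an object of class `cluster_size_dist`: a list with elements
#'   `K`, `gamma`, `delta`, and (when counts are known) `M_k`, `N_k`, `M`, `N`.
#' @examples
#' cluster_size_dist(delta = c(0.50, 0.20, 0.20, 0.05, 0.05))
#' cluster_size_dist(M_k = c(280, 60, 40, 20))
#' @export
cluster_size_dist <- function(gamma = NULL, delta = NULL, M_k = NULL) {
  supplied <- !c(is.null(gamma), is.null(delta), is.null(M_k))
  if (sum(supplied) != 1L) {
    stop("supply exactly one of 'gamma', 'delta' or 'M_k'", call. = FALSE)
  }
  if (!is.null(M_k)) {
    if (!is.numeric(M_k) || any(M_k < 0) || any(M_k != round(M_k))) {
      stop("'M_k' must be non-negative integer counts", call. = FALSE)
    }
    if (sum(M_k) == 0) stop("'M_k' must contain at least one cluster",
                            call. = FALSE)
    K <- length(M_k)
    N_k <- seq_len(K) * M_k
    out <- list(K = K,
                gamma = N_k / sum(N_k),
                delta = M_k / sum(M_k),
                M_k = as.integer(M_k), N_k = as.integer(N_k),
                M = as.integer(sum(M_k)), N = as.integer(sum(N_k)))
  } else if (!is.null(delta)) {
    delta <- check_propvec(delta, "delta")
    out <- list(K = length(delta), gamma = gamma_from_delta(delta),
                delta = delta)
  } else {
    gamma <- check_propvec(gamma, "gamma")
    out <- list(K = length(gamma), gamma = gamma,
                delta = delta_from_gamma(gamma))
  }
  structure(out, class = "cluster_size_dist")
}

check_propvec <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x))) {
    stop(sprintf("'%s' must be a non-empty finite numeric vector", name),
         call. = FALSE)
  }
  if (any(x < 0)) {
    stop(sprintf("invalid distribution: '%s' has negative entries", name),
         call. = FALSE)
  }
  s <- sum(x)
  if (s == 0) {
    stop(sprintf("invalid distribution: '%s' sums to zero", name),
         call. = FALSE)
  }
  if (abs(s - 1) > 1e-8) {
    stop(sprintf("invalid distribution: '%s' must sum to 1 (got %.10f)",
                 name, s), call. = FALSE)
  }
  if (x[length(x)] <= 0) {
    stop(sprintf("'%s' must have a positive entry for the maximum size K",
                 name), call. = FALSE)
  }
  x / s
}

#' @export
print.cluster_size_dist <- function(x, ...) {
  cat("Cluster-size distribution (K =", x$K, ")\n")
  tab <- rbind(gamma = round(x$gamma, 4), delta = round(x$delta, 4))
  colnames(tab) <- paste0("k=", seq_len(x$K))
  if (!is.null(x$M_k)) tab <- rbind(tab, M_k = x$M_k, N_k = x$N_k)
  print(tab)
  if (!is.null(x$M)) cat("M =", x$M, "clusters, N =", x$N, "units\n")
  invisible(x)
}

#' Convert cluster-level proportions to observation-level proportions
#'
#' `gamma[k] = k * delta[k] / sum_j(j * delta[j])`: a cluster of size k
#' contributes k observational units, so the observation-level mix up-weights
#' larger clusters.
#'
#' @param delta numeric vector of cluster-level proportions (sums to 1).
#' @return numeric vector `gamma` of the same length (sums to 1).
#' @examples
#' gamma_from_delta(c(0.50, 0.20, 0.20, 0.05, 0.05))
#' @export
gamma_from_delta <- function(delta) {
  delta <- check_propvec(delta, "delta")
  k <- seq_along(delta)
  g <- k * delta
  g / sum(g)
}

#' Convert observation-level proportions to cluster-level proportions
#'
#' Inverse of [gamma_from_delta()]: `delta[k] = (gamma[k]/k) / sum_j(gamma[j]/j)`.
#'
#' @param gamma numeric vector of observation-level proportions (sums to 1).
#' @return numeric vector `delta` of the same length (sums to 1).
#' @examples
#' delta_from_gamma(c(0.1, 0.2, 0.3, 0.4))
#' @export
delta_from_gamma <- function(gamma) {
  gamma <- check_propvec(gamma, "gamma")
  k <- seq_along(gamma)
  d <- gamma / k
  d / sum(d)
}

#' Convert an observation target to a cluster (recruitment) target
#'
#' Given a target number of observational units `N` and the cluster-size mix,
#' the number of clusters that must be recruited is `M = N * sum_k(gamma_k/k)`,
#' rounded up. Under the default `"total-ceiling"` policy the ceiling is
#' applied once to the supplied `N` (which may itself be a per-group target);
#' `"per-group-ceiling"` splits a total `N` 1:1, rounds each group up, and
#' returns the sum, which can give one cluster more.
#'
#' @param N target number of observational units (total, or per group --
#'   the policy is applied to whatever is supplied).
#' @param dist a [cluster_size_dist()] (or a vector interpreted as `gamma`).
#' @param policy rounding policy, `"total-ceiling"` (default) or
#'   `"per-group-ceiling"`.
#' @return integer number of clusters.
#' @examples
#' d <- cluster_size_dist(delta = c(0.50, 0.20, 0.20, 0.05, 0.05))
#' clusters_from_observations(146, d) # 75
#' @export
clusters_from_observations <- function(N, dist,
                                       policy = c("total-ceiling",
                                                  "per-group-ceiling")) {
  policy <- match.arg(policy)
  if (!is.numeric(N) || length(N) != 1L || N < 1) {
    stop("'N' must be a single count >= 1", call. = FALSE)
  }
  dist <- as_cluster_size_dist(dist)
  s <- sum(dist$gamma / seq_len(dist$K))
  if (policy == "total-ceiling") {
    as.integer(ceiling(N * s - 1e-9))
  } else {
    as.integer(2 * ceiling(N / 2 * s - 1e-9))
  }
}

#' Sum-preserving display rounding for proportion vectors
#'
#' Largest-remainder rounding: each entry is floored at the requested number
#' of decimals and the remaining mass is assigned, one unit in the last
#' decimal place at a time, to the entries with the largest remainders, so
#' the rounded vector sums exactly to 1. This is the convention used for
#' displayed cluster-size mixes; plain `round()` can drift (e.g.
#' `gamma_from_delta(c(0.50, 0.20, 0.20, 0.05, 0.05))` has second element
#' 0.2051, which rounds to 0.21 but displays as 0.20 in the sum-preserving
#' convention). Full-precision vectors are always used in computations.
#'
#' @param x proportion vector summing to 1.
#' @param digits decimal places (default 2).
#' @return rounded vector summing to 1 at the displayed precision.
#' @export
round_proportions <- function(x, digits = 2) {
  scale <- 10^digits
  lo <- floor(x * scale)
  rem <- x * scale - lo
  short <- round(scale * sum(x)) - sum(lo)
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    lo[bump] <- lo[bump] + 1
  }
  lo / scale
}

as_cluster_size_dist <- function(x) {
  if (inherits(x, "cluster_size_dist")) return(x)
  if (is.numeric(x)) return(cluster_size_dist(gamma = x))
  stop("expected a 'cluster_size_dist' or a gamma proportion vector",
       call. = FALSE)
}
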