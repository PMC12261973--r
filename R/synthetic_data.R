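#' Build a partially clustered design with realized cluster counts
#'
#' Either fixes the number of clusters of each size (`M_k`) or, to emulate
#' recruitment variability, draws `M_k` from a multinomial distribution with
#' a fixed total number of clusters `M` and cluster-level probabilities
#' `delta` (so the total number of observations varies around its target).
#'
#' @param M_k integer vector of cluster counts per size (fixed mode).
#' @param M total number of clusters (multinomial mode).
#' @param delta cluster-level size proportions (multinomial mode).
#' @param seed optional RNG seed for the multinomial draw.
#' @return a [cluster_size_dist()] carrying realized counts.
#' @examples
#' build_design(M_k = c(280, 60, 40, 20))
#' build_design(M = 200, delta = c(0.7, 0.15, 0.1, 0.05), seed = 1)
#' @export
build_design <- function(M_k = NULL, M = NULL, delta = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(M_k)) {
    if (is.null(M) || is.null(delta)) {
      stop("supply 'M_k', or 'M' together with 'delta'", call. = FALSE)
    }
    if (M < 1) stop("'M' must be >= 1", call. = FALSE)
    delta <- check_propvec(delta, "delta")
    M_k <- as.integer(rmultinom(1, M, delta))
    # guarantee a valid distribution object: K is the largest realized size
    while (length(M_k) > 1 && M_k[length(M_k)] == 0) {
      M_k <- M_k[-length(M_k)]
    }
  }
  cluster_size_dist(M_k = M_k)
}

#' Randomize a partially clustered design
#'
#' Assigns observational units to two arms. Under `"cluster"` randomization
#' whole clusters go to one arm; under `"individual"` randomization each
#' member is assigned separately. `balance = "strict"` enforces the balance
#' assumptions the closed-form DEFFs are derived under: equal numbers in each
#' arm overall *and within every cluster size* (for cluster randomization
#' this means half the clusters of each size per arm, requiring even `M_k`;
#' for individual randomization, exactly `N_k/2` treated members within each
#' size, requiring even `N_k`). `balance = "relaxed"` only balances the arms
#' overall: cluster randomization assigns half of all clusters to each arm
#' without stratifying by size, individual randomization samples `N/2`
#' treated members.
#'
#' The expected-proportions assumption on within-cluster patterns is not
#' enforced per dataset; it holds on average over replicates.
#'
#' @param design a [cluster_size_dist()] with realized counts (see
#'   [build_design()]).
#' @param method `"cluster"` or `"individual"`.
#' @param balance `"strict"` (default) or `"relaxed"`.
#' @param seed optional RNG seed.
#' @return an [allocation_table()] with one row per cluster.
#' @export
randomize <- function(design, method = c("cluster", "individual"),
                      balance = c("strict", "relaxed"), seed = NULL) {
  method <- match.arg(method)
  balance <- match.arg(balance)
  design <- as_cluster_size_dist(design)
  if (is.null(design$M_k)) {
    stop("'design' must carry realized cluster counts (use build_design())",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  M_k <- design$M_k
  sizes <- rep(seq_along(M_k), M_k)
  M <- length(sizes)
  t <- integer(M)
  if (method == "cluster") {
    if (balance == "strict") {
      odd <- which(M_k %% 2L == 1L & M_k > 0L)
      if (length(odd)) {
        stop(sprintf("strict cluster randomization needs an even number of clusters of every size; size %s has an odd count",
                     paste(odd, collapse = ", ")), call. = FALSE)
      }
      for (k in which(M_k > 0)) {
        idx <- which(sizes == k)
        trt <- sample(idx, M_k[k] / 2)
        t[trt] <- k
      }
    } else {
      if (M %% 2L == 1L) {
        stop("relaxed cluster randomization needs an even total number of clusters", call. = FALSE)
      }
      trt <- sample(M, M / 2)
      t[trt] <- sizes[trt]
    }
  } else {
    if (balance == "strict") {
      oddN <- which((seq_along(M_k) * M_k) %% 2L == 1L)
      if (length(oddN)) {
        stop(sprintf("strict individual randomization needs an even number of members within every cluster size; size %s is infeasible",
                     paste(oddN, collapse = ", ")), call. = FALSE)
      }
      for (k in which(M_k > 0)) {
        idx <- which(sizes == k)
        slots <- rep(idx, each = k)
        trt <- sample(length(slots), k * M_k[k] / 2)
        t <- t + tabulate(slots[trt], nbins = M)
      }
    } else {
      N <- sum(sizes)
      if (N %% 2L == 1L) {
        stop("relaxed individual randomization needs an even total sample size", call. = FALSE)
      }
      slots <- rep(seq_len(M), sizes)
      trt <- sample(N, N / 2)
      t <- tabulate(slots[trt], nbins = M)
    }
  }
  allocation_table(sizes, t)
}

alloc_members <- function(alloc) {
  # expand an allocation table to member level; treated members come first
  # within a cluster (member order is exchangeable)
  n <- alloc$n
  cluster <- rep(seq_along(n), n)
  member <- sequence(n)
  arm <- as.numeric(member <= rep(alloc$t, n))
  list(cluster = cluster, member = member, arm = arm, n = n)
}

#' Generate continuous outcomes with exchangeable within-cluster correlation
#'
#' Linear mixed model `Y_ij = beta0 + beta1 X_ij + a_i + e_ij` with cluster
#' effect `a_i ~ N(0, rho * sigma2)` and residual
#' `e_ij ~ N(0, (1 - rho) * sigma2)`, so the marginal variance is `sigma2`
#' and the ICC is `rho`.
#'
#' @param alloc an [allocation_table()] (see [randomize()]).
#' @param rho ICC in `[0, 1)`.
#' @param beta1 treatment effect (default 0.25).
#' @param beta0 intercept (default 0).
#' @param sigma2 total outcome variance (default 1).
#' @param seed optional RNG seed.
#' @return a [trial_dataset()].
#' @export
gen_continuous <- function(alloc, rho, beta1 = 0.25, beta0 = 0, sigma2 = 1,
                           seed = NULL) {
  stopifnot(inherits(alloc, "allocation_table"))
  check_rho(rho)
  if (!is.null(seed)) set.seed(seed)
  mm <- alloc_members(alloc)
  a <- rnorm(length(mm$n), 0, sqrt(rho * sigma2))
  y <- beta0 + beta1 * mm$arm + a[mm$cluster] +
    rnorm(length(mm$arm), 0, sqrt((1 - rho) * sigma2))
  new_trial_dataset(mm$cluster, mm$member, mm$arm, y, "continuous")
}

#' Generate exchangeable correlated binary outcomes
#'
#' Sequential conditional-linear-family construction: members of a cluster
#' are drawn in order, the conditional success probability of member j being
#' `p_j + b_j * s_j * sum_{i<j} (y_i - p_i)/s_i` with
#' `b_j = rho / (1 + (j-2) rho)` and `s = sqrt(p(1-p))`. When every
#' conditional probability lies in `[0, 1]` for every attainable history,
#' this yields exact marginal means (`pi_I` or `pi_C` by arm) and exact
#' pairwise correlation `rho` for every pair in the cluster, including pairs
#' in opposite arms of mixed clusters (a single exchangeable `rho`).
#'
#' Feasibility is checked up front for every cluster composition present:
#' for each (size, treated-count) pattern the member ordering with the
#' smallest worst-case bound violation is selected (single-arm clusters and
#' all mixed clusters at moderate `rho` are exactly feasible). If some
#' composition is infeasible under every ordering -- which happens for
#' mixed-arm clusters when `rho` approaches the Frechet bound for the
#' cross-arm pair -- behaviour is governed by `infeasible`: `"error"`
#' (default) reports the violated bound, `"clamp"` truncates the offending
#' conditional probabilities into `[0, 1]` and records the number of clamped
#' draws in the `clamped` attribute of the result (marginal moments are then
#' mildly distorted for those compositions).
#'
#' @param alloc an [allocation_table()].
#' @param rho ICC in `[0, 1)`.
#' @param pi_I,pi_C marginal prevalence on intervention / control (defaults
#'   0.3 / 0.4).
#' @param seed optional RNG seed.
#' @param infeasible `"error"` or `"clamp"`.
#' @return a [trial_dataset()] with attribute `clamped` (count of clamped
#'   conditional probabilities, 0 when the construction is exact).
#' @export
gen_binary <- function(alloc, rho, pi_I = 0.3, pi_C = 0.4, seed = NULL,
                       infeasible = c("error", "clamp")) {
  stopifnot(inherits(alloc, "allocation_table"))
  infeasible <- match.arg(infeasible)
  check_rho(rho)
  check_prob(pi_I, "pi_I")
  check_prob(pi_C, "pi_C")
  if (!is.null(seed)) set.seed(seed)
  ord <- binary_orderings(alloc, rho, pi_I, pi_C,
                          error_on_infeasible = infeasible == "error")
  # member arms per cluster follow the selected ordering
  n <- alloc$n
  cluster <- rep(seq_along(n), n)
  member <- sequence(n)
  arm <- unlist(ord$arm[paste(n, alloc$t)], use.names = FALSE)
  p <- ifelse(arm == 1, pi_I, pi_C)
  s <- sqrt(p * (1 - p))
  y <- numeric(length(p))
  zsum <- numeric(length(n)) # running sum of (y - p)/s per cluster
  clamped <- 0L
  pos_of <- split(seq_along(p), member)
  for (j in seq_len(max(n))) {
    idx <- pos_of[[j]]
    cl <- cluster[idx]
    lambda <- if (j == 1) {
      p[idx]
    } else {
      bj <- rho / (1 + (j - 2) * rho)
      p[idx] + bj * s[idx] * zsum[cl]
    }
    out_of_range <- lambda < 0 | lambda > 1
    if (any(out_of_range)) {
      clamped <- clamped + sum(out_of_range)
      lambda <- pmin(pmax(lambda, 0), 1)
    }
    yj <- as.numeric(runif(length(idx)) < lambda)
    y[idx] <- yj
    zsum[cl] <- zsum[cl] + (yj - p[idx]) / s[idx]
  }
  res <- new_trial_dataset(cluster, member, arm, y, "binary")
  attr(res, "clamped") <- clamped
  res
}

# For each (n, t) composition in the table, pick the member ordering (arm
# sequence) minimising the worst-case violation of the conditional-probability
# bounds; optionally error if even the best ordering violates them.
binary_orderings <- function(alloc, rho, pi_I, pi_C, error_on_infeasible) {
  comps <- unique(data.frame(n = alloc$n, t = alloc$t))
  arms <- list()
  for (i in seq_len(nrow(comps))) {
    n <- comps$n[i]; t <- comps$t[i]
    key <- paste(n, t)
    if (n == 1 || t %in% c(0L, n) || rho == 0) {
      arms[[key]] <- as.numeric(seq_len(n) <= t)
      next
    }
    patterns <- utils::combn(n, t, simplify = FALSE)
    best <- NULL; best_viol <- Inf
    for (pos in patterns) {
      a <- as.numeric(seq_len(n) %in% pos)
      p <- ifelse(a == 1, pi_I, pi_C)
      s <- sqrt(p * (1 - p))
      viol <- 0
      for (j in 2:n) {
        bj <- rho / (1 + (j - 2) * rho)
        lo <- p[j] - bj * s[j] * sum(p[1:(j - 1)] / s[1:(j - 1)])
        hi <- p[j] + bj * s[j] * sum((1 - p[1:(j - 1)]) / s[1:(j - 1)])
        viol <- viol + max(0, -lo) + max(0, hi - 1)
      }
      if (viol < best_viol) { best <- a; best_viol <- viol }
      if (viol == 0) break
    }
    if (best_viol > 1e-12 && error_on_infeasible) {
      stop(sprintf(
        "infeasible (pi, rho): clusters of size %d with %d treated members violate the conditional-probability bounds by %.4f under every member ordering; reduce rho (cross-arm Frechet bound) or use infeasible = \"clamp\"",
        n, t, best_viol), call. = FALSE)
    }
    arms[[key]] <- best
  }
  list(arm = arms)
}
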