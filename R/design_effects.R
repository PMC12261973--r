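#' Analysis specification for a partially clustered trial
#'
#' Bundles the design and analysis choices a DEFF depends on: how clustered
#' observations are randomized, which working correlation the GEE will use,
#' the outcome type and link, the ICC, and (for binary outcomes) the assumed
#' prevalences in each arm.
#'
#' @param outcome `"continuous"` or `"binary"`.
#' @param randomization `"cluster"` (whole clusters to one arm) or
#'   `"individual"` (members randomized independently).
#' @param working GEE working correlation, `"independence"` or
#'   `"exchangeable"`.
#' @param rho intracluster correlation coefficient. Closed forms require
#'   `0 <= rho < 1`; the matrix oracle also accepts `-1/(K-1) < rho < 0`.
#' @param link `"identity"` (continuous; default), `"logit"` or `"log"`
#'   (binary; default `"logit"`).
#' @param pi_I,pi_C assumed outcome prevalence in the intervention / control
#'   arm; required for binary outcomes, each in (0, 1).
#' @param sigma2 outcome variance for continuous outcomes (default 1; DEFFs
#'   do not depend on it).
#' @return an object of class `design_spec`.
#' @examples
#' design_spec("binary", "individual", "exchangeable", rho = 0.2,
#'             pi_I = 0.3, pi_C = 0.4)
#' @export
design_spec <- function(outcome = c("continuous", "binary"),
                        randomization = c("cluster", "individual"),
                        working = c("independence", "exchangeable"),
                        rho,
                        link = NULL,
                        pi_I = NULL, pi_C = NULL,
                        sigma2 = 1) {
  outcome <- match.arg(outcome)
  randomization <- match.arg(randomization)
  working <- match.arg(working)
  if (is.null(link)) link <- if (outcome == "continuous") "identity" else "logit"
  if (outcome == "continuous" && link != "identity") {
    stop("continuous outcomes use the identity link", call. = FALSE)
  }
  if (outcome == "binary") {
    if (!link %in% c("logit", "log")) {
      stop("binary outcomes use the 'logit' or 'log' link", call. = FALSE)
    }
    if (is.null(pi_I) || is.null(pi_C)) {
      stop("binary outcomes require prevalences 'pi_I' and 'pi_C'",
           call. = FALSE)
    }
    check_prob(pi_I, "pi_I")
    check_prob(pi_C, "pi_C")
  }
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho >= 1) {
    stop("'rho' must be a single number < 1", call. = FALSE)
  }
  if (!is.numeric(sigma2) || sigma2 <= 0) {
    stop("'sigma2' must be positive", call. = FALSE)
  }
  structure(list(outcome = outcome, randomization = randomization,
                 working = working, rho = rho, link = link,
                 pi_I = pi_I, pi_C = pi_C, sigma2 = sigma2),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("Design: %s outcome (%s link), %s randomization, %s GEE, rho = %g\n",
              x$outcome, x$link, x$randomization, x$working, x$rho))
  if (x$outcome == "binary") {
    cat(sprintf("Prevalences: pi_I = %g, pi_C = %g\n", x$pi_I, x$pi_C))
  }
  invisible(x)
}

#' Per-cluster allocation table
#'
#' Records, for each cluster, its size `n` and its treatment split: `t`
#' members on intervention, `c = n - t` on control. The general DEFFs and the
#' matrix oracle are sums of per-cluster terms, so an optional `weight`
#' column allows fractional cluster counts; this is how expected-proportions
#' mixtures over allocation patterns are represented.
#'
#' @param n integer vector of cluster sizes.
#' @param t integer vector, members on intervention per cluster (`0 <= t <= n`).
#' @param weight optional non-negative cluster multiplicities (default 1).
#' @return an object of class `allocation_table` (a data frame with columns
#'   `n`, `t`, `c`, `weight`) with attributes `N`, `N_I`, `N_C`.
#' @examples
#' allocation_table(n = c(2, 2, 1, 1), t = c(2, 0, 1, 0))
#' @export
allocation_table <- function(n, t, weight = NULL) {
  if (length(n) == 0) stop("empty allocation table", call. = FALSE)
  if (is.null(weight)) weight <- rep(1, length(n))
  if (length(t) != length(n) || length(weight) != length(n)) {
    stop("'n', 't' and 'weight' must have equal length", call. = FALSE)
  }
  if (any(n < 1) || any(t < 0) || any(t > n) || any(weight < 0)) {
    stop("need n >= 1, 0 <= t <= n and weight >= 0", call. = FALSE)
  }
  out <- data.frame(n = n, t = t, c = n - t, weight = weight)
  attr(out, "N") <- sum(weight * n)
  attr(out, "N_I") <- sum(weight * t)
  attr(out, "N_C") <- sum(weight * (n - t))
  class(out) <- c("allocation_table", "data.frame")
  out
}

#' Prevalence term entering the binary individual-randomization DEFFs
#'
#' For a binary outcome under individual randomization the DEFF depends on
#' the arm prevalences only through
#' `h = sqrt(pi_I pi_C (1-pi_I)(1-pi_C)) / (pi_I(1-pi_I) + pi_C(1-pi_C))`
#' (logit link); for the log link the denominator is
#' `pi_I(1-pi_C) + pi_C(1-pi_I)`. `h` lies in (0, 0.5], and equals 0.5 --
#' making the binary DEFFs coincide with the continuous ones -- exactly when
#' `pi_I == pi_C` or `pi_I == 1 - pi_C`.
#'
#' @param pi_I,pi_C prevalences in (0, 1).
#' @param link `"logit"` or `"log"`.
#' @return a number in (0, 0.5].
#' @examples
#' h_term(0.3, 0.4, "logit")
#' @export
h_term <- function(pi_I, pi_C, link = c("logit", "log")) {
  link <- match.arg(link)
  check_prob(pi_I, "pi_I")
  check_prob(pi_C, "pi_C")
  num <- sqrt(pi_I * pi_C * (1 - pi_I) * (1 - pi_C))
  den <- if (link == "logit") {
    pi_I * (1 - pi_I) + pi_C * (1 - pi_C)
  } else {
    pi_I * (1 - pi_C) + pi_C * (1 - pi_I)
  }
  num / den
}

#' Closed-form design effects for partially clustered trials
#'
#' Evaluates the randomization-specific DEFF for the design described by
#' `spec` and the cluster-size mix `dist`. Writing `g[k]` for the proportion
#' of observations in clusters of size k and `rho` for the ICC:
#'
#' * cluster randomization, independence GEE (any outcome):
#'   `1 + rho * sum((k-1) g[k])`
#' * cluster randomization, exchangeable GEE (any outcome):
#'   `1 / sum(g[k] / (1 + (k-1) rho))`
#' * individual randomization, continuous outcome: independence GEE gives 1;
#'   exchangeable GEE gives
#'   `1 / sum(g[k] (1 + (k-2) rho) / ((1-rho)(1 + (k-1) rho)))`
#' * individual randomization, binary outcome: as the continuous forms but
#'   shifted by the prevalence term `h` ([h_term()]); with
#'   `S1 = sum(g[k]/(1+(k-1)rho))` and `S2 = sum((k-1) g[k]/(1+(k-1)rho))`,
#'   the independence GEE gives `1 + rho (1/2 - h) sum((k-1) g[k])` and the
#'   exchangeable GEE gives
#'   `(S1 + (1/2-h)(rho/(1-rho)) S2) / (S1^2 + (rho/(1-rho)) S1 S2)`.
#'
#' All forms equal 1 when `rho = 0` or all clusters are singletons. Values
#' are returned at full precision; round for presentation.
#'
#' @param spec a [design_spec()].
#' @param dist a [cluster_size_dist()] (or a `gamma` proportion vector).
#' @return the DEFF (positive scalar).
#' @examples
#' d <- cluster_size_dist(gamma = c(0.70, 0.25, 0.05))
#' s <- design_spec("continuous", "cluster", "independence", rho = 0.5)
#' deff_closed_form(s, d) # 1.175
#' @export
deff_closed_form <- function(spec, dist) {
  stopifnot(inherits(spec, "design_spec"))
  dist <- as_cluster_size_dist(dist)
  rho <- check_rho(spec$rho)
  g <- dist$gamma
  k <- seq_along(g)
  if (spec$randomization == "cluster") {
    # binary cluster-randomized DEFFs coincide with the continuous ones
    if (spec$working == "independence") {
      return(1 + rho * sum((k - 1) * g))
    }
    return(1 / sum(g / (1 + (k - 1) * rho)))
  }
  # individual randomization
  if (spec$outcome == "continuous") {
    if (spec$working == "independence") return(1)
    if (rho == 0) return(1)
    return(1 / sum(g * (1 + (k - 2) * rho) / ((1 - rho) * (1 + (k - 1) * rho))))
  }
  h <- h_term(spec$pi_I, spec$pi_C, spec$link)
  if (spec$working == "independence") {
    return(1 + rho * (0.5 - h) * sum((k - 1) * g))
  }
  if (rho == 0) return(1)
  S1 <- sum(g / (1 + (k - 1) * rho))
  S2 <- sum((k - 1) * g / (1 + (k - 1) * rho))
  r <- rho / (1 - rho)
  (S1 + (0.5 - h) * r * S2) / (S1^2 + r * S1 * S2)
}

#' General design effect, independence working correlation
#'
#' Allocation-based form valid for any pattern of treatment splits within
#' clusters, assuming overall 1:1 balance (`N_I = N_C = N/2`):
#' `DEFF = 1 + rho * ((sum(n_i^2) - 4 sum(t_i c_i)) / N - 1)`.
#' Continuous outcomes, identity link.
#'
#' @param alloc an [allocation_table()].
#' @param rho ICC.
#' @return the DEFF.
#' @examples
#' deff_general_independence(allocation_table(n = c(2, 2), t = c(2, 0)), 0.5)
#' @export
deff_general_independence <- function(alloc, rho) {
  stopifnot(inherits(alloc, "allocation_table"))
  check_rho(rho, allow_negative = TRUE, kmax = max(alloc$n))
  w <- alloc$weight
  N <- sum(w * alloc$n)
  1 + rho * ((sum(w * alloc$n^2) - 4 * sum(w * alloc$t * alloc$c)) / N - 1)
}

#' General design effect, exchangeable working correlation
#'
#' Allocation-based form for a continuous outcome analysed by a GEE whose
#' exchangeable working correlation equals the true ICC. With
#' `A = sum(n_i / (1 + (n_i - 1) rho))`,
#' `B = sum(t_i (1 + (c_i - 1) rho) / ((1 - rho)(1 + (n_i - 1) rho)))` and
#' `C = sum(t_i / (1 + (n_i - 1) rho))`, the DEFF under overall 1:1 balance is
#' `N A / (4 (A B - C^2))`.
#'
#' @inheritParams deff_general_independence
#' @return the DEFF.
#' @export
deff_general_exchangeable <- function(alloc, rho) {
  stopifnot(inherits(alloc, "allocation_table"))
  check_rho(rho, allow_negative = TRUE, kmax = max(alloc$n))
  w <- alloc$weight
  n <- alloc$n; t <- alloc$t; cc <- alloc$c
  d <- 1 + (n - 1) * rho
  N <- sum(w * n)
  A <- sum(w * n / d)
  B <- sum(w * t * (1 + (cc - 1) * rho) / ((1 - rho) * d))
  C <- sum(w * t / d)
  den <- 4 * (A * B - C^2)
  if (den <= 1e-9 * N * A) {
    stop("degenerate design: both arms must be represented", call. = FALSE)
  }
  N * A / den
}

#' Design effect by direct evaluation of the sandwich covariance
#'
#' Ground-truth oracle: assembles, cluster by cluster, the model derivative
#' matrices `D_i`, the working covariance `V_i = A_i^{1/2} R_i A_i^{1/2}` at
#' the true parameter values, and the true exchangeable correlation `C_i`,
#' and evaluates the sandwich covariance
#' `(sum D'V^{-1}D)^{-1} (sum D'V^{-1} cov(Y) V^{-1} D) (sum D'V^{-1}D)^{-1}`.
#' The DEFF is the ratio of its treatment-coefficient element to the
#' classical (model-based) variance from the corresponding independence
#' regression. Cluster `weight`s multiply each cluster's contribution, so a
#' fractional table can represent an expected-proportions mixture of
#' allocation patterns.
#'
#' Intended for small designs; cost is linear in the number of table rows.
#'
#' @param alloc an [allocation_table()].
#' @param spec a [design_spec()]; `spec$working` selects the working
#'   correlation, `spec$rho` is the true (and, for exchangeable, working) ICC.
#' @return the DEFF.
#' @export
deff_matrix_oracle <- function(alloc, spec) {
  stopifnot(inherits(alloc, "allocation_table"), inherits(spec, "design_spec"))
  rho <- check_rho(spec$rho, allow_negative = TRUE, kmax = max(alloc$n))
  bread <- meat <- bread_ind <- matrix(0, 2, 2)
  for (i in seq_len(nrow(alloc))) {
    w <- alloc$weight[i]
    if (w == 0) next
    n <- alloc$n[i]; t <- alloc$t[i]
    x <- c(rep(1, t), rep(0, n - t))
    X <- cbind(1, x)
    if (spec$outcome == "continuous") {
      a <- rep(spec$sigma2, n)          # var(Y_ij)
      D <- X                            # identity link
      w_ind <- rep(1 / spec$sigma2, n)  # GLM weight, classical linear model
    } else {
      mu <- ifelse(x == 1, spec$pi_I, spec$pi_C)
      a <- mu * (1 - mu)
      dmu <- if (spec$link == "logit") mu * (1 - mu) else mu
      D <- dmu * X
      w_ind <- dmu^2 / a
    }
    Ci <- matrix(rho, n, n); diag(Ci) <- 1
    Ri <- if (spec$working == "independence") diag(n) else Ci
    As <- sqrt(a)
    Vi <- As * Ri * rep(As, each = n)          # A^1/2 R A^1/2
    covY <- As * Ci * rep(As, each = n)
    ViD <- solve(Vi, D)
    bread <- bread + w * crossprod(D, ViD)
    meat <- meat + w * crossprod(ViD, covY %*% ViD)
    bread_ind <- bread_ind + w * crossprod(X, w_ind * X)
  }
  bi <- solve(bread)
  v_gee <- (bi %*% meat %*% bi)[2, 2]
  v_ind <- solve(bread_ind)[2, 2]
  v_gee / v_ind
}

#' Expected allocation-pattern weights under 1:1 individual randomization
#'
#' Within clusters of size `k` whose members are randomized independently
#' 1:1, the probability that exactly `t` of the `k` members land on the
#' intervention arm is `choose(k, t) / 2^k`, for `t = 0, ..., k`. The
#' individual-randomization closed forms are the general DEFFs averaged over
#' these pattern weights (the "expected proportions" assumption).
#'
#' @param k cluster size (integer >= 1).
#' @return numeric vector of length `k + 1`, the weights for `t = 0:k`.
#' @examples
#' expected_allocation_weights(2) # 0.25 0.50 0.25
#' @export
expected_allocation_weights <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("'k' must be a single integer >= 1", call. = FALSE)
  }
  choose(k, 0:k) / 2^k
}

#' Build the expected (balanced) allocation table implied by a design
#'
#' Returns the fractional [allocation_table()] over which the Table-style
#' closed forms are exact: for cluster randomization, half the clusters of
#' each size on each arm; for individual randomization, the
#' expected-proportions mixture of within-cluster patterns
#' ([expected_allocation_weights()]). Weights are per observational unit of
#' the mix (`gamma[k]/k` clusters of size k), so the table integrates to one
#' observation; DEFFs are scale-invariant in the weights.
#'
#' @param dist a [cluster_size_dist()] (or gamma vector).
#' @param randomization `"cluster"` or `"individual"`.
#' @return an [allocation_table()] with fractional weights.
#' @export
expected_allocation <- function(dist,
                                randomization = c("cluster", "individual")) {
  randomization <- match.arg(randomization)
  dist <- as_cluster_size_dist(dist)
  n <- integer(0); t <- integer(0); wt <- numeric(0)
  for (k in seq_len(dist$K)) {
    gk <- dist$gamma[k]
    if (gk == 0) next
    if (randomization == "cluster") {
      n <- c(n, k, k); t <- c(t, k, 0L); wt <- c(wt, gk / (2 * k), gk / (2 * k))
    } else {
      n <- c(n, rep(k, k + 1)); t <- c(t, 0:k)
      wt <- c(wt, gk / k * expected_allocation_weights(k))
    }
  }
  allocation_table(n, t, wt)
}
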