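#' Effect specification for sample-size planning
#'
#' For a continuous outcome supply the target mean difference `delta` and the
#' outcome standard deviation `sd`; for a binary outcome supply the assumed
#' prevalences `pi_C` (control) and `pi_I` (intervention). `alpha` is the
#' two-sided significance level, `power` the target power.
#'
#' @param delta mean difference (continuous outcomes).
#' @param sd outcome standard deviation (continuous; default 1).
#' @param pi_I,pi_C arm prevalences (binary outcomes), each in (0, 1).
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.80).
#' @return an object of class `effect_spec` with an `outcome` element.
#' @examples
#' effect_spec(delta = 0.92, sd = 2, power = 0.90)
#' effect_spec(pi_C = 0.2, pi_I = 0.14)
#' @export
effect_spec <- function(delta = NULL, sd = 1, pi_I = NULL, pi_C = NULL,
                        alpha = 0.05, power = 0.80) {
  check_prob(alpha, "alpha")
  check_prob(power, "power")
  if (!is.null(delta)) {
    if (delta == 0) stop("'delta' must be non-zero", call. = FALSE)
    if (sd <= 0) stop("'sd' must be positive", call. = FALSE)
    out <- list(outcome = "continuous", delta = delta, sd = sd,
                alpha = alpha, power = power)
  } else {
    if (is.null(pi_I) || is.null(pi_C)) {
      stop("supply 'delta' (continuous) or both 'pi_I' and 'pi_C' (binary)",
           call. = FALSE)
    }
    check_prob(pi_I, "pi_I")
    check_prob(pi_C, "pi_C")
    if (pi_I == pi_C) stop("'pi_I' and 'pi_C' must differ", call. = FALSE)
    out <- list(outcome = "binary", pi_I = pi_I, pi_C = pi_C,
                alpha = alpha, power = power)
  }
  structure(out, class = "effect_spec")
}

#' Per-group sample size for independent continuous data
#'
#' Two-sample comparison of means. The default normal approximation gives
#' `n = 2 sd^2 (z_{1-alpha/2} + z_{power})^2 / delta^2` per group (rounded
#' up); `method = "noncentral_t"` instead searches for the smallest n whose
#' exact two-sample t-test power reaches the target.
#'
#' @param effect an [effect_spec()] with a continuous effect.
#' @param method `"normal"` (default) or `"noncentral_t"`.
#' @return integer per-group sample size.
#' @examples
#' n_independent_continuous(effect_spec(delta = 0.92, sd = 2, power = 0.9))
#' @export
n_independent_continuous <- function(effect, method = c("normal",
                                                        "noncentral_t")) {
  method <- match.arg(method)
  stopifnot(inherits(effect, "effect_spec"), effect$outcome == "continuous")
  za <- qnorm(1 - effect$alpha / 2)
  zb <- qnorm(effect$power)
  n0 <- 2 * effect$sd^2 * (za + zb)^2 / effect$delta^2
  if (method == "normal") return(as.integer(ceiling(n0 - 1e-9)))
  n <- max(2L, as.integer(floor(n0)))
  while (t_test_power(n, effect) < effect$power) n <- n + 1L
  n
}

t_test_power <- function(n_per_group, effect) {
  df <- 2 * n_per_group - 2
  ncp <- abs(effect$delta) / (effect$sd * sqrt(2 / n_per_group))
  tc <- qt(1 - effect$alpha / 2, df)
  1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
}

#' Per-group sample size for independent binary data
#'
#' Two-proportion chi-square test sample size. Uncorrected:
#' `n = (z_{1-alpha/2} sqrt(2 pbar qbar) + z_{power} sqrt(pi_I q_I + pi_C q_C))^2
#'      / (pi_C - pi_I)^2` with `pbar` the mean prevalence. With the
#' continuity correction (default), the Fleiss adjustment
#' `n_c = (n/4) (1 + sqrt(1 + 4 / (n |pi_C - pi_I|)))^2` is applied before
#' rounding up.
#'
#' @param effect an [effect_spec()] with a binary effect.
#' @param continuity_correction apply the Fleiss continuity correction
#'   (default TRUE).
#' @return integer per-group sample size.
#' @examples
#' n_independent_binary(effect_spec(pi_C = 0.2, pi_I = 0.14)) # 647
#' @export
n_independent_binary <- function(effect, continuity_correction = TRUE) {
  stopifnot(inherits(effect, "effect_spec"), effect$outcome == "binary")
  pI <- effect$pi_I; pC <- effect$pi_C
  pbar <- (pI + pC) / 2
  d <- abs(pC - pI)
  za <- qnorm(1 - effect$alpha / 2)
  zb <- qnorm(effect$power)
  n <- (za * sqrt(2 * pbar * (1 - pbar)) +
        zb * sqrt(pI * (1 - pI) + pC * (1 - pC)))^2 / d^2
  if (continuity_correction) {
    n <- n / 4 * (1 + sqrt(1 + 4 / (n * d)))^2
  }
  as.integer(ceiling(n - 1e-9))
}

#' Inflate an independent-data sample size by a design effect
#'
#' Default policy mirrors hand calculation: the DEFF is rounded to 2 decimal
#' places, multiplied by the per-group size, and the product rounded up.
#' `policy = "full"` multiplies at full precision instead.
#'
#' @param n_per_group independent-data per-group sample size.
#' @param deff design effect (positive).
#' @param policy `"round2"` (default) or `"full"`.
#' @return integer per-group target size.
#' @examples
#' apply_deff(647, 1.175) # 764: 647 x 1.18 rounded up
#' @export
apply_deff <- function(n_per_group, deff, policy = c("round2", "full")) {
  policy <- match.arg(policy)
  if (n_per_group < 1) stop("'n_per_group' must be >= 1", call. = FALSE)
  if (deff <= 0) stop("'deff' must be positive", call. = FALSE)
  d <- if (policy == "round2") round2(deff) else deff
  as.integer(ceiling(n_per_group * d - 1e-9))
}

#' Expected power at a given total sample size and design effect
#'
#' Converts the actual total sample size to an effective independent-data
#' size `N_e = N / deff` (split 1:1) and evaluates the power of the
#' corresponding two-sample test. For continuous outcomes the default is the
#' noncentral-t power of the two-sample t-test (`"wald_normal"` optional).
#' For binary outcomes the default (`"pooled_t"`) evaluates a t-approximated
#' test of the prevalence difference with pooled standard deviation
#' `sqrt(pbar (1 - pbar))`; `"wald_normal"` instead uses the normal Wald test
#' of the log odds ratio (logit) or log relative risk (log link) with
#' unpooled variance.
#'
#' @param N_total total (both groups) actual sample size.
#' @param deff design effect (positive).
#' @param effect an [effect_spec()].
#' @param method `"auto"` (the defaults above), `"noncentral_t"`,
#'   `"pooled_t"` or `"wald_normal"`.
#' @param link link function for `"wald_normal"` with binary outcomes
#'   (`"logit"` or `"log"`).
#' @return expected power (proportion in (0, 1)).
#' @examples
#' expected_power(600, 1, effect_spec(delta = 0.25, power = 0.85)) # 0.8637
#' @export
expected_power <- function(N_total, deff, effect,
                           method = c("auto", "noncentral_t", "pooled_t",
                                      "wald_normal"),
                           link = "logit") {
  method <- match.arg(method)
  stopifnot(inherits(effect, "effect_spec"))
  if (deff <= 0) stop("'deff' must be positive", call. = FALSE)
  ne <- N_total / deff / 2 # effective per-group size
  if (ne < 2) stop("effective sample size too small (N/deff < 4)",
                   call. = FALSE)
  za <- qnorm(1 - effect$alpha / 2)
  if (effect$outcome == "continuous") {
    if (method %in% c("auto", "noncentral_t", "pooled_t")) {
      df <- 2 * ne - 2
      ncp <- abs(effect$delta) / (effect$sd * sqrt(2 / ne))
      tc <- qt(1 - effect$alpha / 2, df)
      return(1 - pt(tc, df, ncp) + pt(-tc, df, ncp))
    }
    z <- abs(effect$delta) / (effect$sd * sqrt(2 / ne))
    return(pnorm(z - za) + pnorm(-z - za))
  }
  pI <- effect$pi_I; pC <- effect$pi_C
  if (method %in% c("auto", "pooled_t", "noncentral_t")) {
    pbar <- (pI + pC) / 2
    sdp <- sqrt(pbar * (1 - pbar))
    df <- 2 * ne - 2
    ncp <- abs(pI - pC) / (sdp * sqrt(2 / ne))
    tc <- qt(1 - effect$alpha / 2, df)
    return(1 - pt(tc, df, ncp) + pt(-tc, df, ncp))
  }
  if (link == "logit") {
    b <- abs(qlogis(pI) - qlogis(pC))
    se <- sqrt((1 / (pI * (1 - pI)) + 1 / (pC * (1 - pC))) / ne)
  } else {
    b <- abs(log(pI) - log(pC))
    se <- sqrt(((1 - pI) / pI + (1 - pC) / pC) / ne)
  }
  pnorm(b / se - za) + pnorm(-b / se - za)
}

#' Sample-size plan for a partially clustered trial
#'
#' Composes the full planning workflow: (1) per-group sample size assuming
#' independence; (2) DEFF for the chosen design ([deff_closed_form()]);
#' (3) DEFF-inflated per-group observation target ([apply_deff()]);
#' (4) cluster (recruitment) target ([clusters_from_observations()]);
#' (5) expected power at the achieved size.
#'
#' @param spec a [design_spec()].
#' @param dist a [cluster_size_dist()] (or gamma vector).
#' @param effect an [effect_spec()]; its outcome type must match `spec`.
#' @param continuity_correction for binary base sample sizes (default TRUE).
#' @param deff_policy passed to [apply_deff()].
#' @param cluster_policy passed to [clusters_from_observations()].
#' @return an object of class `sample_size_plan`.
#' @examples
#' plan_sample_size(
#'   design_spec("binary", "cluster", "exchangeable", rho = 0.5,
#'               pi_I = 0.14, pi_C = 0.2),
#'   cluster_size_dist(gamma = c(0.70, 0.25, 0.05)),
#'   effect_spec(pi_C = 0.2, pi_I = 0.14, power = 0.80))
#' @export
plan_sample_size <- function(spec, dist, effect,
                             continuity_correction = TRUE,
                             deff_policy = "round2",
                             cluster_policy = "total-ceiling") {
  stopifnot(inherits(spec, "design_spec"), inherits(effect, "effect_spec"))
  if (spec$outcome != effect$outcome) {
    stop("'spec' and 'effect' disagree on the outcome type", call. = FALSE)
  }
  dist <- as_cluster_size_dist(dist)
  n_ind <- if (effect$outcome == "continuous") {
    n_independent_continuous(effect)
  } else {
    n_independent_binary(effect, continuity_correction)
  }
  deff <- deff_closed_form(spec, dist)
  n_obs <- apply_deff(n_ind, deff, deff_policy)
  structure(list(
    n_independent = n_ind,
    deff = deff, deff_rounded = round2(deff),
    n_observations_per_group = n_obs,
    n_observations_total = 2L * n_obs,
    # clusters are converted from the observation target at the matching
    # scale: the two need not be a factor of two apart under ceiling rounding
    n_clusters_per_group = clusters_from_observations(n_obs, dist,
                                                      cluster_policy),
    n_clusters_total = clusters_from_observations(2L * n_obs, dist,
                                                  cluster_policy),
    expected_power = expected_power(2 * n_obs, deff, effect),
    spec = spec, dist = dist, effect = effect,
    policies = list(deff = deff_policy, clusters = cluster_policy,
                    continuity_correction = continuity_correction)),
    class = "sample_size_plan")
}

#' @export
print.sample_size_plan <- function(x, ...) {
  cat("Sample-size plan for a partially clustered trial\n")
  print(x$spec)
  cat(sprintf("Independent-data size:  %d per group\n", x$n_independent))
  cat(sprintf("DEFF:                   %.4f (applied as %.2f)\n",
              x$deff, x$deff_rounded))
  cat(sprintf("Observation target:     %d per group (%d total)\n",
              x$n_observations_per_group, x$n_observations_total))
  cat(sprintf("Cluster target:         %d per group (%d total)\n",
              x$n_clusters_per_group, x$n_clusters_total))
  cat(sprintf("Expected power:         %.1f%%\n", 100 * x$expected_power))
  invisible(x)
}
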