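#' Run one simulation scenario
#'
#' Replicates the generate / analyse cycle used to validate the design
#' effects: each replicate builds the design (fixed counts, or multinomial
#' counts when `design_mode = "multinomial"`), randomizes it, generates
#' outcomes, fits the GEE under each requested working correlation plus the
#' independence regression, and records the observed DEFF (sandwich variance
#' over classical variance) and the Wald p-value. Replicates whose model fits
#' do not converge are excluded from the aggregates; non-positive definite
#' exchangeable fits are retained and counted.
#'
#' @param design a [cluster_size_dist()] with realized counts: the per-size
#'   cluster numbers of the scenario.
#' @param randomization `"cluster"` or `"individual"`.
#' @param outcome `"continuous"` or `"binary"`.
#' @param rho generating (and analysis) ICC.
#' @param reps number of replicate datasets.
#' @param seed scenario seed (all randomness derives from it).
#' @param link `"identity"`, `"logit"` or `"log"` (defaults by outcome).
#' @param balance `"strict"` (default) or `"relaxed"` randomization balance.
#' @param design_mode `"fixed"` (default) or `"multinomial"` cluster counts.
#' @param beta1,sigma2 continuous generator parameters (defaults 0.25, 1).
#' @param pi_I,pi_C binary generator prevalences (defaults 0.3, 0.4).
#' @param alpha significance level for observed power (default 0.05).
#' @param workings working correlations to fit (default both).
#' @return an object of class `scenario_result`: a list with `summary` (one
#'   row per working correlation) and the scenario settings.
#' @export
run_scenario <- function(design, randomization, outcome, rho, reps, seed,
                         link = NULL,
                         balance = "strict",
                         design_mode = c("fixed", "multinomial"),
                         beta1 = 0.25, sigma2 = 1,
                         pi_I = 0.3, pi_C = 0.4, alpha = 0.05,
                         workings = c("independence", "exchangeable")) {
  design_mode <- match.arg(design_mode)
  design <- as_cluster_size_dist(design)
  workings <- match.arg(workings, several.ok = TRUE)
  if (reps < 1) stop("'reps' must be >= 1", call. = FALSE)
  if (is.null(link)) link <- if (outcome == "continuous") "identity" else "logit"
  set.seed(seed)

  deff_exp <- vapply(workings, function(w) {
    deff_closed_form(design_spec(outcome, randomization, w, rho = rho,
                                 link = link, pi_I = pi_I, pi_C = pi_C,
                                 sigma2 = sigma2), design)
  }, numeric(1))
  effect <- if (outcome == "continuous") {
    effect_spec(delta = beta1, sd = sqrt(sigma2), alpha = alpha)
  } else {
    effect_spec(pi_I = pi_I, pi_C = pi_C, alpha = alpha)
  }
  N_target <- design$N
  power_exp <- vapply(deff_exp, function(d) {
    expected_power(N_target, d, effect)
  }, numeric(1))

  nw <- length(workings)
  deff_obs <- matrix(NA_real_, reps, nw)
  pval <- matrix(NA_real_, reps, nw)
  conv <- matrix(FALSE, reps, nw)
  npd <- matrix(FALSE, reps, nw)
  n_clamped <- 0L

  for (r in seq_len(reps)) {
    # per-replicate failures (e.g., an infeasible randomization draw in
    # multinomial mode) are recorded as non-converged, never raised
    tryCatch({
      des_r <- if (design_mode == "fixed") {
        design
      } else {
        build_design(M = design$M, delta = design$delta)
      }
      alloc <- randomize(des_r, randomization, balance)
      dat <- if (outcome == "continuous") {
        gen_continuous(alloc, rho, beta1 = beta1, sigma2 = sigma2)
      } else {
        # near the cross-arm Frechet bound some mixed-arm compositions are
        # not exactly representable; clamp with diagnostics rather than abort
        gen_binary(alloc, rho, pi_I = pi_I, pi_C = pi_C, infeasible = "clamp")
      }
      n_clamped <- n_clamped + (attr(dat, "clamped") %||% 0L)
      ind <- fit_independent(dat, link)
      for (wi in seq_len(nw)) {
        g <- fit_gee(dat, link, workings[wi])
        ok <- g$converged && ind$converged
        conv[r, wi] <- ok
        npd[r, wi] <- g$npd
        if (ok) {
          deff_obs[r, wi] <- g$vbeta[2, 2] / ind$vbeta[2, 2]
          pval[r, wi] <- g$wald_p
        }
      }
    }, error = function(e) NULL)
  }

  summ <- do.call(rbind, lapply(seq_len(nw), function(wi) {
    use <- conv[, wi]
    dobs <- deff_obs[use, wi]
    data.frame(
      working = workings[wi],
      reps = reps,
      n_converged = sum(use),
      nonconvergence_rate = mean(!use),
      npd_rate = mean(npd[, wi]),
      median_deff_obs = median(dobs),
      deff_exp = unname(deff_exp[wi]),
      median_rel_diff_pct = median(100 * (dobs - deff_exp[wi]) / deff_exp[wi]),
      power_obs = mean(pval[use, wi] <= alpha),
      power_exp = unname(power_exp[wi]),
      stringsAsFactors = FALSE)
  }))
  summ$power_diff_pp <- 100 * (summ$power_obs - summ$power_exp)
  summ$clamped_per_rep <- n_clamped / reps

  structure(list(summary = summ,
                 settings = list(randomization = randomization,
                                 outcome = outcome, link = link, rho = rho,
                                 N = N_target, M_k = design$M_k,
                                 balance = balance, design_mode = design_mode,
                                 reps = reps, seed = seed, alpha = alpha,
                                 beta1 = beta1, sigma2 = sigma2,
                                 pi_I = pi_I, pi_C = pi_C)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Scenario: %s outcome (%s), %s randomization, rho = %g, N = %d, %d reps\n",
              s$outcome, s$link, s$randomization, s$rho, s$N, s$reps))
  df <- x$summary
  df$median_deff_obs <- round(df$median_deff_obs, 3)
  df$deff_exp <- round(df$deff_exp, 3)
  df$median_rel_diff_pct <- round(df$median_rel_diff_pct, 2)
  df$power_obs <- round(100 * df$power_obs, 2)
  df$power_exp <- round(100 * df$power_exp, 2)
  df$power_diff_pp <- round(df$power_diff_pp, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Difference between observed and expected power
#'
#' @param result a `scenario_result` from [run_scenario()].
#' @return named numeric vector (percentage points, observed minus expected),
#'   one element per working correlation.
#' @export
power_comparison <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  stats::setNames(result$summary$power_diff_pp, result$summary$working)
}

#' Run a factorial grid of simulation scenarios
#'
#' Crosses randomization methods, total sample sizes, cluster-size
#' distributions and ICCs for one outcome type / link, running
#' [run_scenario()] for each cell. Scenario seeds are derived from the master
#' seed by a stable hash of the scenario label, so results do not depend on
#' the order in which cells are executed.
#'
#' @param randomization character vector from `c("cluster", "individual")`.
#' @param N integer vector of total sample sizes.
#' @param distributions named list of `delta` (cluster-level proportion)
#'   vectors; each `N * delta_k / k` must be a whole number of clusters.
#' @param rho numeric vector of ICCs.
#' @param outcome,link outcome type and link.
#' @param reps replicates per scenario.
#' @param seed master seed.
#' @param ... further arguments passed to [run_scenario()].
#' @return a data frame of class `pcd_grid`, one row per scenario x working
#'   correlation.
#' @export
run_grid <- function(randomization, N, distributions, rho,
                     outcome, link = NULL, reps, seed, ...) {
  if (is.null(names(distributions))) {
    names(distributions) <- paste0("dist", seq_along(distributions))
  }
  rows <- list()
  for (rnd in randomization) for (n_tot in N) {
    for (dn in names(distributions)) for (r in rho) {
      delta <- distributions[[dn]]
      k <- seq_along(delta)
      M_k <- n_tot * gamma_from_delta(delta) / k # = M * delta_k
      if (any(abs(M_k - round(M_k)) > 1e-9)) {
        stop(sprintf("N = %d is not divisible into whole clusters for distribution '%s'",
                     n_tot, dn), call. = FALSE)
      }
      design <- cluster_size_dist(M_k = round(M_k))
      label <- paste(rnd, n_tot, dn, r, outcome, sep = "|")
      res <- run_scenario(design, rnd, outcome, r, reps,
                          seed = derive_seed(seed, label), link = link, ...)
      s <- res$summary
      s <- cbind(data.frame(randomization = rnd, N = n_tot,
                            distribution = dn, rho = r,
                            outcome = outcome, link = res$settings$link,
                            stringsAsFactors = FALSE),
                 s)
      rows[[label]] <- s
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pcd_grid", "data.frame")
  out
}
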