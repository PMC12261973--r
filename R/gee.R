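#' Long-format trial dataset
#'
#' Constructs and validates the long-format representation of a partially
#' clustered trial: one row per observational unit, with its cluster id,
#' member index within the cluster, treatment arm (1 = intervention,
#' 0 = control) and outcome.
#'
#' @param cluster_id vector identifying the cluster of each unit (rows of the
#'   same cluster must be contiguous).
#' @param arm 0/1 treatment indicator per unit.
#' @param y outcome per unit (numeric; 0/1 for binary outcomes).
#' @param member_id optional member index within cluster (derived if absent).
#' @param outcome `"continuous"` or `"binary"`; inferred from `y` if missing.
#' @return a data frame of class `trial_dataset` with columns `cluster_id`,
#'   `member_id`, `arm`, `y` and attribute `outcome`.
#' @export
trial_dataset <- function(cluster_id, arm, y, member_id = NULL,
                          outcome = NULL) {
  nn <- length(y)
  if (length(cluster_id) != nn || length(arm) != nn) {
    stop("'cluster_id', 'arm' and 'y' must have equal length", call. = FALSE)
  }
  if (!all(arm %in% c(0, 1))) stop("'arm' must be 0/1", call. = FALSE)
  r <- rle(as.character(cluster_id))
  if (anyDuplicated(r$values)) {
    stop("rows of the same cluster must be contiguous", call. = FALSE)
  }
  if (is.null(member_id)) member_id <- sequence(r$lengths)
  if (is.null(outcome)) {
    outcome <- if (all(y %in% c(0, 1))) "binary" else "continuous"
  }
  if (outcome == "binary" && !all(y %in% c(0, 1))) {
    stop("binary outcomes must be coded 0/1", call. = FALSE)
  }
  structure(list(cluster_id = cluster_id, member_id = member_id,
                 arm = as.numeric(arm), y = as.numeric(y)),
            class = c("trial_dataset", "data.frame"),
            row.names = c(NA_integer_, -nn), outcome = outcome)
}

# internal fast constructor: callers guarantee validity
new_trial_dataset <- function(cluster_id, member_id, arm, y, outcome) {
  structure(list(cluster_id = cluster_id, member_id = member_id,
                 arm = arm, y = y),
            class = c("trial_dataset", "data.frame"),
            row.names = c(NA_integer_, -length(y)), outcome = outcome)
}

# link helpers --------------------------------------------------------------

link_funs <- function(link) {
  switch(link,
    identity = list(
      linkinv = function(eta) eta,
      mu_eta  = function(mu) rep(1, length(mu)),
      varfun  = function(mu) rep(1, length(mu))),
    logit = list(
      linkinv = function(eta) plogis(eta),
      mu_eta  = function(mu) mu * (1 - mu),
      varfun  = function(mu) mu * (1 - mu)),
    log = list(
      linkinv = function(eta) pmin(exp(eta), 1 - 1e-10),
      mu_eta  = function(mu) mu,
      varfun  = function(mu) mu * (1 - mu)),
    stop("unknown link: ", link, call. = FALSE))
}

arm_counts <- function(arm, y) {
  nI <- sum(arm == 1); nC <- sum(arm == 0)
  list(nI = nI, nC = nC,
       sI = sum(y[arm == 1]), sC = sum(y[arm == 0]))
}

#' Fit the marginal model ignoring clustering
#'
#' Maximum-likelihood fit of `g(mu) = beta0 + beta1 * arm` treating every
#' observation as independent, with the classical (model-based, non-robust)
#' covariance. Because the single regressor is the arm indicator, the MLE has
#' closed form: arm means for the identity link, the 2x2-table estimates for
#' the logit (variance `sum(1/cell)`, Woolf) and log links.
#'
#' @param data a [trial_dataset()] (or list with `arm` and `y`).
#' @param link `"identity"`, `"logit"` or `"log"`.
#' @return an object of class `pcd_fit` with elements `coefficients`,
#'   `vbeta` (classical covariance), `phi`, `converged`, `link`,
#'   `working = "none"`.
#' @export
fit_independent <- function(data, link = c("identity", "logit", "log")) {
  link <- match.arg(link)
  arm <- data$arm; y <- data$y
  ct <- arm_counts(arm, y)
  if (ct$nI == 0 || ct$nC == 0) {
    stop("both arms must be present", call. = FALSE)
  }
  nn <- ct$nI + ct$nC
  converged <- TRUE
  if (link == "identity") {
    mI <- ct$sI / ct$nI; mC <- ct$sC / ct$nC
    beta <- c(mC, mI - mC)
    rss <- sum((y - ifelse(arm == 1, mI, mC))^2)
    s2 <- rss / (nn - 2)
    vb <- s2 * matrix(c(1 / ct$nC, -1 / ct$nC,
                        -1 / ct$nC, 1 / ct$nI + 1 / ct$nC), 2, 2)
    phi <- s2
  } else {
    a <- ct$sI; b <- ct$nI - ct$sI; cc <- ct$sC; d <- ct$nC - ct$sC
    if (min(a, b, cc, d) == 0) {
      # separation / boundary: report the 0.5-corrected estimates, flag
      a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
      converged <- FALSE
    }
    pI <- a / (a + b); pC <- cc / (cc + d)
    if (link == "logit") {
      beta <- c(qlogis(pC), qlogis(pI) - qlogis(pC))
      v0 <- 1 / cc + 1 / d
      v1 <- 1 / a + 1 / b + v0
    } else {
      beta <- c(log(pC), log(pI) - log(pC))
      v0 <- (1 - pC) / ((cc + d) * pC)
      v1 <- (1 - pI) / ((a + b) * pI) + v0
    }
    vb <- matrix(c(v0, -v0, -v0, v1), 2, 2)
    phi <- 1
  }
  names(beta) <- c("(Intercept)", "arm")
  structure(list(coefficients = beta, vbeta = vb, vbeta_model = vb,
                 phi = phi, rho_hat = NA_real_, converged = converged,
                 npd = FALSE, iterations = 0L, link = link,
                 working = "none", n = nn),
            class = "pcd_fit")
}

#' Fit the marginal model by generalized estimating equations
#'
#' Solves the estimating equations `sum_i D_i' V_i^{-1} (Y_i - mu_i) = 0` for
#' the two-parameter marginal model `g(mu) = beta0 + beta1 * arm` by Fisher
#' scoring, with the chosen working correlation structure. For the
#' exchangeable structure, the common correlation is re-estimated at each
#' iteration by the moment estimator on Pearson residuals
#' (`sum of within-cluster cross-products / ((sum n_i(n_i-1)/2 - 2) * phi)`,
#' the geepack convention), and the fit is flagged non-positive definite when
#' the estimate falls outside `[-1, 1]` (results are retained, not truncated).
#' The covariance of the estimates is the robust sandwich form with the
#' empirical outer product of residuals as `cov(Y_i)`; the model-based
#' covariance `phi * (sum D'V^{-1}D)^{-1}` is also returned.
#'
#' Degenerate outcomes (e.g., an all-zero arm with a logit link) are reported
#' via `converged = FALSE` rather than an error.
#'
#' @param data a [trial_dataset()] (or list with `cluster_id`, `arm`, `y`,
#'   rows contiguous by cluster).
#' @param link `"identity"`, `"logit"` or `"log"`.
#' @param working `"independence"` or `"exchangeable"`.
#' @param maxit,tol Fisher-scoring controls: stop when `max(abs(delta)) < tol`
#'   (default 1e-8) or after `maxit` (default 50) iterations.
#' @return an object of class `pcd_fit`: `coefficients`, `vbeta` (sandwich),
#'   `vbeta_model`, `rho_hat`, `phi`, `converged`, `npd`, `iterations`,
#'   `wald_z`, `wald_p`.
#' @export
fit_gee <- function(data, link = c("identity", "logit", "log"),
                    working = c("independence", "exchangeable"),
                    maxit = 50L, tol = 1e-8) {
  link <- match.arg(link)
  working <- match.arg(working)
  arm <- data$arm; y <- data$y
  nn <- length(y)
  if (nn < 4) stop("need at least 4 observations", call. = FALSE)
  id <- cumsum(c(1L, data$cluster_id[-1] != data$cluster_id[-nn]))
  ni <- tabulate(id)
  L <- link_funs(link)

  ind <- fit_independent(data, link)
  beta <- unname(ind$coefficients)
  npairs <- sum(ni * (ni - 1)) / 2

  exch <- working == "exchangeable"
  converged <- FALSE
  rho_hat <- 0
  phi <- NA_real_
  it <- 0L
  bread <- NULL; Gmat <- NULL

  for (it in seq_len(maxit)) {
    eta <- beta[1] + beta[2] * arm
    mu <- L$linkinv(eta)
    vv <- L$varfun(mu)
    if (any(!is.finite(mu)) || any(vv <= 0)) break
    sv <- sqrt(vv)
    dmu <- L$mu_eta(mu)
    u1 <- dmu / sv
    u2 <- u1 * arm
    e <- (y - mu) / sv
    r2 <- e * e
    phi <- sum(r2) / (nn - 2)
    cs <- rowsum(cbind(u1, u2, e, u1 * u1, u1 * u2, u2 * u2,
                       u1 * e, u2 * e, r2), id, reorder = FALSE)
    S1 <- cs[, 1]; S2 <- cs[, 2]; Se <- cs[, 3]
    P11 <- cs[, 4]; P12 <- cs[, 5]; P22 <- cs[, 6]
    P1e <- cs[, 7]; P2e <- cs[, 8]; Sr2 <- cs[, 9]
    rho_hat <- if (npairs > 2 && phi > 0) {
      sum(Se * Se - Sr2) / 2 / ((npairs - 2) * phi)
    } else 0
    aw <- if (exch) rho_hat else 0
    # exchangeable inverse: R^{-1} = a I + b J
    acoef <- 1 / (1 - aw)
    bcoef <- -aw / ((1 - aw) * (1 + (ni - 1) * aw))
    b11 <- sum(acoef * P11 + bcoef * S1 * S1)
    b12 <- sum(acoef * P12 + bcoef * S1 * S2)
    b22 <- sum(acoef * P22 + bcoef * S2 * S2)
    g1 <- acoef * P1e + bcoef * S1 * Se
    g2 <- acoef * P2e + bcoef * S2 * Se
    det <- b11 * b22 - b12 * b12
    if (!is.finite(det) || abs(det) < 1e-300) break
    sc1 <- sum(g1); sc2 <- sum(g2)
    d1 <- (b22 * sc1 - b12 * sc2) / det
    d2 <- (b11 * sc2 - b12 * sc1) / det
    if (!is.finite(d1) || !is.finite(d2)) break
    beta <- beta + c(d1, d2)
    bread <- matrix(c(b11, b12, b12, b22), 2, 2)
    Gmat <- cbind(g1, g2)
    if (max(abs(c(d1, d2))) < tol) {
      converged <- TRUE
      break
    }
  }

  if (is.null(bread)) { # first iteration failed outright
    bread <- diag(2); Gmat <- matrix(0, 1, 2)
  }
  bi <- solve(bread)
  vb <- bi %*% crossprod(Gmat) %*% bi
  vb_model <- phi * bi
  se1 <- sqrt(vb[2, 2])
  z <- beta[2] / se1
  names(beta) <- c("(Intercept)", "arm")
  structure(list(coefficients = beta, vbeta = vb, vbeta_model = vb_model,
                 rho_hat = if (exch || npairs > 0) rho_hat else NA_real_,
                 phi = phi,
                 converged = converged,
                 npd = exch && (rho_hat < -1 || rho_hat > 1),
                 iterations = it, link = link, working = working, n = nn,
                 wald_z = z, wald_p = 2 * pnorm(-abs(z))),
            class = "pcd_fit")
}

#' @export
print.pcd_fit <- function(x, ...) {
  cat(sprintf("Marginal model fit (%s link, %s working correlation)\n",
              x$link, x$working))
  se <- sqrt(diag(x$vbeta))
  tab <- cbind(estimate = x$coefficients, se = se)
  print(round(tab, 5))
  if (!is.na(x$rho_hat)) cat("rho_hat =", round(x$rho_hat, 5), "\n")
  if (!x$converged) cat("WARNING: fit did not converge\n")
  if (isTRUE(x$npd)) cat("NOTE: non-positive definite working correlation\n")
  invisible(x)
}

#' Wald test for the treatment effect
#'
#' Two-sided test of `beta1 = 0` against a standard normal reference, using
#' the robust (sandwich) standard error for GEE fits and the classical one
#' for independence fits.
#'
#' @param fit a `pcd_fit` from [fit_gee()] or [fit_independent()].
#' @return a list with `statistic` (z), `p.value` and `estimate`.
#' @export
wald_test <- function(fit) {
  stopifnot(inherits(fit, "pcd_fit"))
  se <- sqrt(fit$vbeta[2, 2])
  if (!is.finite(se) || se == 0) {
    stop("zero or undefined standard error", call. = FALSE)
  }
  z <- unname(fit$coefficients[2]) / se
  list(statistic = z, p.value = 2 * pnorm(-abs(z)),
       estimate = unname(fit$coefficients[2]))
}

#' Observed design effect from a trial dataset
#'
#' Ratio of the sandwich variance of the treatment effect from the GEE fit to
#' the classical variance from the corresponding regression that ignores
#' clustering.
#'
#' @inheritParams fit_gee
#' @return the observed DEFF (NA if either fit fails to converge).
#' @export
observed_deff <- function(data, link = c("identity", "logit", "log"),
                          working = c("independence", "exchangeable")) {
  link <- match.arg(link)
  working <- match.arg(working)
  gee <- fit_gee(data, link, working)
  ind <- fit_independent(data, link)
  if (!gee$converged || !ind$converged) return(NA_real_)
  gee$vbeta[2, 2] / ind$vbeta[2, 2]
}
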