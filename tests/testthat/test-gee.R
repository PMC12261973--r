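test_that("identity link with independence working equals ordinary least squares", {
  al <- randomize(build_design(M_k = c(20, 10, 6, 4)), "cluster", "strict",
                  seed = 11)
  dat <- gen_continuous(al, rho = 0.4, seed = 12)
  f <- fit_gee(dat, "identity", "independence")
  ols <- lm(y ~ arm, data = as.data.frame(dat))
  expect_true(f$converged)
  expect_equal(unname(coef(f)), unname(coef(ols)), tolerance = 1e-10)
  fi <- fit_independent(dat, "identity")
  expect_equal(unname(fi$vbeta), unname(vcov(ols)), tolerance = 1e-12)
})

test_that("sandwich covariance equals direct matrix evaluation on fixtures", {
  dat <- fixture_dataset()
  for (wk in c("independence", "exchangeable")) {
    f <- fit_gee(dat, "identity", wk)
    expect_true(f$converged)
    rho_w <- if (wk == "exchangeable") f$rho_hat else 0
    vb <- oracle_sandwich(dat, "identity", unname(coef(f)), rho_w)
    expect_equal(unname(f$vbeta), unname(vb), tolerance = 1e-8)
    expect_equal(f$vbeta[1, 2], f$vbeta[2, 1]) # symmetry
  }
  bdat <- fixture_binary_dataset()
  for (lk in c("logit", "log")) {
    f <- fit_gee(bdat, lk, "exchangeable")
    expect_true(f$converged)
    vb <- oracle_sandwich(bdat, lk, unname(coef(f)), f$rho_hat)
    expect_equal(unname(f$vbeta), unname(vb), tolerance = 1e-8)
  }
})

test_that("the estimating equations are solved at the reported estimates", {
  bdat <- fixture_binary_dataset()
  for (lk in c("logit", "log")) for (wk in c("independence", "exchangeable")) {
    f <- fit_gee(bdat, lk, wk)
    beta <- unname(coef(f))
    rho_w <- if (wk == "exchangeable") f$rho_hat else 0
    score <- c(0, 0)
    for (cl in unique(bdat$cluster_id)) {
      idx <- which(bdat$cluster_id == cl)
      X <- cbind(1, bdat$arm[idx])
      eta <- X %*% beta
      mu <- if (lk == "logit") plogis(eta) else exp(eta)
      vv <- as.vector(mu * (1 - mu))
      dd <- if (lk == "logit") vv else as.vector(mu)
      n <- length(idx)
      R <- matrix(rho_w, n, n); diag(R) <- 1
      V <- sqrt(vv) * R * rep(sqrt(vv), each = n)
      score <- score + t(dd * X) %*% solve(V, bdat$y[idx] - as.vector(mu))
    }
    expect_equal(as.vector(score), c(0, 0), tolerance = 1e-6)
  }
})

test_that("fit_independent matches glm / closed two-sample forms", {
  bdat <- fixture_binary_dataset()
  fl <- fit_independent(bdat, "logit")
  gl <- glm(y ~ arm, family = binomial, data = as.data.frame(bdat))
  expect_equal(unname(coef(fl)), unname(coef(gl)), tolerance = 1e-8)
  expect_equal(unname(fl$vbeta), unname(vcov(gl)), tolerance = 1e-5)
  # Woolf: variance of the log odds ratio is the sum of reciprocal cells
  tab <- table(bdat$arm, bdat$y)
  expect_equal(fl$vbeta[2, 2], sum(1 / tab), tolerance = 1e-12)
  glog <- glm(y ~ arm, family = binomial(link = "log"),
              data = as.data.frame(bdat), start = c(-1, 0))
  flog <- fit_independent(bdat, "log")
  expect_equal(unname(coef(flog)), unname(coef(glog)), tolerance = 1e-6)
  cdat <- fixture_dataset()
  fc <- fit_independent(cdat, "identity")
  nI <- sum(cdat$arm); nC <- sum(1 - cdat$arm)
  s2 <- fc$phi
  expect_equal(fc$vbeta[2, 2], s2 * (1 / nI + 1 / nC), tolerance = 1e-12)
})

test_that("singleton-only data make the working structures equivalent", {
  dat <- trial_dataset(cluster_id = 1:40, arm = rep(c(1, 0), 20),
                       y = rnorm(40))
  fi <- fit_gee(dat, "identity", "independence")
  fe <- fit_gee(dat, "identity", "exchangeable")
  expect_equal(coef(fi), coef(fe), tolerance = 1e-12)
  expect_equal(fi$vbeta, fe$vbeta, tolerance = 1e-12)
  # sandwich and classical variances agree asymptotically; here just close
  ind <- fit_independent(dat, "identity")
  expect_equal(fi$vbeta[2, 2] / ind$vbeta[2, 2], 1, tolerance = 0.2)
})

test_that("rho_hat recovers the generating ICC", {
  al <- allocation_table(n = rep(2, 1500), t = rep(c(2, 0), 750))
  dat <- gen_continuous(al, rho = 0.5, seed = 21)
  f <- fit_gee(dat, "identity", "exchangeable")
  expect_true(f$converged)
  expect_false(f$npd)
  expect_equal(f$rho_hat, 0.5, tolerance = 0.05)
})

test_that("degenerate outcomes flag non-convergence instead of erroring", {
  dat <- trial_dataset(cluster_id = 1:20, arm = rep(c(1, 0), 10),
                       y = rep(c(0, 1), 10)) # intervention arm all zero
  fi <- fit_independent(dat, "logit")
  expect_false(fi$converged)
  f <- fit_gee(dat, "logit", "independence")
  expect_false(f$converged)
})

test_that("wald_test matches the normal reference", {
  dat <- fixture_dataset()
  f <- fit_gee(dat, "identity", "independence")
  w <- wald_test(f)
  se <- sqrt(f$vbeta[2, 2])
  expect_equal(w$statistic, unname(coef(f)[2]) / se, tolerance = 1e-12)
  expect_equal(w$p.value, 2 * pnorm(-abs(w$statistic)), tolerance = 1e-12)
  expect_equal(f$wald_p, w$p.value)
  # z = 1.96 gives p ~ 0.05
  expect_equal(2 * pnorm(-qnorm(0.975)), 0.05, tolerance = 1e-12)
})

test_that("observed_deff is the sandwich-to-classical variance ratio", {
  dat <- fixture_dataset()
  f <- fit_gee(dat, "identity", "exchangeable")
  ind <- fit_independent(dat, "identity")
  expect_equal(observed_deff(dat, "identity", "exchangeable"),
               f$vbeta[2, 2] / ind$vbeta[2, 2], tolerance = 1e-12)
})
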