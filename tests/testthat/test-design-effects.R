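spec_of <- function(outcome, rand, working, rho, link = NULL) {
  design_spec(outcome, rand, working, rho = rho, link = link,
              pi_I = 0.3, pi_C = 0.4)
}

test_that("h_term matches direct arithmetic and its boundary identities", {
  expect_equal(h_term(0.3, 0.4, "logit"), 0.49888765157, tolerance = 1e-10)
  expect_equal(h_term(0.3, 0.4, "log"), 0.48804226784, tolerance = 1e-10)
  expect_equal(h_term(0.3, 0.3, "logit"), 0.5)
  expect_equal(h_term(0.35, 0.65, "logit"), 0.5)
  expect_error(h_term(0, 0.4), "pi_I")
  expect_error(h_term(0.3, 1), "pi_C")
})

test_that("closed-form DEFFs reproduce the worked examples", {
  g1 <- c(0.70, 0.25, 0.05)
  expect_equal(round(deff_closed_form(spec_of("continuous", "cluster",
                                              "independence", 0.5), g1), 2),
               1.18)
  expect_equal(round(deff_closed_form(spec_of("continuous", "cluster",
                                              "exchangeable", 0.5), g1), 2),
               1.12)
  g2 <- c(0.737, 0.263)
  expect_equal(round(deff_closed_form(spec_of("continuous", "cluster",
                                              "independence", 0.5), g2), 2),
               1.13)
  expect_equal(round(deff_closed_form(spec_of("continuous", "cluster",
                                              "exchangeable", 0.5), g2), 2),
               1.10)
  d5 <- cluster_size_dist(delta = c(0.50, 0.20, 0.20, 0.05, 0.05))
  expect_equal(round(deff_closed_form(spec_of("continuous", "individual",
                                              "exchangeable", 0.5), d5), 2),
               0.73)
  expect_equal(deff_closed_form(spec_of("continuous", "individual",
                                        "independence", 0.5), d5), 1)
  expect_equal(round(deff_closed_form(spec_of("continuous", "cluster",
                                              "exchangeable", 0.8),
                                      c(0.1, 0.2, 0.3, 0.4)), 2), 2.25)
})

test_that("all closed forms equal 1 at rho = 0 and for singleton designs", {
  for (outc in c("continuous", "binary")) {
    for (rand in c("cluster", "individual")) {
      for (wk in c("independence", "exchangeable")) {
        link <- if (outc == "binary") "logit" else NULL
        expect_equal(deff_closed_form(spec_of(outc, rand, wk, 0, link),
                                      c(0.2, 0.3, 0.5)), 1)
        expect_equal(deff_closed_form(spec_of(outc, rand, wk, 0.6, link),
                                      1), 1)
      }
    }
  }
})

test_that("binary DEFFs coincide with continuous ones when h = 1/2", {
  g <- c(0.4, 0.3, 0.3)
  for (rand in c("cluster", "individual")) {
    for (wk in c("independence", "exchangeable")) {
      bin <- design_spec("binary", rand, wk, rho = 0.45, link = "logit",
                         pi_I = 0.3, pi_C = 0.3)
      con <- design_spec("continuous", rand, wk, rho = 0.45)
      expect_equal(deff_closed_form(bin, g), deff_closed_form(con, g),
                   tolerance = 1e-12)
    }
  }
})

test_that("general DEFFs match hand-computable cases", {
  singletons <- allocation_table(n = rep(1, 10), t = rep(c(1, 0), 5))
  expect_equal(deff_general_independence(singletons, 0.7), 1)
  expect_equal(deff_general_exchangeable(singletons, 0.7), 1)
  two_pairs <- allocation_table(n = c(2, 2), t = c(2, 0))
  expect_equal(deff_general_independence(two_pairs, 0.5), 1.5)
  # balanced cluster-randomized allocation reproduces the closed form
  al <- randomize(build_design(M_k = c(280, 60, 40, 20)), "cluster",
                  "strict", seed = 3)
  expect_equal(deff_general_independence(al, 0.2),
               deff_closed_form(spec_of("continuous", "cluster",
                                        "independence", 0.2),
                                gamma_unequal), tolerance = 1e-12)
  expect_equal(deff_general_exchangeable(al, 0.2),
               deff_closed_form(spec_of("continuous", "cluster",
                                        "exchangeable", 0.2),
                                gamma_unequal), tolerance = 1e-12)
  expect_error(deff_general_exchangeable(
    allocation_table(n = c(2, 2), t = c(2, 2)), 0.3), "degenerate")
})

test_that("general DEFFs agree with the matrix oracle on random balanced allocations", {
  set.seed(7)
  for (i in 1:40) {
    repeat { # rejection-sample a balanced allocation of <= 6 clusters
      m <- sample(2:6, 1)
      n <- sample(1:4, m, replace = TRUE)
      t <- vapply(n, function(k) sample(0:k, 1), integer(1))
      if (sum(t) == sum(n - t) && sum(t) > 0) break
    }
    al <- allocation_table(n, t)
    for (rho in c(0.15, 0.6)) {
      expect_equal(deff_general_independence(al, rho),
                   deff_matrix_oracle(al, spec_of("continuous", "cluster",
                                                  "independence", rho)),
                   tolerance = 1e-10)
      expect_equal(deff_general_exchangeable(al, rho),
                   deff_matrix_oracle(al, spec_of("continuous", "cluster",
                                                  "exchangeable", rho)),
                   tolerance = 1e-10)
    }
  }
})

test_that("closed forms equal the expected-proportions oracle mixture", {
  for (gam in list(gamma_unequal, gamma_equal)) {
    dist <- cluster_size_dist(gamma = gam)
    for (rand in c("cluster", "individual")) {
      ea <- expected_allocation(dist, rand)
      for (rho in c(0.2, 0.8)) {
        for (wk in c("independence", "exchangeable")) {
          for (cfg in list(list("continuous", NULL),
                           list("binary", "logit"),
                           list("binary", "log"))) {
            sp <- spec_of(cfg[[1]], rand, wk, rho, cfg[[2]])
            expect_equal(deff_closed_form(sp, dist),
                         deff_matrix_oracle(ea, sp), tolerance = 1e-8)
          }
        }
      }
    }
  }
})

test_that("DEFF orderings behave as the theory predicts", {
  g <- gamma_unequal
  rhos <- seq(0.05, 0.9, by = 0.05)
  ci <- vapply(rhos, function(r) deff_closed_form(
    spec_of("continuous", "cluster", "independence", r), g), numeric(1))
  ce <- vapply(rhos, function(r) deff_closed_form(
    spec_of("continuous", "cluster", "exchangeable", r), g), numeric(1))
  ie <- vapply(rhos, function(r) deff_closed_form(
    spec_of("continuous", "individual", "exchangeable", r), g), numeric(1))
  expect_true(all(ci > 1) && all(ce > 1))
  expect_true(all(ci >= ce))
  expect_true(all(diff(ci - ce) > 0)) # gap widens with the ICC
  expect_true(all(ie <= 1) && all(diff(ie) < 0))
})

test_that("expected_allocation_weights are binomial", {
  expect_equal(expected_allocation_weights(2), c(0.25, 0.5, 0.25))
  expect_equal(expected_allocation_weights(1), c(0.5, 0.5))
  expect_equal(expected_allocation_weights(4), c(1, 4, 6, 4, 1) / 16)
  expect_error(expected_allocation_weights(0), "integer")
})

test_that("invalid specifications are rejected", {
  expect_error(design_spec("binary", "cluster", "independence", rho = 0.2),
               "prevalences")
  expect_error(design_spec("continuous", "cluster", "independence", rho = 1),
               "rho")
  expect_error(deff_closed_form(spec_of("continuous", "cluster",
                                        "exchangeable", -0.1),
                                c(0.5, 0.5)), "non-negative")
  expect_error(design_spec("continuous", "cluster", "independence",
                           rho = 0.2, link = "logit"), "identity")
})
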