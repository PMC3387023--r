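test_that("closed-form local decision variable matches the generative-model oracle", {
  set.seed(21)
  for (i in 1:25) {
    kx <- runif(1, 0, 15); ky <- runif(1, 0, 15)
    x <- runif(1, -pi, pi); y <- runif(1, -pi, pi)
    expect_equal(local_d(x, y, kx, ky), d_oracle(x, y, kx, ky),
                 tolerance = 1e-6)
  }
  # no information => likelihood ratio exactly 1
  expect_equal(local_d(0.3, -2, 0, 0), 1)
  # identical measurements, equal concentrations: d = I0(k)^2 / I0(2k) <= 1
  for (k in c(0.5, 3, 10)) {
    expect_equal(local_d(0.7, 0.7, k, k), besselI(k, 0)^2 / besselI(2 * k, 0))
    expect_lte(local_d(0.7, 0.7, k, k), 1)
  }
  expect_error(local_d(NA, 0, 1, 1), "finite")
  expect_error(local_d(0, 0, -1, 1), ">= 0")
})

test_that("local decision variable increases with circular distance", {
  dl <- seq(0, pi, length.out = 60)
  for (kk in list(c(2, 2), c(8, 3), c(0.5, 12))) {
    d <- local_d(0, dl, kk[1], kk[2])
    expect_true(all(diff(d) > 0))
    expect_equal(which.max(local_d(0, seq(-pi, pi, length.out = 201), kk[1], kk[2])),
                 c(1))                     # maximal at distance pi (endpoint)
  }
})

test_that("optimal rule implements prior-weighted mean thresholding", {
  expect_false(optimal_rule(c(1, 1, 1, 1), 0.5))  # exact boundary -> no change
  expect_true(optimal_rule(c(9, 1, 1, 1), 0.5))
  expect_false(optimal_rule(c(2, 0.5, 0.5, 0.5), 0.5))
  # degenerate priors
  expect_true(optimal_rule(c(0.01, 0.01, 0.01, 0.01), 0.999))
  expect_false(optimal_rule(c(50, 50, 50, 50), 1e-4))
  expect_error(optimal_rule(c(1, 1, 1, 1), 0), "p_change")
})

test_that("optimal-rule decisions agree with a brute-force Bayesian posterior", {
  set.seed(22)
  n <- 300
  agree <- logical(n)
  for (i in 1:n) {
    kx <- runif(4, 0.2, 12); ky <- runif(4, 0.2, 12)
    x <- runif(4, -pi, pi); y <- runif(4, -pi, pi)
    d_num <- mapply(d_oracle, x, y, kx, ky, n = 256)
    post_ratio <- 0.5 / 0.5 * mean(d_num)          # numerical marginalization
    d_cf <- local_d(x, y, kx, ky)
    agree[i] <- identical(optimal_rule(d_cf, 0.5), post_ratio > 1)
  }
  expect_identical(mean(agree), 1)
})

test_that("Max rule thresholds the largest local decision variable", {
  expect_true(max_rule(c(0.5, 0.9, 1.1, 0.7), 1.0))
  expect_false(max_rule(c(0.5, 0.9, 1.1, 0.7), 1.1))  # tie -> no change
  expect_false(max_rule(c(0.5, 0.9, 1.1, 0.7), 100))
  expect_true(max_rule(c(0.1, 0.1, 0.1, 0.1), -2.2))  # k <= 0: always change
})

test_that("single-precision Max observers are max-circular-distance observers", {
  # Table-taxonomy equivalence: with one assumed concentration everywhere,
  # thresholding max d_i equals thresholding the max absolute circular
  # difference at a transformed criterion.
  kappa <- kappa_from_j(changedet:::.j_single_max)
  k_crit <- 3
  # transform the criterion: solve d(delta) = k on [0, pi]
  dstar <- uniroot(function(dl) local_d(0, dl, kappa, kappa) - k_crit,
                   c(0, pi), tol = 1e-12)$root
  set.seed(23)
  n <- 1e4
  x <- matrix(runif(4 * n, -pi, pi), n)
  y <- matrix(runif(4 * n, -pi, pi), n)
  d <- matrix(local_d(x, y, kappa, kappa), n)
  dec_d <- apply(d, 1, max) > k_crit
  dec_dist <- apply(circ_dist(x, y), 1, max) > dstar
  expect_identical(dec_d, dec_dist)
})

test_that("assumed concentrations implement the four precision assumptions", {
  pars_vso <- default_params("VSO")
  p <- list(jx = c(2, 4, 6, 8), jy = c(3, 5, 7, 9),
            reliability = c("L", "L", "H", "H"))
  # S: one assumed value for everything
  ks <- assumed_kappas(p, "VSO", pars_vso)
  expect_true(all(ks$kappa_x == kappa_from_j(15)))
  expect_true(all(ks$kappa_y == kappa_from_j(15)))
  # A: arithmetic display mean of realized precision, per display
  ka <- assumed_kappas(p, "VAO", default_params("VAO"))
  expect_true(all(ka$kappa_x == kappa_from_j(5)))
  expect_true(all(ka$kappa_y == kappa_from_j(6)))
  # E under VP: concentrations from the reliability-dependent gamma means
  ke <- assumed_kappas(p, "VEO", default_params("VEO"))
  expect_equal(unique(ke$kappa_x[1:2]), kappa_from_j(6))
  expect_equal(unique(ke$kappa_x[3:4]), kappa_from_j(30))
  # V: the realized values themselves
  kv <- assumed_kappas(p, "VVO", default_params("VVO"))
  expect_equal(kv$kappa_x, kappa_from_j(c(2, 4, 6, 8)))
  # V is not defined under EP encoding
  expect_error(assumed_kappas(p, observer_model("EEO"), default_params("EEO")),
               NA)
})

test_that("decision noise degrades gracefully and vanishes at sigma = 0", {
  d <- matrix(rep(c(2, 0.5, 0.5, 0.5), 50), ncol = 4, byrow = TRUE)
  expect_identical(apply_decision_noise(d, "local", 0, 0.5),
                   optimal_rule(d, 0.5))
  expect_identical(apply_decision_noise(d, "global", 0, 0.5),
                   optimal_rule(d, 0.5))
  set.seed(24)
  big <- replicate(40, mean(apply_decision_noise(d, "global", 50, 0.5)))
  expect_equal(mean(big), 0.5, tolerance = 0.05)  # sign of noise dominates
  expect_error(apply_decision_noise(d, "local", -1, 0.5), ">= 0")
})
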