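# naive (unstabilized) weighted Riemann sum over a factorial grid, used as
# the brute-force oracle for the log-sum-exp path
naive_marginal <- function(ll, grid) {
  w <- lapply(grid, function(x) {
    if (length(x) == 1) return(1)
    h <- (c(diff(x), 0) + c(0, diff(x))) / 2
    h / (x[length(x)] - x[1])
  })
  wtot <- Reduce(function(a, b) as.vector(outer(a, b)), w)
  log(sum(exp(ll) * wtot))
}

test_that("stabilized grid marginal agrees with naive summation when finite", {
  set.seed(51)
  # 2-point grid, brute force
  ll <- c(-3.2, -4.7)
  g2 <- list(k = c(1, 3))
  expect_lt(abs(log_marginal_from_grid(ll, g2) - naive_marginal(ll, g2)), 1e-10)
  # larger factorial grids, mixed linear and log spacing
  for (i in 1:5) {
    g <- list(a = exp(seq(0, 4, length.out = 3)),
              b = seq(0.3, 0.7, length.out = 4),
              c = c(1, 10))
    ll <- rnorm(24, -30, 5)
    expect_lt(abs(log_marginal_from_grid(ll, g) - naive_marginal(ll, g)), 1e-10)
  }
  # far below underflow the stabilized path still returns finite values
  ll <- rnorm(8, -5000, 1)
  expect_true(is.finite(log_marginal_from_grid(ll, list(a = 1:8))))
  expect_identical(naive_marginal(ll, list(a = 1:8)), -Inf)  # naive underflows
  expect_error(log_marginal_from_grid(numeric(0), list(a = 1)), "empty")
  expect_error(log_marginal_from_grid(1:3, list(a = c(2, 3))), "prod")
  expect_error(log_marginal_from_grid(1:2, list(a = c(3, 2))), "increasing")
})

test_that("a constant likelihood surface returns the constant exactly", {
  const <- -123.456
  g <- list(a = exp(seq(log(1), log(100), length.out = 8)),
            b = seq(0.3, 0.7, length.out = 8),
            c = seq(1, 30, length.out = 8))
  lm <- log_marginal_from_grid(rep(const, 512), g)
  # trapezoid cell widths tile each range exactly: uniform prior -> 1
  expect_equal(lm, const, tolerance = 1e-12)
  # single point: point evaluation
  expect_identical(log_marginal_from_grid(const, list(a = 5)), const)
})

test_that("marginal likelihood is invariant to trial order and grid order", {
  tr <- simulate_responses(generate_trials(400, seed = 52), "EEO",
                           default_params("EEO"), seed = 1)
  g <- default_grid("EEO", 3)
  a <- log_marginal_likelihood(tr, "EEO", grid = g, n_samples = 200, seed = 2)
  b <- log_marginal_likelihood(tr[sample(nrow(tr)), ], "EEO", grid = g,
                               n_samples = 200, seed = 2)
  expect_identical(as.numeric(a), as.numeric(b))
  # swapping equally weighted evaluations leaves the log-sum-exp unchanged
  set.seed(53)
  ll <- rnorm(2, -40, 3)
  expect_equal(log_marginal_from_grid(ll, list(a = c(1, 5))),
               log_marginal_from_grid(rev(ll), list(a = c(1, 5))))
})

test_that("comparison ranks the generating model first in an easy pair", {
  tr <- simulate_responses(generate_trials(800, seed = 54), "VVO",
                           default_params("VVO"), seed = 3)
  cmp <- compare_observers(tr, c("VVO", "EEO"), n_points = 4,
                           n_samples = 300, seed = 4)
  expect_s3_class(cmp, "observer_comparison")
  expect_identical(cmp$winner, "VVO")
  tab <- cmp$table
  # differences against the reference are antisymmetric by construction
  expect_equal(sum(tab$delta_vs_ref == 0), 1L)
  expect_identical(tab$model[which.max(tab$log_marginal)], "VVO")
  expect_error(compare_observers(tr, "VVO"), "at least two")
  expect_error(compare_observers(tr, c("VVO", "VVO")), "duplicate")
})

test_that("an idle noise parameter cannot buy marginal likelihood", {
  # data from noiseless EEO with the truth on the grid, so the extra sigma
  # is genuinely idle (its best value is 0) and the Occam factor can only
  # hurt, up to Monte-Carlo noise.  (With the truth off-grid, decision
  # noise acts as a lapse parameter and can legitimately help.)
  tr <- simulate_responses(generate_trials(1200, seed = 55), "EEO",
                           default_params("EEO"), seed = 5)
  g_eeo <- list(J_low = c(3, 6, 12, 24), J_high = c(15, 30, 60),
                p_change = c(0.4, 0.5, 0.6))
  g_noise <- c(g_eeo, list(sigma_global = c(0, 0.5, 1, 2)))
  lm_eeo <- log_marginal_likelihood(tr, "EEO", grid = g_eeo,
                                    n_samples = 300, seed = 6)
  lm_noise <- log_marginal_likelihood(tr, "EEO+global",
                                      grid = g_noise[observer_model("EEO+global")$params],
                                      n_samples = 300, seed = 6)
  expect_lt(as.numeric(lm_noise), as.numeric(lm_eeo) + 1)
})

test_that("variable precision nests equal precision as tau -> 0", {
  tr <- simulate_responses(generate_trials(1000, seed = 56), "EEO",
                           c(J_low = 6, J_high = 30, p_change = 0.5), seed = 7)
  f_eeo <- fit_observer(tr, "EEO",
                        grid = list(J_low = c(3, 6, 12), J_high = c(15, 30, 60),
                                    p_change = c(0.4, 0.5, 0.6)),
                        n_samples = 400, seed = 8)
  f_veo <- fit_observer(tr, "VEO",
                        grid = list(Jbar_low = c(3, 6, 12), Jbar_high = c(15, 30, 60),
                                    tau = c(0.05, 10), p_change = c(0.4, 0.5, 0.6)),
                        n_samples = 400, seed = 8)
  expect_lt(abs(f_veo$logLik_max - f_eeo$logLik_max), 10)
  expect_equal(unname(coef(f_veo)[["tau"]]), 0.05)  # the near-EP corner wins
})

test_that("run metadata records grids, seed and the tau prior range", {
  tr <- simulate_responses(generate_trials(300, seed = 57), "EEM",
                           default_params("EEM"), seed = 9)
  cmp <- compare_observers(tr, c("EEM", "ESM"), n_points = 3,
                           n_samples = 150, seed = 10)
  f <- tempfile(fileext = ".json")
  write_run_metadata(cmp, f)
  meta <- jsonlite::fromJSON(f)
  expect_equal(meta$tau_prior_range, c(1, 30))
  expect_equal(meta$seed, 10)
  expect_equal(meta$n_samples, 150)
  expect_setequal(meta$models, c("EEM", "ESM"))
})
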