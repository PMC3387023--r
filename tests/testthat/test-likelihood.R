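test_that("trial-type grid and classifier follow the binning conventions", {
  types <- trial_types()
  expect_identical(nrow(types), 310L)
  expect_identical(length(unique(types$type)), 310L)
  expect_setequal(unique(types$delta_bin), seq(0, 90, 3))

  tr <- generate_trials(6, seed = 41)
  # force known configurations
  tr$change <- c(0L, 1L, 1L, 0L, 1L, 1L)
  tr$change_location <- c(NA, 2L, 3L, NA, 1L, 4L)
  tr[paste0("rel_", 1:4)] <- list(c("L", "H", "H", "L", "H", "H"),
                                  c("L", "H", "H", "L", "H", "H"),
                                  c("H", "H", "L", "L", "H", "H"),
                                  c("L", "H", "L", "L", "H", "H"))
  tr$delta <- c(0, 44, -80.2, 0, 1.2, 89.6)
  idx <- classify_trials(tr)
  got <- trial_types()[idx, ]
  # no-change: bin 0, low by convention
  expect_identical(got$delta_bin[1], 0)
  expect_identical(got$changed_rel[1], "L")
  # |44| -> bin 45, changed item high, n_high counted from flags
  expect_identical(got$delta_bin[2], 45)
  expect_identical(got$changed_rel[2], "H")
  expect_identical(got$n_high[2], 4L)
  # |-80.2| -> 81, change at a low item
  expect_identical(got$delta_bin[3], 81)
  expect_identical(got$changed_rel[3], "L")
  # tiny change rounds into bin 0 but keeps its reliability
  expect_identical(got$delta_bin[5], 0)
  expect_identical(got$changed_rel[5], "H")
  expect_identical(got$delta_bin[6], 90)
  # nearest-multiple rule on random magnitudes
  tr2 <- generate_trials(500, seed = 42)
  bins <- trial_types()$delta_bin[classify_trials(tr2)]
  expect_equal(bins, 3 * round(abs(tr2$delta) / 3))
})

test_that("prediction tables behave at informative limits and are reproducible", {
  pt <- predict_table("EEO", c(J_low = 5e4, J_high = 5e4, p_change = 0.5),
                      n_samples = 300, seed = 2)
  eps <- 1 / 600
  big <- pt$delta_bin == 90 & !is.na(pt$p_change_report)
  expect_true(all(pt$p_change_report[big] == 1 - eps))
  # false alarms are rare but not impossible even at huge precision (the
  # evidence distribution is heavy-tailed), so bin-0 cells sit near the floor
  fa <- pt$delta_bin == 0 & !is.na(pt$p_change_report)
  expect_true(all(pt$p_change_report[fa] < 0.02))
  expect_true(any(pt$p_change_report[fa] == eps))
  expect_true(all(pt$p_change_report >= eps & pt$p_change_report <= 1 - eps,
                  na.rm = TRUE))
  # design-unreachable cells are flagged, not faked
  expect_true(all(is.na(pt$p_change_report[pt$delta_bin > 0 & pt$n_high == 0 &
                                           pt$changed_rel == "H"])))
  expect_identical(pt, predict_table("EEO",
                                     c(J_low = 5e4, J_high = 5e4, p_change = 0.5),
                                     n_samples = 300, seed = 2))
})

test_that("predicted detection improves with change magnitude (VVO)", {
  pt <- predict_table("VVO", default_params("VVO"), n_samples = 500, seed = 3)
  for (h in c(1L, 3L)) {
    p <- pt$p_change_report[pt$n_high == h & pt$changed_rel == "H"]
    p <- p[order(pt$delta_bin[pt$n_high == h & pt$changed_rel == "H"])]
    # non-decreasing within Monte-Carlo error
    expect_true(all(diff(cummax(p)) >= 0))
    expect_true(all(cummax(p) - p < 3 * sqrt(0.25 / 500)))
    expect_gt(p[31], p[1])
  }
})

test_that("log likelihood is additive and matches its prediction table", {
  tr <- simulate_responses(generate_trials(300, seed = 43), "EEO",
                           c(J_low = 5, J_high = 25, p_change = 0.5), seed = 4)
  pars <- c(J_low = 5, J_high = 25, p_change = 0.5)
  ll <- log_likelihood(tr, "EEO", pars, n_samples = 300, seed = 5)
  pt <- predict_table("EEO", pars, n_samples = 300, seed = 5)
  idx <- classify_trials(tr)
  manual <- sum(log(ifelse(tr$response == 1,
                           pt$p_change_report[idx],
                           1 - pt$p_change_report[idx])))
  expect_equal(ll, manual)
  expect_true(is.finite(ll))
  # duplicating every trial doubles the log likelihood
  expect_equal(log_likelihood(rbind(tr, tr), "EEO", pars,
                              n_samples = 300, seed = 5), 2 * ll)
  tr$response[1] <- NA
  expect_error(log_likelihood(tr, "EEO", pars), "responses")
})

test_that("the true parameters beat distant ones on model-generated data", {
  truth <- c(J_low = 5, J_high = 25, p_change = 0.5)
  tr <- simulate_responses(generate_trials(5000, seed = 44), "EEO", truth,
                           seed = 6)
  ll_true <- log_likelihood(tr, "EEO", truth, n_samples = 500, seed = 7)
  ll_far <- log_likelihood(tr, "EEO",
                           c(J_low = 60, J_high = 90, p_change = 0.65),
                           n_samples = 500, seed = 7)
  expect_gt(ll_true, ll_far)
})

test_that("a one-point grid fit returns that point", {
  tr <- simulate_responses(generate_trials(200, seed = 45), "EEM",
                           default_params("EEM"), seed = 8)
  g <- list(J_low = 6, J_high = 30, k = 3)
  f <- fit_observer(tr, "EEM", grid = g, n_samples = 200, seed = 9)
  expect_equal(coef(f), c(J_low = 6, J_high = 30, k = 3))
  expect_equal(f$log_marginal, f$logLik_max)  # degenerate grid
  expect_error(fit_observer(tr, "EEM", grid = list(J_low = 6, J_high = 30)),
               "lacks")
})
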