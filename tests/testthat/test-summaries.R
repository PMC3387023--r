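test_that("summary rates are proportions with the design's undefined cells", {
  tr <- generate_trials(3000, seed = 61)
  tr$response <- 1L                      # an observer that always says change
  s <- summarize_trials(tr)
  expect_true(all(s$rates$fa_rate == 1, na.rm = TRUE))
  expect_true(all(s$rates$hit_rate == 1, na.rm = TRUE))
  # cells the design cannot fill are NA, never 0
  expect_true(is.na(s$rates$hit_high[s$rates$n_high == 0]))
  expect_true(is.na(s$rates$hit_low[s$rates$n_high == 4]))
  tr$response[1] <- NA
  expect_error(summarize_trials(tr), "responses")
})

test_that("the unconditioned hit rate is the count-weighted mixture of the conditioned ones", {
  tr <- simulate_responses(generate_trials(8000, seed = 62), "VEM",
                           default_params("VEM"), seed = 1)
  r <- summarize_trials(tr)$rates
  for (i in 2:4) {      # rows with both conditioned rates defined
    w <- r$n_change_low[i] / r$n_change[i]
    expect_equal(r$hit_rate[i],
                 w * r$hit_low[i] + (1 - w) * r$hit_high[i],
                 tolerance = 1e-12)
  }
})

test_that("r_squared has its textbook fixed points", {
  tr <- simulate_responses(generate_trials(4000, seed = 63), "EEO",
                           default_params("EEO"), seed = 2)
  s <- summarize_trials(tr)
  expect_equal(r_squared(s, s, "rates"), 1)
  expect_equal(r_squared(s, s, "psychometric"), 1)
  # predicting the observed mean everywhere gives exactly 0
  m <- s
  v <- c(s$rates$fa_rate, s$rates$hit_rate)
  m$rates$fa_rate[] <- mean(v)
  m$rates$hit_rate[] <- mean(v)
  expect_equal(r_squared(s, m, "rates"), 0)
  # reflected predictions are worse than the mean
  a <- s
  a$rates$fa_rate <- 2 * mean(v) - s$rates$fa_rate
  a$rates$hit_rate <- 2 * mean(v) - s$rates$hit_rate
  expect_lt(r_squared(s, a, "rates"), 0)
})

test_that("model summaries agree with large simulations from the same model", {
  pars <- default_params("EEO")
  pred <- model_summary("EEO", pars, n_samples = 3000, seed = 3)
  tr <- simulate_responses(generate_trials(4e4, seed = 64), "EEO", pars,
                           seed = 4)
  obs <- summarize_trials(tr)
  expect_lt(max(abs(pred$rates$fa_rate - obs$rates$fa_rate)), 0.03)
  expect_lt(max(abs(pred$rates$hit_rate - obs$rates$hit_rate)), 0.03)
  expect_gt(r_squared(obs, pred, "rates"), 0.97)
  expect_gt(r_squared(obs, pred, "psychometric"), 0.9)
})

test_that("equal low/high precision removes the reliability split", {
  pred <- model_summary("EEO", c(J_low = 12, J_high = 12, p_change = 0.5),
                        n_samples = 2000, seed = 5)
  ok <- !is.na(pred$rates$hit_low) & !is.na(pred$rates$hit_high)
  expect_equal(pred$rates$hit_low[ok], pred$rates$hit_high[ok],
               tolerance = 0.05)
  # false alarms cannot depend on change magnitude by construction
  expect_identical(length(pred$rates$fa_rate), 5L)
})

test_that("precision-weighting observers show the Z-shaped Simpson's pattern", {
  tr <- simulate_responses(generate_trials(3e4, seed = 65), "VVO",
                           default_params("VVO"), seed = 6)
  r <- summarize_trials(tr)$rates
  tol <- 0.03
  expect_true(all(diff(r$hit_rate) > -tol))          # unconditioned rises
  expect_true(all(diff(r$hit_low[1:4]) < tol))       # low-conditioned falls
})
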