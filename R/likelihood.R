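#' The trial-type grid
#'
#' Model predictions are computed per trial type rather than per trial: the
#' probability of reporting "change" depends only on the magnitude of change
#' (binned every 3 degrees from 0 to 90, i.e. 31 bins), the number of
#' high-reliability items (0..4), and whether the changed item had low or
#' high reliability — 31 x 5 x 2 = 310 types.  No-change trials fall in the
#' `delta_bin = 0`, `changed_rel = "L"` cell by convention; all
#' `delta_bin = 0` cells are simulated as genuine no-change trials (a
#' zero-magnitude change is indistinguishable from no change).  Cells that
#' the design cannot produce (e.g. a high-reliability change with
#' `n_high = 0`) are retained in the grid for completeness and get `NA`
#' predictions.
#'
#' @return `trial_types()`: data frame of 310 rows with `type` (index),
#'   `delta_bin` (0, 3, ..., 90 degrees), `n_high`, `changed_rel`.
#' @examples
#' nrow(trial_types())
#' @export
trial_types <- function() {
  g <- expand.grid(changed_rel = c("L", "H"), n_high = 0:4,
                   delta_bin = seq(0, 90, by = 3),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[c("delta_bin", "n_high", "changed_rel")]
  g$type <- seq_len(nrow(g))
  g[c("type", "delta_bin", "n_high", "changed_rel")]
}

# types the experimental design cannot generate
.unreachable_types <- function(types = trial_types()) {
  types$delta_bin > 0 &
    ((types$n_high == 0 & types$changed_rel == "H") |
     (types$n_high == 4 & types$changed_rel == "L"))
}

#' Classify trials into trial types
#'
#' Assigns each trial its type index in [trial_types()]: the magnitude of
#' change is rounded to the nearest multiple of 3 degrees; `n_high` counts
#' the high-reliability items; `changed_rel` is the reliability of the
#' changed item (`"L"` by convention on no-change trials).
#'
#' @param trials a trial table.
#' @return integer vector of type indices (1..310).
#' @examples
#' tr <- generate_trials(10, seed = 1)
#' classify_trials(tr)
#' @export
classify_trials <- function(trials) {
  m <- .trial_mats(trials)
  nh <- rowSums(m$rel == "H")
  bin <- 3 * round(pmin(abs(trials$delta), 90) / 3)
  crel <- rep("L", nrow(trials))
  ch <- which(trials$change == 1)
  if (length(ch)) {
    crel[ch] <- m$rel[cbind(ch, trials$change_location[ch])]
  }
  crel[trials$change == 0] <- "L"
  types <- trial_types()
  idx <- match(paste(bin, nh, crel),
               paste(types$delta_bin, types$n_high, types$changed_rel))
  if (any(is.na(idx))) stop("trial could not be classified (invalid delta or reliabilities)")
  idx
}

# 310 x 1 count matrices of "change"/"no change" responses per type
.count_tables <- function(trials) {
  if (any(is.na(trials$response))) {
    stop("all trials must have responses")
  }
  idx <- classify_trials(trials)
  n1 <- tabulate(idx[trials$response == 1], nbins = 310)
  n0 <- tabulate(idx[trials$response == 0], nbins = 310)
  list(n1 = matrix(n1, ncol = 1), n0 = matrix(n0, ncol = 1))
}

#' Monte-Carlo prediction table for a model
#'
#' For each of the 310 trial types, simulates `n_samples` percepts at the
#' type's nominal change magnitude and reliability configuration (nuisance
#' details — which locations are high-reliability, the change location —
#' are redrawn uniformly per sample), applies the model's decision process,
#' and records the fraction of "change" reports.  Probabilities are clipped
#' to `[eps, 1 - eps]` with `eps = 1/(2 n_samples)` so that downstream log
#' likelihoods stay finite.  With a fixed seed the table is a deterministic
#' function of the parameters.
#'
#' @inheritParams simulate_responses
#' @param n_samples Monte-Carlo samples per type (default 1000).
#' @param seed integer seed for the simulation (default 1).
#' @return the [trial_types()] data frame with columns `p_change_report`
#'   (`NA` for design-unreachable types) and `n_samples`.
#' @examples
#' pt <- predict_table("EEO", default_params("EEO"), n_samples = 200)
#' head(pt)
#' @export
predict_table <- function(model, params, n_samples = 1000, seed = 1) {
  spec <- as_observer_spec(model)
  params <- .check_params(spec, params)
  grids <- lapply(params, function(v) v)
  ev <- .evaluate_models(matrix(0, 310, 1), matrix(0, 310, 1),
                         list(spec), list(grids),
                         n_samples = n_samples, seed = seed,
                         keep_p = TRUE)[[spec$code]]
  types <- trial_types()
  p <- ev$p[, 1]
  p[.unreachable_types(types)] <- NA_real_
  types$p_change_report <- p
  types$n_samples <- n_samples
  types
}

#' Log likelihood of a parameter vector
#'
#' The dataset log likelihood under a model: responses are Bernoulli with
#' the model's per-type probability of reporting "change"
#' ([predict_table()]), so
#' \deqn{\log L = \sum_k \log p(r_k \mid \mathrm{type}_k).}
#' With common `seed` and `n_samples` this is a deterministic function of
#' the parameters, which keeps grid searches stable.
#'
#' @inheritParams predict_table
#' @param trials a trial table with all responses present.
#' @return the log likelihood (scalar).
#' @examples
#' tr <- simulate_responses(generate_trials(200, seed = 1), "EEO",
#'                          default_params("EEO"), seed = 2)
#' log_likelihood(tr, "EEO", default_params("EEO"), n_samples = 200)
#' @export
log_likelihood <- function(trials, model, params, n_samples = 1000, seed = 1) {
  cc <- .count_tables(trials)
  pt <- predict_table(model, params, n_samples = n_samples, seed = seed)
  p <- pt$p_change_report
  reached <- !is.na(p)
  if (any((cc$n1 + cc$n0)[!reached] > 0)) {
    stop("trials fall in design-unreachable types")
  }
  sum(cc$n1[reached] * log(p[reached])) +
    sum(cc$n0[reached] * log1p(-p[reached]))
}
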