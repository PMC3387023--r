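#' Fit an observer model to trial data
#'
#' Grid maximum-likelihood estimation: the dataset log likelihood
#' ([log_likelihood()]) is evaluated at every point of a parameter grid with
#' common random numbers (the Monte-Carlo percepts are re-seeded identically
#' at every grid point, which makes the likelihood surface a deterministic
#' function of the parameters) and the arg-max is returned, together with
#' the grid marginal likelihood used by Bayesian model comparison.  Ties
#' take the first point in grid order.
#'
#' @param trials a trial table with responses (see [generate_trials()],
#'   [simulate_responses()], [read_trials()]).
#' @param model a model code (see [observer_models()]) or an
#'   `"observer_spec"`.
#' @param grid named list of grid vectors, one per free parameter of the
#'   model; defaults to [default_grid()].  Grids must lie inside the prior
#'   ranges ([param_ranges()]).
#' @param n_samples Monte-Carlo samples per trial type per grid point.
#' @param seed integer seed controlling the Monte-Carlo draws.
#' @return an object of class `"observer_fit"` with components
#'   `coefficients` (the MLE), `logLik_max`, `log_marginal`, `model`,
#'   `grid`, `counts`, `n_trials`, `n_samples`, `seed`.  Methods:
#'   `print`, `summary`, `coef`, `logLik`, `predict`, `simulate`,
#'   `residuals`, `plot`.
#' @examples
#' tr <- simulate_responses(generate_trials(400, seed = 1), "EEO",
#'                          default_params("EEO"), seed = 2)
#' f <- fit_observer(tr, "EEO", grid = default_grid("EEO", 5),
#'                   n_samples = 200)
#' coef(f)
#' @export
fit_observer <- function(trials, model, grid = NULL, n_samples = 1000,
                         seed = 1) {
  spec <- as_observer_spec(model)
  grid <- grid %||% default_grid(spec)
  missing <- setdiff(spec$params, names(grid))
  if (length(missing)) {
    stop("grid lacks parameter(s): ", paste(missing, collapse = ", "))
  }
  grid <- grid[spec$params]
  if (any(vapply(grid, length, 0L) < 1)) stop("empty grid")
  cc <- .count_tables(trials)
  ev <- .evaluate_models(cc$n1, cc$n0, list(spec), list(grid),
                         n_samples = n_samples, seed = seed)[[spec$code]]
  ll <- ev$logL[, 1]
  best <- which.max(ll)
  coefs <- unlist(ev$params[best, , drop = TRUE])
  # surface (not silently extend) a criterion pinned at its search boundary
  if ("k" %in% names(coefs) && length(grid$k) > 1 &&
      (coefs[["k"]] == min(grid$k) || coefs[["k"]] == max(grid$k))) {
    warning("Max-rule criterion k estimated at its grid boundary (",
            format(coefs[["k"]]), "); consider the prior range")
  }
  structure(list(
    coefficients = coefs,
    logLik_max = ll[best],
    log_marginal = log_marginal_from_grid(ll, ev$grid_storage),
    model = spec,
    grid = grid,
    counts = cc,
    n_trials = nrow(trials),
    n_samples = n_samples,
    seed = seed,
    call = match.call()
  ), class = "observer_fit")
}

#' @export
print.observer_fit <- function(x, digits = 4, ...) {
  cat("Observer model fit:", x$model$code, "\n")
  cat("  n trials:", x$n_trials, " MC samples/type:", x$n_samples, "\n")
  cat("  maximum-likelihood estimates (grid):\n")
  print(round(x$coefficients, digits))
  cat("  log likelihood:", format(x$logLik_max, digits = digits + 2),
      "  log marginal likelihood:", format(x$log_marginal, digits = digits + 2),
      "\n")
  invisible(x)
}

#' @export
summary.observer_fit <- function(object, ...) {
  gp <- vapply(object$grid, length, 0L)
  cat("Observer model fit:", object$model$code, "\n\n")
  print(object$model)
  cat("\nGrid points per parameter:\n")
  print(gp)
  cat("\nMLE:\n")
  print(object$coefficients)
  cat("\nlog likelihood:", object$logLik_max,
      "\nlog marginal likelihood:", object$log_marginal, "\n")
  cat("seed:", object$seed, " n_samples:", object$n_samples, "\n")
  invisible(object)
}

#' @export
coef.observer_fit <- function(object, ...) object$coefficients

#' @export
logLik.observer_fit <- function(object, ...) {
  structure(object$logLik_max, df = length(object$coefficients),
            nobs = object$n_trials, class = "logLik")
}

#' @export
predict.observer_fit <- function(object, n_samples = NULL, seed = NULL, ...) {
  predict_table(object$model, object$coefficients,
                n_samples = n_samples %||% object$n_samples,
                seed = seed %||% object$seed)
}

#' @export
simulate.observer_fit <- function(object, nsim = 1, seed = NULL,
                                  n_trials = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n_trials <- n_trials %||% object$n_trials
  out <- lapply(seq_len(nsim), function(i) {
    simulate_responses(generate_trials(n_trials), object$model,
                       object$coefficients)
  })
  if (nsim == 1) out[[1]] else out
}

#' @export
residuals.observer_fit <- function(object, ...) {
  pt <- predict.observer_fit(object)
  tot <- object$counts$n1 + object$counts$n0
  obs <- ifelse(tot > 0, object$counts$n1 / tot, NA_real_)
  drop(obs) - pt$p_change_report
}

#' @export
plot.observer_fit <- function(x, n_samples = 2000, ...) {
  obs <- .summary_from_counts(x$counts)
  prd <- model_summary(x$model, x$coefficients, n_samples = n_samples,
                       seed = x$seed)
  .plot_rates(obs, prd, main = paste("Model", x$model$code))
  invisible(x)
}
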