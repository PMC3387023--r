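#' Grid marginal likelihood from tabulated log likelihoods
#'
#' Log of the Riemann-sum approximation to the parameter-averaged
#' likelihood under independent uniform priors.  `logL` is evaluated on the
#' full factorial grid of the vectors in `grid` (first parameter varying
#' fastest, as [expand.grid()] does).  Each point is weighted by its
#' Riemann cell width (half the distance between its neighbours; one-sided
#' at the ends) divided by the parameter's range, so the uniform prior
#' integrates to exactly 1 over the grid span for any monotone spacing:
#' \deqn{\log L(m) = \mathrm{logsumexp}\big(\log L + \textstyle\sum_j
#'   \log(w_j / R_j)\big).}
#' The log-sum-exp is stabilized by shifting by the maximum of its
#' argument, which keeps the summed exponentials of order 1 near the
#' maximum-likelihood point.  A parameter with a single grid point is
#' treated as fixed (no weight); a constant likelihood surface returns the
#' constant exactly.
#'
#' @param log_lik numeric vector of log likelihoods over the grid.
#' @param grid named list of strictly increasing grid vectors (a single
#'   numeric vector is taken as a one-parameter grid).
#' @return the log marginal likelihood (scalar).
#' @examples
#' log_marginal_from_grid(c(-100, -101), list(k = c(1, 2)))
#' @export
log_marginal_from_grid <- function(log_lik, grid) {
  if (is.numeric(grid)) grid <- list(grid)
  if (!length(log_lik)) stop("empty grid")
  nper <- vapply(grid, length, 0L)
  if (prod(nper) != length(log_lik)) {
    stop("length(log_lik) must equal prod(lengths(grid))")
  }
  logw <- lapply(grid, function(x) {
    n <- length(x)
    if (n == 1) return(0)
    if (any(diff(x) <= 0)) stop("grid vectors must be strictly increasing")
    w <- c(diff(x), 0) / 2 + c(0, diff(x)) / 2   # trapezoid cell widths
    log(w) - log(x[n] - x[1])
  })
  lw <- 0
  rep_each <- 1L
  for (d in seq_along(grid)) {
    lw <- lw + rep_len(rep(logw[[d]], each = rep_each), length(log_lik))
    rep_each <- rep_each * nper[d]
  }
  ll <- log_lik + lw
  mx <- max(ll)
  mx + log(sum(exp(ll - mx)))
}

#' Log marginal likelihood of an observer model
#'
#' Evaluates the dataset log likelihood over the model's full parameter
#' grid (common random numbers across points) and integrates it against the
#' uniform priors by [log_marginal_from_grid()].
#'
#' @inheritParams fit_observer
#' @return scalar log marginal likelihood, with attributes `mle` (the grid
#'   MLE) and `logLik_max`.
#' @export
log_marginal_likelihood <- function(trials, model, grid = NULL,
                                    n_samples = 500, seed = 1) {
  fit <- fit_observer(trials, model, grid = grid, n_samples = n_samples,
                      seed = seed)
  structure(fit$log_marginal, mle = fit$coefficients,
            logLik_max = fit$logLik_max)
}

#' Bayesian comparison of observer models
#'
#' Computes each model's log marginal likelihood on the same dataset
#' (uniform priors over the grid ranges, Riemann sum, log-sum-exp
#' stabilization) and ranks the models.  Models sharing an encoding stage
#' are evaluated on shared percept simulations, so their Monte-Carlo noise
#' largely cancels in the comparison.
#'
#' @inheritParams fit_observer
#' @param models character vector of model codes (default: all 14).
#' @param grids optional list of grids, one per model (default:
#'   [default_grid()] with `n_points` points per dimension).
#' @param n_points grid points per dimension for the default grids.
#' @param reference model code differences are reported against (default
#'   `"VVO"` when present, else the winner).
#' @return an object of class `"observer_comparison"`: a list with `table`
#'   (model, number of parameters, log marginal likelihood, difference vs
#'   the reference, max log likelihood), `winner`, `reference`, `mle`
#'   (per-model grid MLEs) and run metadata.
#' @examples
#' \donttest{
#' tr <- simulate_responses(generate_trials(500, seed = 1), "VVO",
#'                          default_params("VVO"), seed = 2)
#' cmp <- compare_observers(tr, c("VVO", "EEO"), n_points = 4,
#'                          n_samples = 200)
#' cmp$winner
#' }
#' @export
compare_observers <- function(trials, models = observer_codes(), grids = NULL,
                              n_points = 8, n_samples = 500, seed = 1,
                              reference = NULL) {
  if (length(models) < 2) stop("need at least two models to compare")
  specs <- lapply(models, as_observer_spec)
  codes <- vapply(specs, `[[`, "", "code")
  if (anyDuplicated(codes)) stop("duplicate model codes")
  grids <- grids %||% lapply(specs, default_grid, n_points = n_points)
  cc <- .count_tables(trials)
  ev <- .evaluate_models(cc$n1, cc$n0, specs, grids,
                         n_samples = n_samples, seed = seed)
  logml <- vapply(codes, function(cd) {
    log_marginal_from_grid(ev[[cd]]$logL[, 1], ev[[cd]]$grid_storage)
  }, numeric(1))
  mle <- lapply(codes, function(cd) {
    best <- which.max(ev[[cd]]$logL[, 1])
    unlist(ev[[cd]]$params[best, , drop = TRUE])
  })
  names(mle) <- codes
  maxll <- vapply(codes, function(cd) max(ev[[cd]]$logL[, 1]), numeric(1))
  winner <- codes[which.max(logml)]
  reference <- reference %||% (if ("VVO" %in% codes) "VVO" else winner)
  if (!reference %in% codes) stop("reference model not among 'models'")
  tab <- data.frame(
    model = codes,
    n_params = vapply(specs, function(s) length(s$params), 0L),
    log_marginal = logml,
    delta_vs_ref = logml - logml[[reference]],
    max_log_lik = maxll,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(list(
    table = tab[order(-tab$log_marginal), ],
    winner = winner,
    reference = reference,
    mle = mle,
    metadata = .run_metadata(models = codes, grids = grids,
                             n_samples = n_samples, seed = seed,
                             n_trials = nrow(trials))
  ), class = "observer_comparison")
}

#' @export
print.observer_comparison <- function(x, digits = 2, ...) {
  cat("Bayesian observer-model comparison (", nrow(x$table), " models, ",
      x$metadata$n_trials, " trials)\n", sep = "")
  tab <- x$table
  tab$log_marginal <- round(tab$log_marginal, digits)
  tab$delta_vs_ref <- round(tab$delta_vs_ref, digits)
  tab$max_log_lik <- round(tab$max_log_lik, digits)
  print(tab, row.names = FALSE)
  cat("winner:", x$winner, "  (differences vs ", x$reference, ")\n", sep = "")
  invisible(x)
}

#' @export
plot.observer_comparison <- function(x, ...) {
  tab <- x$table[order(x$table$delta_vs_ref), ]
  op <- par(mar = c(4, 5, 2, 1))
  on.exit(par(op))
  barplot(tab$delta_vs_ref, names.arg = tab$model, horiz = TRUE, las = 1,
          xlab = paste("log marginal likelihood vs", x$reference),
          col = ifelse(tab$model == x$winner, "steelblue", "grey70"), ...)
  abline(v = 0, lty = 2)
  invisible(x)
}

#' Model-recovery harness
#'
#' The validation the fitting machinery must pass before being trusted on
#' real data: simulate a synthetic experiment from each model at
#' representative generating parameters, run the full Bayesian model
#' comparison on every dataset, and tabulate which model wins.  With
#' adequate trial counts the winners should lie on the diagonal.
#'
#' @param models character vector of generating (and candidate) model codes.
#' @param params list of named generating parameter vectors, one per model
#'   (default [default_params()]).
#' @param n_trials trials per synthetic dataset.
#' @param n_points,n_samples,seed,grids passed to the comparison stage.
#' @return an object of class `"recovery_matrix"`: a list with
#'   `log_marginal` (generating model x candidate model), `winner` (per
#'   generating model), `diagonal` (logical), `n_correct`.
#' @examples
#' \donttest{
#' rec <- recovery_harness(c("VVO", "EEO"), n_trials = 400, n_points = 4,
#'                         n_samples = 200, seed = 1)
#' rec$winner
#' }
#' @export
recovery_harness <- function(models = observer_codes(), params = NULL,
                             n_trials = 2000, n_points = 8, n_samples = 500,
                             seed = 1, grids = NULL) {
  specs <- lapply(models, as_observer_spec)
  codes <- vapply(specs, `[[`, "", "code")
  params <- params %||% lapply(codes, default_params)
  if (length(params) != length(codes)) {
    stop("need one generating parameter vector per model")
  }
  grids <- grids %||% lapply(specs, default_grid, n_points = n_points)

  D <- length(codes)
  N1 <- matrix(0, 310, D)
  N0 <- matrix(0, 310, D)
  for (i in seq_len(D)) {
    tr <- generate_trials(n_trials, seed = seed + i)
    tr <- simulate_responses(tr, specs[[i]], params[[i]],
                             seed = seed + 1000L + i)
    cc <- .count_tables(tr)
    N1[, i] <- cc$n1
    N0[, i] <- cc$n0
  }
  ev <- .evaluate_models(N1, N0, specs, grids,
                         n_samples = n_samples, seed = seed)
  logml <- matrix(NA_real_, D, D, dimnames = list(generating = codes,
                                                  candidate = codes))
  for (j in seq_len(D)) {
    lm <- apply(ev[[codes[j]]]$logL, 2, log_marginal_from_grid,
                grid = ev[[codes[j]]]$grid_storage)
    logml[, j] <- lm
  }
  winner <- codes[apply(logml, 1, which.max)]
  structure(list(
    log_marginal = logml,
    winner = setNames(winner, codes),
    diagonal = winner == codes,
    n_correct = sum(winner == codes),
    metadata = .run_metadata(models = codes, grids = grids,
                             n_samples = n_samples, seed = seed,
                             n_trials = n_trials)
  ), class = "recovery_matrix")
}

#' @export
print.recovery_matrix <- function(x, ...) {
  n <- length(x$winner)
  cat("Model recovery: ", x$n_correct, "/", n,
      " generating models recovered\n", sep = "")
  print(data.frame(generating = names(x$winner), winner = unname(x$winner),
                   recovered = x$diagonal), row.names = FALSE)
  invisible(x)
}

# run metadata carried on results and writable as JSON
.run_metadata <- function(...) {
  info <- list(...)
  info$tau_prior_range <- .param_ranges$tau
  info$package_version <- as.character(utils::packageVersion("changedet"))
  info$r_version <- R.version.string
  info
}

#' Write run metadata
#'
#' Serializes the configuration of a comparison or recovery run (models,
#' grids — including the tau prior range actually used — seeds, sample
#' counts, versions) as JSON so the run can be reproduced.
#'
#' @param x an `"observer_comparison"` or `"recovery_matrix"` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(x, path) {
  if (is.null(x$metadata)) stop("object carries no run metadata")
  writeLines(jsonlite::toJSON(x$metadata, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}
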