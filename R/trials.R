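#' Generate a synthetic change-detection experiment
#'
#' Produces trial tables with the statistical structure of the task: four
#' items per display; the number of high-reliability items drawn uniformly
#' from 0..4 and their locations uniformly at random; orientations i.i.d.
#' uniform over the orientation circle; a change on half the trials (one
#' item, uniform location, magnitude drawn as a uniform orientation
#' offset).  Orientations are stored in physical degrees in \[-90, 90);
#' `delta` is the signed change in (-90, 90\], 0 on no-change trials.
#'
#' @param n number of trials (> 0).
#' @param p_change probability of a change trial (default 0.5, the design
#'   value).
#' @param seed optional integer seed (applied via [set.seed()]).
#' @return data frame with columns `trial_id`, `rel_1..rel_4` (`"L"`/`"H"`),
#'   `theta_1..theta_4`, `phi_1..phi_4` (degrees), `change` (0/1),
#'   `change_location` (1-4 or `NA`), `delta` (degrees) and `response`
#'   (`NA` until filled by [simulate_responses()] or an experiment).
#' @examples
#' head(generate_trials(5, seed = 1))
#' @export
generate_trials <- function(n, p_change = 0.5, seed = NULL) {
  if (length(n) != 1 || !is.finite(n) || n < 1) stop("'n' must be a positive count")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  n_items <- 4L
  nh <- sample(0:4, n, replace = TRUE)
  rel <- matrix("L", n, n_items)
  for (i in seq_len(n)) {
    if (nh[i] > 0) rel[i, sample.int(n_items, nh[i])] <- "H"
  }
  theta <- matrix(runif(n * n_items, -90, 90), n, n_items)
  change <- as.integer(runif(n) < p_change)
  loc <- ifelse(change == 1, sample.int(n_items, n, replace = TRUE), NA_integer_)
  offs <- runif(n, -90, 90)
  delta <- ifelse(change == 1, offs, 0)
  phi <- theta
  ch <- which(change == 1)
  if (length(ch)) {
    idx <- cbind(ch, loc[ch])
    phi[idx] <- internal_to_deg(deg_to_internal(theta[idx] + delta[ch]))
  }
  out <- data.frame(trial_id = seq_len(n), stringsAsFactors = FALSE)
  for (i in 1:4) out[[paste0("rel_", i)]] <- rel[, i]
  for (i in 1:4) out[[paste0("theta_", i)]] <- theta[, i]
  for (i in 1:4) out[[paste0("phi_", i)]] <- phi[, i]
  out$change <- change
  out$change_location <- loc
  out$delta <- delta
  out$response <- NA_integer_
  out
}

# extract matrices from a trial table
.trial_mats <- function(trials) {
  need <- c(paste0("rel_", 1:4), paste0("theta_", 1:4), paste0("phi_", 1:4),
            "change", "delta")
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    stop("trial table lacks column(s): ", paste(missing, collapse = ", "))
  }
  list(
    rel = as.matrix(trials[paste0("rel_", 1:4)]),
    theta = as.matrix(trials[paste0("theta_", 1:4)]),
    phi = as.matrix(trials[paste0("phi_", 1:4)])
  )
}

#' Simulate observer responses for a trial table
#'
#' Runs the full decision process of one observer model on each trial:
#' measurements of both displays are drawn through the encoding stage
#' ([sample_measurement()] semantics), the observer's assumed
#' concentrations are formed per the model's assumption, local decision
#' variables are computed, and the model's integration rule (with decision
#' noise, for the noise variants) produces a response.  Trials are
#' independent; a fixed seed reproduces the output exactly.
#'
#' @param trials a trial table from [generate_trials()] or [read_trials()].
#' @param model a model code or `"observer_spec"`.
#' @param params named parameter values for the model (see
#'   [default_params()]).
#' @param seed optional integer seed.
#' @return the trial table with `response` filled in (1 = "change").
#' @examples
#' tr <- generate_trials(20, seed = 1)
#' tr <- simulate_responses(tr, "VVO", default_params("VVO"), seed = 2)
#' table(tr$response)
#' @export
simulate_responses <- function(trials, model, params, seed = NULL) {
  spec <- as_observer_spec(model)
  params <- .check_params(spec, params)
  if (!is.null(seed)) set.seed(seed)
  m <- .trial_mats(trials)
  n <- nrow(trials)
  hi <- m$rel == "H"

  draw_j <- function() {
    if (spec$encoding == "E") {
      ifelse(hi, params[["J_high"]], params[["J_low"]])
    } else {
      jbar <- ifelse(hi, params[["Jbar_high"]], params[["Jbar_low"]])
      matrix(stats::rgamma(length(jbar), shape = jbar / params[["tau"]],
                           scale = params[["tau"]]), n)
    }
  }
  jx <- draw_j()
  jy <- draw_j()
  kx_true <- matrix(.kappa_fast(jx), n)
  ky_true <- matrix(.kappa_fast(jy), n)
  x <- matrix(rvm_vec_cpp(as.vector(deg_to_internal(m$theta)), as.vector(kx_true)), n)
  y <- matrix(rvm_vec_cpp(as.vector(deg_to_internal(m$phi)), as.vector(ky_true)), n)

  ak <- .assumed_kappas_fast(spec, params, jx, jy, hi)
  logd <- matrix(logd_cpp(cos(as.vector(x - y)), as.vector(ak$kx), as.vector(ak$ky)), n)

  report <- .decide(spec, params, logd)
  trials$response <- as.integer(report)
  trials
}

# fast internal version of assumed_kappas working on matrices, using the
# cached inverse-precision interpolant
.assumed_kappas_fast <- function(spec, params, jx, jy, hi) {
  n <- nrow(jx)
  switch(spec$assumption,
    V = list(kx = matrix(.kappa_fast(jx), n), ky = matrix(.kappa_fast(jy), n)),
    E = {
      jm <- if (spec$encoding == "V") c(params[["Jbar_low"]], params[["Jbar_high"]])
            else c(params[["J_low"]], params[["J_high"]])
      kk <- .kappa_fast(jm)
      k <- matrix(ifelse(hi, kk[2], kk[1]), n)
      list(kx = k, ky = k)
    },
    A = list(kx = matrix(.kappa_fast(rowMeans(jx)), n, 4),
             ky = matrix(.kappa_fast(rowMeans(jy)), n, 4)),
    S = {
      ja <- if ("J_assumed" %in% names(params)) params[["J_assumed"]] else .j_single_max
      k <- .kappa_fast(ja)
      list(kx = matrix(k, n, 4), ky = matrix(k, n, 4))
    }
  )
}

# apply the spec's rule (with noise variant) to a matrix of log d
.decide <- function(spec, params, logd) {
  if (spec$noise == "local" && params[["sigma_local"]] > 0) {
    logd <- logd + matrix(rnorm(length(logd), 0, params[["sigma_local"]]),
                          nrow(logd))
  }
  if (spec$rule == "O") {
    lhs <- log(params[["p_change"]] / (1 - params[["p_change"]])) +
      .row_lse(logd) - log(ncol(logd))
    if (spec$noise == "global" && params[["sigma_global"]] > 0) {
      lhs <- lhs + rnorm(length(lhs), 0, params[["sigma_global"]])
    }
    lhs > 0
  } else {
    k <- params[["k"]]
    if (k <= 0) rep(TRUE, nrow(logd)) else apply(logd, 1, max) > log(k)
  }
}

#' Read and write trial tables
#'
#' Trial tables are plain CSV files with a header row, one row per trial,
#' orientations in physical degrees.  Numeric values are written with 17
#' significant digits so that a write/read cycle reproduces doubles
#' exactly and files round-trip byte-identically.
#'
#' @param trials a trial table (see [generate_trials()] for the schema).
#' @param path file path.
#' @return `read_trials`: the trial table; `write_trials`: `path`,
#'   invisibly.
#' @export
write_trials <- function(trials, path) {
  out <- trials
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  # NA fields stay empty
  out[] <- lapply(out, function(x) ifelse(is.na(x) | x == "NA", "", as.character(x)))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- tryCatch(
    suppressWarnings(read.csv(path, stringsAsFactors = FALSE, colClasses = NA)),
    error = function(e) stop("failed to parse trial table ", path, ": ",
                             conditionMessage(e))
  )
  need <- c("trial_id", paste0("rel_", 1:4), paste0("theta_", 1:4),
            paste0("phi_", 1:4), "change", "change_location", "delta")
  missing <- setdiff(need, names(tr))
  if (length(missing)) {
    stop("trial table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"response" %in% names(tr)) tr$response <- NA_integer_
  for (col in c("trial_id", "change", "change_location", "response")) {
    tr[[col]] <- as.integer(tr[[col]])
  }
  for (col in c(paste0("theta_", 1:4), paste0("phi_", 1:4), "delta")) {
    tr[[col]] <- as.numeric(tr[[col]])
  }
  bad <- which(!(tr$change %in% c(0L, 1L)))
  if (length(bad)) stop("invalid 'change' value at row ", bad[1])
  tr
}
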