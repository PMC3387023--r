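# Fixed assumed precision used by the single-precision Max models (VSM/ESM).
# In these models the assumed precision and the criterion are redundant: the
# decision is equivalent to thresholding the maximum absolute circular
# difference, so only the criterion is free (hence Table-style parameter
# counts of 4 and 3).  The constant sets the scale on which the criterion k
# maps onto distance thresholds.
.j_single_max <- 5

.model_codes <- c("VVO", "VEO", "VAO", "VSO", "VVM", "VEM", "VAM", "VSM",
                  "EEO", "EAO", "ESO", "EEM", "EAM", "ESM")
.noise_codes <- c("EEO+local", "EEO+global")

.spec_params <- function(encoding, assumption, rule, noise) {
  p <- if (encoding == "V") c("Jbar_low", "Jbar_high", "tau")
       else c("J_low", "J_high")
  if (assumption == "S" && rule == "O") p <- c(p, "J_assumed")
  p <- c(p, if (rule == "O") "p_change" else "k")
  if (noise == "local") p <- c(p, "sigma_local")
  if (noise == "global") p <- c(p, "sigma_global")
  p
}

#' Observer model specification
#'
#' An observer model is a point in the taxonomy
#' (encoding EP/VP) x (assumption about precision) x (integration rule),
#' written as a three-letter code.  First letter: `V`ariable or `E`qual
#' encoding precision.  Second letter, the observer's assumption about
#' precision: `V` = knows each item's realized precision (only meaningful
#' under VP encoding), `E` = precision determined by reliability, `A` =
#' the display average of the realized precisions, `S` = one single value
#' throughout.  Third letter: `O`ptimal integration of local likelihood
#' ratios, or the suboptimal `M`ax rule.  Under EP encoding, assumptions
#' V and E coincide, which is why there is no `EV*` model; exactly 14
#' combinations remain.  Two decision-noise variants of EEO
#' (`"EEO+local"`, `"EEO+global"`) add zero-mean Gaussian noise to the log
#' local decision variables or to the log of the pooled decision variable.
#'
#' @param code model code, e.g. `"VVO"` or `"EEO+local"`.
#' @return an object of class `"observer_spec"`: a list with elements
#'   `code`, `encoding`, `assumption`, `rule`, `noise` and `params` (the
#'   ordered free-parameter names).
#' @seealso [observer_models()] for the full table, [default_params()],
#'   [default_grid()].
#' @examples
#' observer_model("VVO")
#' observer_model("ESM")$params
#' @export
observer_model <- function(code) {
  valid <- c(.model_codes, .noise_codes)
  if (!is.character(code) || length(code) != 1 || !(code %in% valid)) {
    stop("unknown model code ", deparse(code), "; valid codes are: ",
         paste(valid, collapse = ", "))
  }
  base <- sub("\\+.*$", "", code)
  noise <- if (grepl("\\+local$", code)) "local"
           else if (grepl("\\+global$", code)) "global" else "none"
  enc <- substr(base, 1, 1)
  ass <- substr(base, 2, 2)
  rule <- substr(base, 3, 3)
  structure(list(code = code, encoding = enc, assumption = ass, rule = rule,
                 noise = noise,
                 params = .spec_params(enc, ass, rule, noise)),
            class = "observer_spec")
}

#' @export
print.observer_spec <- function(x, ...) {
  enc <- c(V = "variable precision", E = "equal precision")[x$encoding]
  ass <- c(V = "knows realized precision", E = "precision from reliability",
           A = "display-average precision", S = "single assumed precision")[x$assumption]
  rule <- c(O = "optimal rule", M = "Max rule")[x$rule]
  cat("Observer model ", x$code, "\n",
      "  encoding:   ", enc, "\n",
      "  assumption: ", ass, "\n",
      "  rule:       ", rule, "\n", sep = "")
  if (x$noise != "none") cat("  decision noise: ", x$noise, "\n", sep = "")
  cat("  free parameters (", length(x$params), "): ",
      paste(x$params, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Enumerate the observer-model taxonomy
#'
#' Lists the 14 observer models (optionally plus the two EEO decision-noise
#' variants) with their free-parameter counts.
#'
#' @param noise_variants also include `"EEO+local"` and `"EEO+global"`.
#' @return data frame with columns `code`, `encoding`, `assumption`,
#'   `rule`, `noise`, `n_params`.
#' @examples
#' observer_models()
#' @export
observer_models <- function(noise_variants = FALSE) {
  codes <- .model_codes
  if (noise_variants) codes <- c(codes, .noise_codes)
  specs <- lapply(codes, observer_model)
  data.frame(
    code = codes,
    encoding = vapply(specs, `[[`, "", "encoding"),
    assumption = vapply(specs, `[[`, "", "assumption"),
    rule = vapply(specs, `[[`, "", "rule"),
    noise = vapply(specs, `[[`, "", "noise"),
    n_params = vapply(specs, function(s) length(s$params), 0L),
    stringsAsFactors = FALSE
  )
}

#' @rdname observer_models
#' @export
observer_codes <- function(noise_variants = FALSE) {
  if (noise_variants) c(.model_codes, .noise_codes) else .model_codes
}

# prior ranges for all parameters (uniform priors; used for grids)
.param_ranges <- list(
  J_low = c(1, 100), J_high = c(1, 100),
  Jbar_low = c(1, 100), Jbar_high = c(1, 100),
  J_assumed = c(1, 100),
  tau = c(1, 30),
  k = c(-2.2, 51.8),
  p_change = c(0.3, 0.7),
  sigma_local = c(0, 3), sigma_global = c(0, 3)
)

#' Parameter prior ranges
#'
#' The uniform prior range for each model parameter, used to build default
#' fitting/comparison grids: \[1, 100\] for all precision parameters,
#' \[1, 30\] for the gamma scale `tau`, \[-2.2, 51.8\] for the Max-rule
#' criterion `k` (on the likelihood-ratio scale; `k <= 0` always reports
#' "change"), \[0.3, 0.7\] for `p_change`, and \[0, 3\] for the decision
#' noise standard deviations.
#'
#' @param param optional parameter name(s); default all.
#' @return named list of length-2 numeric ranges.
#' @export
param_ranges <- function(param = NULL) {
  if (is.null(param)) return(.param_ranges)
  missing <- setdiff(param, names(.param_ranges))
  if (length(missing)) stop("unknown parameter(s): ", paste(missing, collapse = ", "))
  .param_ranges[param]
}

#' Representative parameter values for a model
#'
#' A single plausible parameter vector per model, used as generating values
#' for synthetic experiments and model-recovery checks: mean precision 6
#' (low reliability) and 30 (high), gamma scale `tau = 8` for VP encoding,
#' assumed precision 15 for single-precision optimal observers, unbiased
#' change prior 0.5, Max criterion `k = 3`, and decision-noise sd 0.3.
#' These put task accuracy in the informative mid-range (well off floor and
#' ceiling) for the experimental design simulated by [generate_trials()].
#'
#' @param model a model code or `"observer_spec"` object.
#' @return named numeric vector of the model's free parameters.
#' @examples
#' default_params("VSO")
#' @export
default_params <- function(model) {
  spec <- as_observer_spec(model)
  vals <- c(J_low = 6, J_high = 30, Jbar_low = 6, Jbar_high = 30,
            tau = 8, J_assumed = 15, p_change = 0.5, k = 3,
            sigma_local = 0.3, sigma_global = 0.3)
  vals[spec$params]
}

#' Default parameter grid for a model
#'
#' Grid points over each free parameter's prior range ([param_ranges()]),
#' used for grid maximum-likelihood fitting and Riemann-sum marginal
#' likelihoods.  Scale-like parameters (all precisions and the gamma scale
#' `tau`) get log-spaced points, which resolves their behaviorally relevant
#' low range; probabilities and noise standard deviations get linear
#' spacing.  The Max criterion `k` gets one point at the lower end of its
#' range (every `k <= 0` produces the same always-"change" observer) plus
#' log-spaced points over \[0.5, 51.8\].  The priors themselves remain
#' uniform over the full ranges: marginalization weights each grid point by
#' its Riemann cell width (see [log_marginal_from_grid()]).
#'
#' @param model a model code or `"observer_spec"` object.
#' @param n_points grid points per dimension (default 15; model-recovery
#'   runs typically use coarser grids, e.g. 8).
#' @return named list of numeric grid vectors, in the model's canonical
#'   parameter order.
#' @examples
#' default_grid("EEO", n_points = 5)
#' @export
default_grid <- function(model, n_points = 15) {
  spec <- as_observer_spec(model)
  stopifnot(n_points >= 1)
  log_pars <- c("J_low", "J_high", "Jbar_low", "Jbar_high", "J_assumed", "tau")
  out <- lapply(spec$params, function(p) {
    r <- .param_ranges[[p]]
    if (n_points == 1) return(mean(r))
    if (p %in% log_pars) {
      exp(seq(log(r[1]), log(r[2]), length.out = n_points))
    } else if (p == "k") {
      c(r[1], exp(seq(log(0.5), log(r[2]), length.out = n_points - 1)))
    } else {
      seq(r[1], r[2], length.out = n_points)
    }
  })
  setNames(out, spec$params)
}

#' @rdname observer_model
#' @param x object to coerce: a code string or an `"observer_spec"`.
#' @export
as_observer_spec <- function(x) {
  if (inherits(x, "observer_spec")) return(x)
  observer_model(x)
}

# validate a named parameter vector against a spec
.check_params <- function(spec, params) {
  params <- unlist(params)
  missing <- setdiff(spec$params, names(params))
  if (length(missing)) {
    stop("model ", spec$code, " needs parameter(s): ",
         paste(missing, collapse = ", "))
  }
  params <- params[spec$params]
  jpars <- intersect(names(params),
                     c("J_low", "J_high", "Jbar_low", "Jbar_high",
                       "J_assumed", "tau"))
  if (any(params[jpars] <= 0)) stop("precision/scale parameters must be > 0")
  if ("p_change" %in% names(params) &&
      (params[["p_change"]] <= 0 || params[["p_change"]] >= 1)) {
    stop("'p_change' must be strictly between 0 and 1")
  }
  if (any(params[grepl("^sigma", names(params))] < 0)) {
    stop("decision-noise sd must be >= 0")
  }
  params
}
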