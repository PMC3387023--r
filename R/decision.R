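#' Local decision variable for change at one location
#'
#' The posterior likelihood ratio of "change" versus "no change" at a single
#' location, given the two measurements and the concentrations the observer
#' attributes to them:
#' \deqn{d_i = \frac{I_0(\kappa_x) I_0(\kappa_y)}{I_0(\kappa_c)}, \qquad
#'   \kappa_c = \sqrt{\kappa_x^2 + \kappa_y^2 +
#'                    2 \kappa_x \kappa_y \cos(x_i - y_i)}.}
#' This closed form equals the ratio of the two marginal densities of the
#' generative model (change magnitude uniform on the circle), which the test
#' suite verifies against direct 2-D numerical marginalization.  `d_i = 1`
#' when both concentrations are 0 and grows monotonically with the circular
#' distance between the measurements.
#'
#' @param x,y measurements in the two displays (internal radians);
#'   vectors are paired elementwise.
#' @param kappa_x,kappa_y concentrations the observer assigns to the
#'   measurements (>= 0, recycled).
#' @return `local_d`: the likelihood ratio(s) `d_i > 0`; `local_log_d`:
#'   their logarithm (numerically safe for large concentrations).
#' @examples
#' local_d(0.2, -0.1, 5, 5)
#' @export
local_d <- function(x, y, kappa_x, kappa_y) {
  exp(local_log_d(x, y, kappa_x, kappa_y))
}

#' @rdname local_d
#' @export
local_log_d <- function(x, y, kappa_x, kappa_y) {
  if (any(!is.finite(c(x, y, kappa_x, kappa_y)))) {
    stop("all arguments must be finite")
  }
  if (any(c(kappa_x, kappa_y) < 0)) stop("concentrations must be >= 0")
  kc <- sqrt(kappa_x^2 + kappa_y^2 + 2 * kappa_x * kappa_y * cos(x - y))
  log_bessel_i0(kappa_x) + log_bessel_i0(kappa_y) - log_bessel_i0(kc)
}

#' Concentrations an observer assumes for a trial's measurements
#'
#' Implements the four assumptions about encoding precision.  `"V"`: the
#' observer knows each item's realized precision.  `"E"`: precision is taken
#' to be determined by reliability alone (the fixed `J_low`/`J_high` under
#' EP encoding, the gamma means `Jbar_low`/`Jbar_high` under VP).  `"A"`:
#' all items in a display get the arithmetic mean of that display's four
#' realized precisions (a "gist" representation, computed per display).
#' `"S"`: one single `J_assumed` for everything.  Under EP encoding, `"V"`
#' and `"E"` coincide.
#'
#' @param percept list with `jx`, `jy` (realized precisions, n x 4 matrices
#'   or length-4 vectors) and `reliability` (`"L"`/`"H"`, same shape).
#' @param model a model code or `"observer_spec"`.
#' @param params named parameters consistent with the model.
#' @return list with `kappa_x` and `kappa_y`, same shape as `percept$jx`.
#' @examples
#' p <- list(jx = c(2, 4, 6, 8), jy = c(2, 4, 6, 8),
#'           reliability = c("L", "L", "H", "H"))
#' assumed_kappas(p, "VAO", default_params("VAO"))
#' @export
assumed_kappas <- function(percept, model, params) {
  spec <- as_observer_spec(model)
  params <- .check_params(spec, params)
  jx <- percept$jx
  jy <- percept$jy
  rel <- percept$reliability
  as_mat <- function(v) if (is.matrix(v)) v else matrix(v, nrow = 1)
  jx <- as_mat(jx); jy <- as_mat(jy); rel <- as_mat(rel)
  if (!all(dim(jx) == dim(jy)) || !all(dim(jx) == dim(rel))) {
    stop("percept components must have matching dimensions")
  }
  shape <- function(k) if (is.matrix(percept$jx)) k else drop(k)
  switch(spec$assumption,
    V = {
      if (spec$encoding == "E") {
        stop("assumption \"V\" is not defined under EP encoding (equivalent to \"E\")")
      }
      list(kappa_x = shape(matrix(kappa_from_j(jx), nrow(jx))),
           kappa_y = shape(matrix(kappa_from_j(jy), nrow(jx))))
    },
    E = {
      jm <- if (spec$encoding == "V") c(params[["Jbar_low"]], params[["Jbar_high"]])
            else c(params[["J_low"]], params[["J_high"]])
      kk <- kappa_from_j(jm)
      k <- matrix(ifelse(rel == "H", kk[2], kk[1]), nrow(jx))
      list(kappa_x = shape(k), kappa_y = shape(k))
    },
    A = {
      kx <- kappa_from_j(rowMeans(jx))
      ky <- kappa_from_j(rowMeans(jy))
      list(kappa_x = shape(matrix(kx, nrow(jx), ncol(jx))),
           kappa_y = shape(matrix(ky, nrow(jx), ncol(jx))))
    },
    S = {
      ja <- if ("J_assumed" %in% names(params)) params[["J_assumed"]] else .j_single_max
      k <- kappa_from_j(ja)
      list(kappa_x = shape(matrix(k, nrow(jx), ncol(jx))),
           kappa_y = shape(matrix(k, nrow(jx), ncol(jx))))
    }
  )
}

#' Integration rules over local decision variables
#'
#' `optimal_rule` reports "change" when the prior-weighted mean of the local
#' likelihood ratios exceeds 1:
#' \deqn{\frac{p_{change}}{1 - p_{change}} \cdot \frac{1}{N} \sum_i d_i > 1.}
#' `max_rule` reports "change" when the largest local decision variable
#' exceeds a constant criterion, `max_i d_i > k` (so `k <= 0` always reports
#' "change").  Ties report "no change".
#'
#' @param d local decision variables: length-N vector (one trial) or an
#'   n x N matrix (n trials); all > 0.
#' @param p_change prior probability of a change, in (0, 1).
#' @param k Max-rule criterion on the likelihood-ratio scale.
#' @return logical (per trial): `TRUE` = report "change".
#' @examples
#' optimal_rule(c(9, 1, 1, 1), 0.5)
#' max_rule(c(0.5, 0.9, 1.1, 0.7), 1)
#' @export
optimal_rule <- function(d, p_change) {
  if (p_change <= 0 || p_change >= 1) stop("'p_change' must be in (0, 1)")
  d <- if (is.matrix(d)) d else matrix(d, nrow = 1)
  if (any(d <= 0)) stop("'d' must be > 0")
  drop(p_change / (1 - p_change) * rowMeans(d) > 1)
}

#' @rdname optimal_rule
#' @export
max_rule <- function(d, k) {
  d <- if (is.matrix(d)) d else matrix(d, nrow = 1)
  if (any(d <= 0)) stop("'d' must be > 0")
  drop(apply(d, 1, max) > k)
}

#' Decision rules with late Gaussian noise
#'
#' Variants of the optimal rule with zero-mean Gaussian noise added on the
#' log scale: `"local"` perturbs each log local decision variable
#' independently before integration; `"global"` perturbs the log of the
#' pooled (prior-weighted mean) decision variable once.  `sigma = 0`
#' reduces exactly to [optimal_rule()].  Noise is drawn from R's RNG
#' stream.
#'
#' @inheritParams optimal_rule
#' @param variant `"local"` or `"global"`.
#' @param sigma noise standard deviation (log units), >= 0.
#' @return logical (per trial): `TRUE` = report "change".
#' @examples
#' set.seed(1)
#' apply_decision_noise(c(2, 0.5, 0.5, 0.5), "local", 0.3, 0.5)
#' @export
apply_decision_noise <- function(d, variant = c("local", "global"), sigma,
                                 p_change) {
  variant <- match.arg(variant)
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (p_change <= 0 || p_change >= 1) stop("'p_change' must be in (0, 1)")
  d <- if (is.matrix(d)) d else matrix(d, nrow = 1)
  if (any(d <= 0)) stop("'d' must be > 0")
  logd <- log(d)
  if (variant == "local" && sigma > 0) {
    logd <- logd + matrix(rnorm(length(logd), 0, sigma), nrow(logd))
  }
  lhs <- log(p_change / (1 - p_change)) + .row_lse(logd) - log(ncol(logd))
  if (variant == "global" && sigma > 0) {
    lhs <- lhs + rnorm(length(lhs), 0, sigma)
  }
  drop(lhs > 0)
}

# row-wise log-sum-exp
.row_lse <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}
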