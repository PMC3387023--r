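#' Sample from a von Mises distribution
#'
#' Draws from VM(mu, kappa) on the internal orientation circle \[-pi, pi)
#' using the Best-Fisher rejection algorithm.  `kappa = 0` gives the uniform
#' distribution.  Randomness comes from R's RNG stream, so results are
#' reproducible via [set.seed()].
#'
#' @param n number of draws.
#' @param mu mean direction (internal radians); scalar or length `n`.
#' @param kappa concentration >= 0; scalar or length `n`.
#' @return numeric vector of `n` angles in \[-pi, pi).
#' @examples
#' set.seed(1)
#' x <- sample_von_mises(1000, 0, 5)
#' mean(cos(x)) # close to I1(5)/I0(5)
#' @export
sample_von_mises <- function(n, mu = 0, kappa = 1) {
  stopifnot(length(n) == 1, n >= 0)
  if (any(!is.finite(kappa)) || any(kappa < 0)) {
    stop("'kappa' must be finite and >= 0")
  }
  if (length(mu) == 1 && length(kappa) == 1) {
    return(rvm_cpp(as.integer(n), wrap_internal(mu), kappa))
  }
  mu <- rep_len(wrap_internal(mu), n)
  kappa <- if (length(kappa) == 1) kappa else rep_len(kappa, n)
  rvm_vec_cpp(mu, kappa)
}

#' Draw a noisy measurement of an orientation
#'
#' One step of the encoding stage.  Under equal precision (EP) the realized
#' precision is the fixed value for the item's reliability
#' (`J_low`/`J_high`).  Under variable precision (VP) it is drawn fresh from
#' a gamma distribution with mean `Jbar_low`/`Jbar_high` (by reliability)
#' and scale `tau`, so the marginal measurement distribution is a
#' gamma-mixture of von Mises distributions.  The measurement is then drawn
#' from VM(theta, kappa(J)).
#'
#' @param theta true orientation(s), internal radians.
#' @param reliability `"L"` or `"H"` per item (recycled).
#' @param encoding `"E"` (equal precision) or `"V"` (variable precision).
#' @param params named list/vector with `J_low`, `J_high` (EP) or
#'   `Jbar_low`, `Jbar_high`, `tau` (VP); all > 0.
#' @return list with `measurement` (internal radians) and `j` (the realized
#'   precision, available to the omniscient observer assumption).
#' @examples
#' set.seed(1)
#' sample_measurement(0, "H", "E", list(J_low = 5, J_high = 20))
#' @export
sample_measurement <- function(theta, reliability, encoding = c("E", "V"),
                               params) {
  encoding <- match.arg(encoding)
  n <- length(theta)
  reliability <- rep_len(reliability, n)
  if (!all(reliability %in% c("L", "H"))) {
    stop("'reliability' must be \"L\" or \"H\"")
  }
  hi <- reliability == "H"
  p <- as.list(params)
  if (encoding == "E") {
    jl <- p$J_low
    jh <- p$J_high
    if (is.null(jl) || is.null(jh) || jl <= 0 || jh <= 0) {
      stop("EP encoding needs J_low > 0 and J_high > 0")
    }
    j <- ifelse(hi, jh, jl)
  } else {
    jl <- p$Jbar_low
    jh <- p$Jbar_high
    tau <- p$tau
    if (is.null(jl) || is.null(jh) || is.null(tau) ||
        jl <= 0 || jh <= 0 || tau <= 0) {
      stop("VP encoding needs Jbar_low, Jbar_high and tau, all > 0")
    }
    jbar <- ifelse(hi, jh, jl)
    j <- stats::rgamma(n, shape = jbar / tau, scale = tau)
  }
  kappa <- .kappa_fast(j)
  list(measurement = sample_von_mises(n, theta, kappa), j = j)
}
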