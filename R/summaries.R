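#' Behavioral summary statistics
#'
#' Hit and false-alarm rates as a function of the number of high-reliability
#' items, hit rates conditioned on the reliability of the changed item (the
#' decomposition behind the Simpson's-paradox Z-shape), and psychometric
#' curves (proportion of "change" reports on change trials in 8 equal-width
#' magnitude bins over (0, 90\] degrees, per `n_high`).  Cells the design
#' leaves undefined (a high-reliability change with `n_high = 0`, a
#' low-reliability change with `n_high = 4`) or that contain no trials are
#' `NA`, never 0.
#'
#' @param trials a trial table with responses.
#' @return an object of class `"cd_summary"`: list with `rates` (data frame
#'   over `n_high` 0..4: `fa_rate`, `hit_rate`, `hit_low`, `hit_high` and
#'   the trial counts behind them), `psychometric` (8 x 5 matrix),
#'   `psy_counts`, and `psy_edges`.
#' @examples
#' tr <- simulate_responses(generate_trials(2000, seed = 1), "VVO",
#'                          default_params("VVO"), seed = 2)
#' summarize_trials(tr)$rates
#' @export
summarize_trials <- function(trials) {
  if (any(is.na(trials$response))) stop("all trials must have responses")
  m <- .trial_mats(trials)
  nh <- rowSums(m$rel == "H")
  resp <- trials$response == 1
  chg <- trials$change == 1
  crel <- rep(NA_character_, nrow(trials))
  ch <- which(chg)
  if (length(ch)) crel[ch] <- m$rel[cbind(ch, trials$change_location[ch])]

  rate <- function(sel) {
    vapply(0:4, function(h) {
      i <- sel & nh == h
      if (!any(i)) NA_real_ else mean(resp[i])
    }, numeric(1))
  }
  count <- function(sel) vapply(0:4, function(h) sum(sel & nh == h), numeric(1))

  rates <- data.frame(
    n_high = 0:4,
    n_nochange = count(!chg),
    fa_rate = rate(!chg),
    n_change = count(chg),
    hit_rate = rate(chg),
    n_change_low = count(chg & crel == "L" & !is.na(crel)),
    hit_low = rate(chg & crel == "L" & !is.na(crel)),
    n_change_high = count(chg & crel == "H" & !is.na(crel)),
    hit_high = rate(chg & crel == "H" & !is.na(crel))
  )

  edges <- seq(0, 90, length.out = 9)
  bin <- cut(abs(trials$delta), edges, include.lowest = TRUE, labels = FALSE)
  psy <- matrix(NA_real_, 8, 5, dimnames = list(NULL, paste0("nh", 0:4)))
  psy_n <- matrix(0L, 8, 5, dimnames = dimnames(psy))
  for (h in 0:4) {
    for (b in 1:8) {
      i <- chg & nh == h & !is.na(bin) & bin == b
      psy_n[b, h + 1] <- sum(i)
      if (any(i)) psy[b, h + 1] <- mean(resp[i])
    }
  }
  structure(list(rates = rates, psychometric = psy, psy_counts = psy_n,
                 psy_edges = edges), class = "cd_summary")
}

#' @export
print.cd_summary <- function(x, digits = 3, ...) {
  cat("Change-detection summary\n")
  r <- x$rates
  r[-1] <- lapply(r[-1], function(v) round(v, digits))
  print(r, row.names = FALSE)
  invisible(x)
}

#' Model-predicted summary statistics
#'
#' The same statistics as [summarize_trials()], computed from a model's
#' Monte-Carlo prediction table weighted by the experimental design's
#' trial-type frequencies (uniform `n_high`, 50% change prior, uniform
#' change magnitude, change location uniform so that a high-reliability
#' change has probability `n_high / 4`).
#'
#' @inheritParams predict_table
#' @return a `"cd_summary"` object (counts are `NA`: the statistics are
#'   exact design expectations given the prediction table).
#' @examples
#' model_summary("EEO", default_params("EEO"), n_samples = 200)$rates
#' @export
model_summary <- function(model, params, n_samples = 1000, seed = 1) {
  pt <- predict_table(model, params, n_samples = n_samples, seed = seed)
  bins <- seq(0, 90, by = 3)
  wb <- ifelse(bins %in% c(0, 90), 1.5, 3) / 90
  p_of <- function(b, h, r) {
    pt$p_change_report[pt$delta_bin == b & pt$n_high == h &
                       pt$changed_rel == r]
  }
  fa <- vapply(0:4, function(h) p_of(0, h, "L"), numeric(1))
  hit_low <- vapply(0:4, function(h) {
    if (h == 4) return(NA_real_)
    sum(wb * vapply(bins, p_of, numeric(1), h = h, r = "L"))
  }, numeric(1))
  hit_high <- vapply(0:4, function(h) {
    if (h == 0) return(NA_real_)
    sum(wb * vapply(bins, p_of, numeric(1), h = h, r = "H"))
  }, numeric(1))
  wlow <- 1 - (0:4) / 4
  hit <- ifelse(wlow > 0, wlow * hit_low, 0) +
         ifelse(wlow < 1, (1 - wlow) * hit_high, 0)

  edges <- seq(0, 90, length.out = 9)
  psy <- matrix(NA_real_, 8, 5, dimnames = list(NULL, paste0("nh", 0:4)))
  grp <- pmax(1L, ceiling(bins / 11.25))
  for (h in 0:4) {
    pl <- vapply(bins, p_of, numeric(1), h = h, r = "L")
    ph <- vapply(bins, p_of, numeric(1), h = h, r = "H")
    w <- wlow[h + 1]
    pmix <- (if (w > 0) w * pl else 0) + (if (w < 1) (1 - w) * ph else 0)
    for (b in 1:8) {
      sel <- grp == b
      psy[b, h + 1] <- sum(wb[sel] * pmix[sel]) / sum(wb[sel])
    }
  }
  rates <- data.frame(
    n_high = 0:4, n_nochange = NA, fa_rate = fa, n_change = NA,
    hit_rate = hit, n_change_low = NA, hit_low = hit_low,
    n_change_high = NA, hit_high = hit_high
  )
  structure(list(rates = rates, psychometric = psy, psy_counts = NULL,
                 psy_edges = edges), class = "cd_summary")
}

#' Goodness of fit between observed and predicted summaries
#'
#' Coefficient of determination `1 - SS_res / SS_tot` over matched summary
#' cells.  `which = "rates"` uses the false-alarm rates and unconditioned
#' hit rates (up to 10 points); `which = "psychometric"` uses the 8 x 5
#' psychometric cells.  Cells undefined in either summary are dropped;
#' fewer than 2 shared cells is an error.
#'
#' @param observed,predicted `"cd_summary"` objects.
#' @param which `"rates"` or `"psychometric"`.
#' @return scalar (at most 1; can be negative for fits worse than the
#'   observed mean).
#' @export
r_squared <- function(observed, predicted,
                      which = c("rates", "psychometric")) {
  which <- match.arg(which)
  if (which == "rates") {
    x <- c(observed$rates$fa_rate, observed$rates$hit_rate)
    y <- c(predicted$rates$fa_rate, predicted$rates$hit_rate)
  } else {
    x <- as.vector(observed$psychometric)
    y <- as.vector(predicted$psychometric)
  }
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) stop("fewer than 2 shared defined cells")
  x <- x[ok]
  y <- y[ok]
  1 - sum((x - y)^2) / sum((x - mean(x))^2)
}

# observed summary reconstructed from 310-type counts (used by fit plots;
# the tiny fraction of change trials with |delta| < 1.5 degrees shares the
# bin-0 cells with the no-change trials, so its false-alarm rate is an
# approximation at the per-mille level)
.summary_from_counts <- function(counts) {
  types <- trial_types()
  tot <- drop(counts$n1 + counts$n0)
  p <- ifelse(tot > 0, drop(counts$n1) / tot, NA_real_)
  agg <- function(sel) {
    n <- sum(tot[sel])
    if (n == 0) NA_real_ else sum(drop(counts$n1)[sel]) / n
  }
  rates <- data.frame(
    n_high = 0:4,
    n_nochange = vapply(0:4, function(h) sum(tot[types$delta_bin == 0 &
      types$n_high == h & types$changed_rel == "L"]), numeric(1)),
    fa_rate = vapply(0:4, function(h) agg(types$delta_bin == 0 &
      types$n_high == h & types$changed_rel == "L"), numeric(1)),
    n_change = vapply(0:4, function(h) sum(tot[types$delta_bin > 0 &
      types$n_high == h]), numeric(1)),
    hit_rate = vapply(0:4, function(h) agg(types$delta_bin > 0 &
      types$n_high == h), numeric(1)),
    n_change_low = NA,
    hit_low = vapply(0:4, function(h) agg(types$delta_bin > 0 &
      types$n_high == h & types$changed_rel == "L"), numeric(1)),
    n_change_high = NA,
    hit_high = vapply(0:4, function(h) agg(types$delta_bin > 0 &
      types$n_high == h & types$changed_rel == "H"), numeric(1))
  )
  edges <- seq(0, 90, length.out = 9)
  psy <- matrix(NA_real_, 8, 5, dimnames = list(NULL, paste0("nh", 0:4)))
  grp <- pmax(1L, ceiling(types$delta_bin / 11.25))
  for (h in 0:4) {
    for (b in 1:8) {
      sel <- types$delta_bin > 0 & types$n_high == h & grp == b
      psy[b, h + 1] <- agg(sel)
    }
  }
  structure(list(rates = rates, psychometric = psy, psy_counts = NULL,
                 psy_edges = edges), class = "cd_summary")
}

.plot_rates <- function(obs, prd = NULL, main = "") {
  r <- obs$rates
  plot(r$n_high, r$hit_rate, type = "b", pch = 16, ylim = c(0, 1),
       xlab = expression(N[H]), ylab = "proportion 'change' reports",
       main = main)
  points(r$n_high, r$hit_low, type = "b", pch = 17, col = "goldenrod")
  points(r$n_high, r$hit_high, type = "b", pch = 15, col = "forestgreen")
  points(r$n_high, r$fa_rate, type = "b", pch = 1, col = "grey40")
  if (!is.null(prd)) {
    pr <- prd$rates
    lines(pr$n_high, pr$hit_rate, lwd = 2, col = "black")
    lines(pr$n_high, pr$hit_low, lwd = 2, col = "goldenrod")
    lines(pr$n_high, pr$hit_high, lwd = 2, col = "forestgreen")
    lines(pr$n_high, pr$fa_rate, lwd = 2, col = "grey40")
  }
  legend("topleft", bty = "n", cex = 0.8,
         legend = c("hit", "hit | low change", "hit | high change",
                    "false alarm"),
         col = c("black", "goldenrod", "forestgreen", "grey40"),
         pch = c(16, 17, 15, 1))
}

#' @export
plot.cd_summary <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  .plot_rates(x, main = "rates by reliability")
  mids <- (x$psy_edges[-1] + x$psy_edges[-9]) / 2
  matplot(mids, x$psychometric, type = "b", pch = 16, lty = 1, ylim = c(0, 1),
          xlab = "magnitude of change (deg)",
          ylab = "proportion 'change' reports", main = "psychometric curves")
  legend("bottomright", bty = "n", cex = 0.8, col = 1:5, lty = 1, pch = 16,
         legend = paste0("N_H = ", 0:4))
  invisible(x)
}
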