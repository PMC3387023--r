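# ---------------------------------------------------------------------------
# Grid evaluation engine.
#
# Everything downstream of the percept simulation depends on the dataset only
# through its 310 x 2 table of response counts per trial type, and on the
# model only through (a) the percepts simulated at one *encoding* parameter
# combination and (b) cheap decision-stage sweeps.  The engine therefore
# loops over encoding combinations once, simulates percepts there (common
# random numbers: the RNG is re-seeded identically at every combination),
# computes per-sample decision statistics per observer assumption (cached
# within a combination so that e.g. VVO and VVM share them), sweeps the
# decision parameters analytically, and scores all datasets at once.
# ---------------------------------------------------------------------------

# Evaluate log likelihood over full parameter grids for several specs and
# several datasets.
#
# n1, n0: 310 x D matrices of per-type response counts ("change"/"no change")
# specs: list of observer_spec; grids_list: per spec, named list of grid
# vectors covering every free parameter (length-1 vectors give point
# evaluation).  Returns, per spec code: logL (n_grid_points x D), params
# (grid table, canonical parameter order), n_per_par, and optionally the
# last prediction matrix (keep_p, only meaningful for single-point encoding
# grids).
.evaluate_models <- function(n1, n0, specs, grids_list, n_samples, seed,
                             keep_p = FALSE) {
  types <- trial_types()
  tnh <- as.integer(types$n_high)
  tdel <- types$delta_bin * pi / 90       # physical deg -> internal radians
  tcrel <- as.integer(types$changed_rel == "H")
  unreach <- .unreachable_types(types)
  eps <- 1 / (2 * n_samples)
  D <- ncol(n1)
  codes <- vapply(specs, `[[`, "", "code")
  out <- setNames(vector("list", length(specs)), codes)
  kg <- .kappa_cache()
  qt <- .vm_qtable()

  # Shared noise quantiles and nuisance-configuration draws: one set per
  # call, reused at every grid point and by both encoding regimes, so that
  # Monte-Carlo error is common across models and cancels in comparisons.
  S <- length(tnh) * n_samples
  set.seed(seed)
  zx <- rnorm(4L * S)
  zy <- rnorm(4L * S)
  ucfg <- runif(5L * S)
  any_noise <- any(vapply(specs, function(s) s$noise != "none", TRUE))
  nd <- if (any_noise) list(z = rnorm(4L * S), g = rnorm(S))

  for (enc in c("V", "E")) {
    gi <- which(vapply(specs, function(s) s$encoding == enc, TRUE))
    if (!length(gi)) next
    enc_names <- if (enc == "V") c("Jbar_low", "Jbar_high", "tau")
                 else c("J_low", "J_high")
    eg0 <- grids_list[[gi[1]]][enc_names]
    for (i in gi[-1]) {
      same <- identical(lapply(grids_list[[i]][enc_names], as.numeric),
                        lapply(eg0, as.numeric))
      if (!same) {
        stop("models sharing an encoding stage must use identical ",
             "encoding-parameter grids (", paste(enc_names, collapse = ", "), ")")
      }
    }
    eg <- expand.grid(eg0, KEEP.OUT.ATTRS = FALSE)
    nG <- nrow(eg)

    store <- list()
    dec_grids <- list()
    for (i in gi) {
      s <- specs[[i]]
      dg <- grids_list[[i]][setdiff(s$params, enc_names)]
      ndec <- max(1L, prod(vapply(dg, length, 0L)))
      store[[s$code]] <- matrix(NA_real_, nG * ndec, D)
      dec_grids[[s$code]] <- dg
    }

    for (g in seq_len(nG)) {
      ep <- as.list(eg[g, , drop = FALSE])
      pc <- if (enc == "V") {
        set.seed(seed)                     # common gamma stream per point
        sim_percepts_q_cpp(tnh, tdel, tcrel, n_samples, TRUE,
                           ep$Jbar_low, ep$Jbar_high, ep$tau,
                           zx, zy, ucfg,
                           qt$tab, qt$nz, qt$zmax, qt$dz,
                           qt$lkmin, qt$dlk, qt$nk,
                           kg$lk, kg$ljmin, kg$dlj)
      } else {
        sim_percepts_q_cpp(tnh, tdel, tcrel, n_samples, FALSE,
                           ep$J_low, ep$J_high, 1,
                           zx, zy, ucfg,
                           qt$tab, qt$nz, qt$zmax, qt$dz,
                           qt$lkmin, qt$dlk, qt$nk,
                           kg$lk, kg$ljmin, kg$dlj)
      }
      cache <- new.env(parent = emptyenv())
      for (i in gi) {
        s <- specs[[i]]
        P <- .spec_p_matrix(s, pc, enc, ep, dec_grids[[s$code]], n_samples,
                            cache, nd)
        P[unreach, ] <- 0.5                # never reached; keep logs finite
        P <- pmin(pmax(P, eps), 1 - eps)
        ll <- crossprod(log(P), n1) + crossprod(log1p(-P), n0)
        ndec <- nrow(ll)
        store[[s$code]][((g - 1L) * ndec + 1L):(g * ndec), ] <- ll
        if (keep_p && nG == 1L) {
          attr(store[[s$code]], "p") <- P
        }
      }
    }

    for (i in gi) {
      s <- specs[[i]]
      dg <- dec_grids[[s$code]]
      dec_tab <- if (length(dg)) expand.grid(dg, KEEP.OUT.ATTRS = FALSE)
                 else data.frame(.dummy = 1)[, 0, drop = FALSE]
      ndec <- max(1L, nrow(dec_tab))
      ptab <- cbind(eg[rep(seq_len(nG), each = ndec), , drop = FALSE],
                    dec_tab[rep_len(seq_len(max(1L, nrow(dec_tab))), ndec * nG), ,
                            drop = FALSE])
      rownames(ptab) <- NULL
      ptab <- ptab[s$params]
      out[[s$code]] <- list(
        logL = store[[s$code]],
        params = ptab,
        n_per_par = vapply(grids_list[[i]][s$params], length, 0L),
        # grid vectors in the storage order of logL rows (decision
        # parameters vary fastest, then encoding parameters)
        grid_storage = c(dg, eg0),
        p = attr(store[[s$code]], "p")
      )
    }
  }
  out
}

# Prediction matrix (310 types x decision-parameter combinations) for one
# spec at one encoding combination.  Column order matches
# expand.grid(decision grids) with the first decision parameter varying
# fastest.
.spec_p_matrix <- function(spec, pc, enc, ep, dg, n_samples, cache, nd) {
  nT <- pc$n_types

  if (spec$noise == "none") {
    if (spec$rule == "O") {
      pgrid <- dg$p_change
      thr_p <- log((1 - pgrid) / pgrid)
      if (spec$assumption == "S") {
        stm <- .s_stats(pc, dg$J_assumed, cache)
        nja <- length(dg$J_assumed)
        out <- matrix(NA_real_, nT, nja * length(pgrid))
        for (ij in seq_len(nja)) {
          cols <- sweep_cpp(stm[, 2L * ij - 1L], n_samples, thr_p)
          out[, (seq_along(pgrid) - 1L) * nja + ij] <- cols
        }
        out
      } else {
        st <- .assumption_stats(pc, enc, ep, spec$assumption, cache)
        sweep_cpp(st$stats[, 1], n_samples, thr_p)
      }
    } else {
      kg <- dg$k
      st_m <- if (spec$assumption == "S") {
        .s_stats(pc, .j_single_max, cache)[, 2]
      } else {
        .assumption_stats(pc, enc, ep, spec$assumption, cache)$stats[, 2]
      }
      pos <- kg > 0
      out <- matrix(1, nT, length(kg))
      if (any(pos)) out[, pos] <- sweep_cpp(st_m, n_samples, log(kg[pos]))
      out
    }
  } else {
    # EEO decision-noise variants: assumption E, optimal rule.  Standard
    # normal draws are shared across the sigma sweep (common random numbers).
    st <- .assumption_stats(pc, enc, ep, "E", cache)
    pgrid <- dg$p_change
    thr_p <- log((1 - pgrid) / pgrid)
    np <- length(pgrid)
    sgrid <- if (spec$noise == "local") dg$sigma_local else dg$sigma_global
    out <- matrix(NA_real_, nT, np * length(sgrid))
    for (is in seq_along(sgrid)) {
      a <- if (sgrid[is] == 0) {
        st$stats[, 1]
      } else if (spec$noise == "local") {
        pair_stats_cpp(st$logd + sgrid[is] * nd$z, 4L)[, 1]
      } else {
        st$stats[, 1] + sgrid[is] * nd$g
      }
      out[, ((is - 1L) * np + 1L):(is * np)] <- sweep_cpp(a, n_samples, thr_p)
    }
    out
  }
}

# Per-sample decision statistics (optimal-rule pooled statistic and Max
# statistic) for one observer assumption at one encoding combination,
# cached so models sharing an assumption reuse them.
.assumption_stats <- function(pc, enc, ep, assumption, cache) {
  got <- cache[[assumption]]
  if (!is.null(got)) return(got)
  res <- if (assumption == "V") {
    # the concentrations actually used to draw the measurements
    list(stats = stats_cpp(pc$cosd, pc$kx, pc$ky, 4L))
  } else if (assumption == "E") {
    jm <- if (enc == "V") c(ep$Jbar_low, ep$Jbar_high) else c(ep$J_low, ep$J_high)
    kk <- .kappa_fast(jm)
    k <- ifelse(pc$rel == 1L, kk[2], kk[1])
    logd <- logd_cpp(pc$cosd, k, k)
    list(stats = pair_stats_cpp(logd, 4L), logd = logd)
  } else {                                    # A
    kx <- rep(.kappa_fast(pc$mjx), each = 4L)
    ky <- rep(.kappa_fast(pc$mjy), each = 4L)
    list(stats = stats_cpp(pc$cosd, kx, ky, 4L))
  }
  cache[[assumption]] <- res
  res
}

# Statistics for the single-assumed-precision observer over a sweep of
# assumed precisions (columns 2j-1, 2j of the result belong to ja[j]);
# c0 = sqrt(2 + 2 cos(x - y)) is shared across the sweep and cached.
.s_stats <- function(pc, ja, cache) {
  key <- paste0("S_", paste(format(ja, digits = 15), collapse = "_"))
  got <- cache[[key]]
  if (!is.null(got)) return(got)
  if (is.null(cache[["c0"]])) cache[["c0"]] <- sqrt(pmax(2 + 2 * pc$cosd, 0))
  res <- stats_s_cpp(cache[["c0"]], .kappa_fast(ja), 4L)
  cache[[key]] <- res
  res
}
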