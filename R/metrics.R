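# Error metrics and analytic validity estimates for QSSA reductions.

#' Initial-condition region for the reduction-error scan
#'
#' The region over which the deterministic reduction error is maximized:
#' per-slow-species intervals (typically stationary mean +/- 3 SD from the
#' reduced model's stochastic simulation) crossed with the fast species'
#' physical ranges.
#'
#' @param slow_intervals Named list of `c(lo, hi)` intervals, one per reduced
#'   (slow) species.
#' @param fast_ranges Named list of `c(lo, hi)` ranges, one per fast species.
#' @param grid_points_per_dim Grid resolution per dimension (endpoints
#'   included; a degenerate interval contributes a single point).
#' @return A `qssa_ic_region` object.
#' @export
ic_region <- function(slow_intervals, fast_ranges = list(),
                      grid_points_per_dim = 5) {
  check_intervals <- function(lst, what) {
    for (nm in names(lst)) {
      iv <- lst[[nm]]
      if (length(iv) != 2 || !is.numeric(iv) || iv[1] > iv[2])
        stop(what, " for `", nm, "` must be c(lo, hi) with lo <= hi", call. = FALSE)
    }
  }
  check_intervals(slow_intervals, "slow interval")
  check_intervals(fast_ranges, "fast range")
  structure(list(slow_intervals = slow_intervals, fast_ranges = fast_ranges,
                 grid_points_per_dim = as.integer(grid_points_per_dim)),
            class = "qssa_ic_region")
}

#' @export
print.qssa_ic_region <- function(x, ...) {
  cat("<IC region> grid:", x$grid_points_per_dim, "points per dimension\n")
  for (nm in names(x$slow_intervals))
    cat("  slow", nm, ": [", format(x$slow_intervals[[nm]][1]), ",",
        format(x$slow_intervals[[nm]][2]), "]\n")
  for (nm in names(x$fast_ranges))
    cat("  fast", nm, ": [", format(x$fast_ranges[[nm]][1]), ",",
        format(x$fast_ranges[[nm]][2]), "]\n")
  invisible(x)
}

grid_points <- function(iv, g) {
  if (abs(iv[2] - iv[1]) < 1e-12) return(iv[1])
  seq(iv[1], iv[2], length.out = g)
}

#' Deterministic reduction error over an initial-condition region
#'
#' Evaluates the relative L1 trajectory error (see [l1_relative_error()]) of
#' the reduced model against the full model for every point of the cartesian
#' grid (slow intervals x fast ranges). The reduced model's initial condition
#' takes only the slow coordinates, so each reduced trajectory is shared
#' across the fast grid; the full model starts from the lifted state.
#' Returns the maximum error, where it occurred, and the full per-IC table.
#'
#' @param pair A [model_pair()].
#' @param region A [ic_region()] covering every reduced species (and every
#'   fast species of the pair with a finite range).
#' @param T Error horizon; defaults to the pair's recommended `T`.
#' @param n_out,rtol,atol ODE settings (see [integrate_network()]); `NULL`
#'   falls back to the pair's recommended settings.
#' @param on_failure `"stop"` (default) to fail hard on an ODE failure at any
#'   initial condition, or `"skip"` to record `NA` and exclude that point.
#' @return A `qssa_det_error` object with fields `max_error`, `argmax`,
#'   `per_ic` (tibble of initial conditions and errors), `T`, `observable`.
#' @export
deterministic_qssa_error <- function(pair, region, T = NULL, n_out = NULL,
                                     rtol = NULL, atol = NULL,
                                     on_failure = c("stop", "skip")) {
  on_failure <- match.arg(on_failure)
  stopifnot(inherits(pair, "model_pair"), inherits(region, "qssa_ic_region"))
  T <- T %||% pair$defaults$T %||% stop("supply the error horizon `T`", call. = FALSE)
  n_out <- n_out %||% pair$defaults$n_out %||% 2000
  rtol <- rtol %||% pair$defaults$rtol %||% 1e-8
  atol <- atol %||% pair$defaults$atol %||% 1e-10

  red_sp <- pair$reduced$species$name
  missing_slow <- setdiff(red_sp, names(region$slow_intervals))
  if (length(missing_slow))
    stop("region lacks slow intervals for: ", paste(missing_slow, collapse = ", "),
         call. = FALSE)
  g <- region$grid_points_per_dim
  slow_grid <- expand.grid(lapply(region$slow_intervals[red_sp], grid_points, g = g),
                           KEEP.OUT.ATTRS = FALSE)
  names(slow_grid) <- red_sp

  if (length(pair$fast)) {
    missing_fast <- setdiff(pair$fast, names(region$fast_ranges))
    if (length(missing_fast))
      stop("region lacks fast ranges for: ", paste(missing_fast, collapse = ", "),
           call. = FALSE)
    rng <- region$fast_ranges[pair$fast]
    if (any(!is.finite(unlist(rng))))
      stop("fast species with an unbounded physical range need an explicit cap ",
           "(see validate_qssa()'s `fast_caps`)", call. = FALSE)
    fast_grid <- expand.grid(lapply(rng, grid_points, g = g),
                             KEEP.OUT.ATTRS = FALSE)
    names(fast_grid) <- pair$fast
  } else {
    fast_grid <- data.frame(row.names = 1)  # single empty row: one lift per slow IC
  }

  rows <- list()
  for (i in seq_len(nrow(slow_grid))) {
    slow <- stats::setNames(as.numeric(slow_grid[i, ]), red_sp)
    red_tr <- tryCatch(
      integrate_network(pair$reduced, initial = slow, t_end = T,
                        n_out = n_out, rtol = rtol, atol = atol),
      error = function(e) if (on_failure == "skip") NULL else stop(e))
    for (j in seq_len(nrow(fast_grid))) {
      fast_vals <- if (length(pair$fast))
        stats::setNames(as.numeric(fast_grid[j, ]), pair$fast) else numeric()
      full_ic <- pair$lift(slow, fast_vals)
      full_ic <- stats::setNames(as.numeric(full_ic)[match(pair$full$species$name,
                                                           names(full_ic))],
                                 pair$full$species$name)
      feasible <- all(is.finite(full_ic)) &&
        all(full_ic >= pair$full$species$lo - 1e-9) &&
        all(full_ic <= pair$full$species$hi + 1e-9) &&
        (is.null(pair$ic_filter) || isTRUE(pair$ic_filter(full_ic)))
      if (!feasible) next
      err <- if (is.null(red_tr)) NA_real_ else tryCatch({
        full_tr <- integrate_network(pair$full, initial = pmax(full_ic, 0),
                                     t_end = T, n_out = n_out,
                                     rtol = rtol, atol = atol)
        l1_relative_error(full_tr, red_tr, pair$observable, T)
      }, error = function(e) if (on_failure == "skip") NA_real_ else stop(e))
      rows[[length(rows) + 1L]] <-
        tibble::as_tibble_row(c(as.list(slow), as.list(fast_vals),
                                list(error = err)))
    }
  }
  per_ic <- dplyr::bind_rows(rows)
  if (!nrow(per_ic) || all(is.na(per_ic$error)))
    stop("no feasible initial condition in the region", call. = FALSE)
  imax <- which.max(per_ic$error)
  out <- list(max_error = per_ic$error[imax],
              argmax = unlist(per_ic[imax, setdiff(names(per_ic), "error")]),
              per_ic = per_ic, T = T, observable = pair$observable,
              n_evaluated = sum(!is.na(per_ic$error)),
              settings = list(n_out = n_out, rtol = rtol, atol = atol,
                              grid_points_per_dim = g))
  class(out) <- "qssa_det_error"
  out
}

#' @export
print.qssa_det_error <- function(x, ...) {
  cat("<deterministic QSSA error> observable", x$observable,
      "over [0,", format(x$T), "]\n")
  cat("  max error:", format(x$max_error), "over", x$n_evaluated,
      "initial conditions\n")
  cat("  at IC:", paste(names(x$argmax), format(unname(x$argmax), digits = 4),
                        sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Stochastic reduction error: relative CV difference at steady state
#'
#' Simulates the full and the reduced model to stationarity and compares the
#' coefficient of variation of the observable. Two error measures are
#' reported: `cv_rel_error = |cv_full - cv_reduced| / cv_full` (the
#' normalized relative difference used for sweep/correlation analyses) and
#' `cv_diff = cv_full - cv_reduced` (the CV difference, i.e. the stationary
#' SD difference relative to the mean, which is the quantity with the
#' `sqrt(k_P)` small-rate scaling in the linear cascade). Standard errors
#' come from a moving-block bootstrap over the per-replicate stationary
#' samples (default block length 100).
#'
#' @param full,reduced Stochastically simulable networks, or pass a
#'   [model_pair()] as `full` (then `reduced` and `observable` are taken from
#'   it and the pair's recommended burn-in/horizon are used).
#' @param observable Compared species.
#' @param n_reps Replicates per model (one stationary sample each).
#' @param burn_in,t_end Stationarity settings, see [stationary_moments()].
#' @param seed_base Root seed; the two models use derived, distinct streams.
#' @param block_length,n_boot Block-bootstrap settings.
#' @return A `qssa_stoch_error` object.
#' @export
stochastic_cv_error <- function(full, reduced = NULL, observable = NULL,
                                n_reps = 1e4, burn_in = NULL, t_end = NULL,
                                seed_base = 1, block_length = 100, n_boot = 200) {
  if (inherits(full, "model_pair")) {
    pair <- full
    full <- pair$full
    reduced <- reduced %||% strip_prefactor(pair$reduced)
    observable <- observable %||% pair$observable
    burn_in <- burn_in %||% pair$defaults$burn_in
    t_end <- t_end %||% pair$defaults$t_end
  }
  mo_f <- stationary_moments(full, burn_in = burn_in, t_end = t_end,
                             n_reps = n_reps, seed_base = seed_base)
  mo_r <- stationary_moments(reduced, burn_in = burn_in, t_end = t_end,
                             n_reps = n_reps, seed_base = seed_base + 104729)
  xf <- mo_f$samples[, observable]
  xr <- mo_r$samples[, observable]
  if (mean(xf) <= 0 || mean(xr) <= 0)
    stop("CV undefined: observable has zero mean at stationarity", call. = FALSE)
  cv <- function(x) stats::sd(x) / mean(x)
  cvf <- cv(xf)
  cvr <- cv(xr)
  boot <- with_local_seed(seed_base + 224737, {
    vapply(seq_len(n_boot), function(b) {
      bf <- cv(resample_blocks(xf, block_length))
      br <- cv(resample_blocks(xr, block_length))
      c(rel = abs(bf - br) / bf, diff = bf - br)
    }, numeric(2))
  })
  out <- list(cv_full = cvf, cv_reduced = cvr,
              cv_rel_error = abs(cvf - cvr) / cvf,
              cv_diff = cvf - cvr,
              se_rel = stats::sd(boot["rel", ]),
              se_diff = stats::sd(boot["diff", ]),
              mean_full = mean(xf), mean_reduced = mean(xr),
              observable = observable, n_reps = n_reps,
              burn_in = burn_in, t_end = t_end, seed_base = seed_base,
              block_length = block_length, n_boot = n_boot)
  class(out) <- "qssa_stoch_error"
  out
}

#' @export
print.qssa_stoch_error <- function(x, ...) {
  cat("<stochastic QSSA error> observable", x$observable, "(", x$n_reps,
      "replicates )\n")
  cat(sprintf("  CV full %.4g, CV reduced %.4g\n", x$cv_full, x$cv_reduced))
  cat(sprintf("  relative CV error %.4g (SE %.2g); CV difference %.4g (SE %.2g)\n",
              x$cv_rel_error, x$se_rel, x$cv_diff, x$se_diff))
  invisible(x)
}

#' Analytic estimate of slow-variable drift during the initial transient
#'
#' For the genetic negative feedback loop, the relative change of the
#' repressor while the promoter relaxes to its quasi-steady state is
#' approximately `(beta_R/k_f + DA_max) / (R0 + K_D)`; the deterministic
#' QSSA is trustworthy when this is small. The promoter relaxation timescale
#' during the transient, `t_DA = 1/(k_f R0 + k_b)`, is returned alongside.
#'
#' @param beta_R Repressor degradation rate.
#' @param k_f,K_D Binding rate and dissociation constant; `k_b = K_D * k_f`
#'   unless given.
#' @param R0 Initial repressor level.
#' @param DA_max Maximum promoter activity during the transient; the default
#'   1 (the species' upper bound in the scaled model) is the conservative
#'   choice.
#' @param k_b Unbinding rate.
#' @return One-row tibble with `estimate` and `t_DA`.
#' @export
#' @examples
#' it_phase_change_estimate(beta_R = 1, k_f = 10, K_D = 10, R0 = 100)  # 0.01
it_phase_change_estimate <- function(beta_R, k_f, K_D, R0, DA_max = 1,
                                     k_b = K_D * k_f) {
  if (R0 + K_D <= 0) stop("need R0 + K_D > 0", call. = FALSE)
  tibble::tibble(estimate = (beta_R / k_f + DA_max) / (R0 + K_D),
                 t_DA = 1 / (k_f * R0 + k_b))
}

#' Measured slow-variable drift during the initial transient
#'
#' The observed counterpart of [it_phase_change_estimate()]: integrates the
#' full deterministic model across the promoter's relaxation transient and
#' reports the maximum relative excursion of the observable from its initial
#' value. The analytic estimate is derived for a repressor decaying from its
#' initial value with the promoter transiently at its maximal activity, so by
#' default the measurement silences production (mRNA starts at zero), starts
#' every fast species at its upper physical bound, and runs for three
#' promoter-relaxation timescales, after which the transient is essentially
#' complete.
#'
#' @param pair A [model_pair()] built by [make_genetic_nfl()] (any pair whose
#'   parameters include `k_f` and `k_b` works).
#' @param horizon Multiple of `t_DA` to integrate over.
#' @param n_out Grid resolution of the transient integration.
#' @param initial Optional full-model initial state; default: the declared
#'   initial values with the mRNA `M` set to zero and the fast species at
#'   their upper bounds.
#' @return One-row tibble with `measured` (max |X(t)-X(0)|/X(0)) and `t_DA`.
#' @export
measure_it_phase_change <- function(pair, horizon = 3, n_out = 400,
                                    initial = NULL) {
  p <- pair$params
  x0 <- initial %||% {
    st <- initial_state(pair$full)
    if ("M" %in% names(st)) st[["M"]] <- 0
    for (f in pair$fast) {
      hi <- pair$full$species$hi[match(f, pair$full$species$name)]
      if (is.finite(hi)) st[[f]] <- hi
    }
    st
  }
  R0 <- x0[[pair$observable]]
  t_DA <- 1 / (p$k_f * R0 + p$k_b)
  tr <- integrate_network(pair$full, initial = x0, t_end = horizon * t_DA,
                          n_out = n_out)
  dev <- max(abs(tr[[pair$observable]] - R0)) / R0
  tibble::tibble(measured = dev, t_DA = t_DA)
}

#' Analytic validity terms of the stochastic QSSA
#'
#' The stochastic QSSA is accurate when (i) the binding reactions are fast
#' compared to degradation (`k_f >> beta_R`, reported as the ratio
#' `timescale_ratio = k_f/beta_R`) and (ii) the deterministic quasi-steady
#' state closely approximates the conditional average of the fast species,
#' which requires the closure term `Var(D_A/D_T) * D_T/(R + K_D)` (equal to
#' `Var(D_A)/(R + K_D)` in the scaled model with `D_T = 1`) to be small.
#'
#' @param k_f,beta_R Binding and degradation rates.
#' @param K_D Dissociation constant.
#' @param R Slow-variable level at which the condition is evaluated.
#' @param var_DA Variance of the scaled fast species `D_A/D_T`.
#' @param D_T Total DNA.
#' @return One-row tibble with `timescale_ratio` and `closure_term`.
#' @export
stochastic_validity_terms <- function(k_f, beta_R, K_D, R, var_DA, D_T = 1) {
  if (R + K_D <= 0) stop("need R + K_D > 0", call. = FALSE)
  tibble::tibble(timescale_ratio = k_f / beta_R,
                 closure_term = var_DA * D_T / (R + K_D))
}

#' Write a per-IC error table / summary report
#'
#' @param report A `qssa_det_error` object.
#' @param path Output CSV path (`ic_<species...>,error` layout).
#' @export
write_error_report_csv <- function(report, path) {
  tb <- report$per_ic
  names(tb) <- c(paste0("ic_", setdiff(names(tb), "error")), "error")
  readr::write_csv(tb, path)
  invisible(path)
}
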