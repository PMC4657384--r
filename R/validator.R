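# The three-step validation procedure for a stochastic QSSA reduction:
#   1. stochastic simulation of the REDUCED model only,
#   2. an initial-condition region from those simulations
#      (slow: stationary mean +/- 3 SD; fast: full physical range),
#   3. the deterministic reduction error maximized over that region.
# The full stochastic model is never simulated - that is the method's point.

#' Estimate the initial-condition region from the reduced model
#'
#' Step 2 of the validation procedure. Slow intervals are the stationary
#' mean +/- 3 SD of each reduced species (one stochastic sample per
#' replicate), clipped to the species' physical range; fast species get their
#' entire physical range. For oscillatory reduced models use
#' `mode = "cycle"`: the intervals are then pooled quantiles of the species
#' over one period of stochastic simulation (a limit-cycle neighborhood
#' rather than a unimodal stationary band).
#'
#' @param reduced A stochastically simulable reduced network.
#' @param fast_ranges Named list of `c(lo, hi)` for the fast species (usually
#'   the full network's declared physical ranges; unbounded species must be
#'   capped before the scan).
#' @param n_reps Reduced-model SSA replicates.
#' @param burn_in,t_end Stationarity settings (see [stationary_moments()]).
#' @param seed_base Root seed.
#' @param grid_points_per_dim Grid resolution stored in the region.
#' @param mode `"stationary"` (mean +/- 3 SD) or `"cycle"` (quantiles over
#'   one period).
#' @param period Oscillation period (required for `mode = "cycle"`).
#' @param cycle_quantiles Pooled quantiles bounding the cycle-mode intervals.
#' @return A [ic_region()] with provenance attributes (`sd`, `sd_se`,
#'   `n_reps`, `seed_base`, `mode`).
#' @export
estimate_ic_region <- function(reduced, fast_ranges = list(), n_reps = 1000,
                               burn_in = NULL, t_end = NULL, seed_base = 1,
                               grid_points_per_dim = 5,
                               mode = c("stationary", "cycle"), period = NULL,
                               cycle_quantiles = c(0.005, 0.995)) {
  mode <- match.arg(mode)
  check_ssa_ready(reduced)
  n0 <- round(initial_state(reduced) * reduced$volume)
  sp <- reduced$species$name
  vol <- reduced$volume
  sd_se <- NULL
  if (mode == "stationary") {
    mo <- stationary_moments(reduced, initial_counts = n0, burn_in = burn_in,
                             t_end = t_end, n_reps = n_reps,
                             seed_base = seed_base)
    samples <- mo$samples
    lo <- (mo$summary$mean - 3 * mo$summary$sd) / vol
    hi <- (mo$summary$mean + 3 * mo$summary$sd) / vol
    sds <- stats::setNames(mo$summary$sd / vol, sp)
  } else {
    if (is.null(period)) stop("cycle mode needs the oscillation `period`", call. = FALSE)
    if (is.null(t_end)) t_end <- (burn_in %||% 0) + 2 * period
    rec <- seq(t_end - period, t_end, length.out = 21)
    ens <- simulate_ensemble(reduced, initial_counts = n0, record_times = rec,
                             n_reps = n_reps, seed_base = seed_base)
    samples <- as.matrix(ens[, sp])
    qs <- apply(samples, 2, stats::quantile, probs = cycle_quantiles)
    lo <- qs[1, ] / vol
    hi <- qs[2, ] / vol
    sds <- apply(samples, 2, stats::sd) / vol
  }
  lo <- pmax(lo, reduced$species$lo)
  hi <- pmin(hi, reduced$species$hi)
  slow <- stats::setNames(purrr::map2(lo, hi, c), sp)
  sd_se <- vapply(sp, function(s) {
    block_bootstrap_se(samples[, s], block_length = min(100, nrow(samples)),
                       n_boot = 100, statistic = stats::sd,
                       seed = seed_base + 7919)
  }, numeric(1)) / vol
  region <- ic_region(slow, fast_ranges, grid_points_per_dim)
  attr(region, "provenance") <- list(mode = mode, n_reps = n_reps,
                                     seed_base = seed_base, sd = sds,
                                     sd_se = sd_se, period = period)
  region
}

# Period of the reduced deterministic limit cycle, from observable peaks.
estimate_period <- function(network, observable, t_end = 80, n_out = 4000,
                            discard = 0.25) {
  tr <- integrate_network(network, t_end = t_end, n_out = n_out)
  x <- tr[[observable]]
  tt <- tr$time
  keep <- tt >= discard * t_end
  x <- x[keep]
  tt <- tt[keep]
  pk <- which(diff(sign(diff(x))) == -2) + 1
  if (length(pk) < 3) stop("could not detect a limit cycle for the period estimate",
                           call. = FALSE)
  stats::median(diff(tt[pk]))
}

#' Validate a stochastic QSSA reduction
#'
#' Runs the full three-step procedure: reduced-model stochastic simulation,
#' initial-condition region (slow: mean +/- 3 SD, or limit-cycle quantiles in
#' `region_mode = "cycle"`; fast: full physical range), then the
#' deterministic reduction error maximized over the region. The verdict is
#' `"valid"` iff the maximal error is at or below `threshold`. The default
#' threshold 0.1 is a documented convention (the underlying claim is
#' comparative, not an absolute pass line) and is always reported alongside
#' the raw error. The full stochastic model is never simulated, except
#' optionally for a short auxiliary run capping an *unbounded* fast species
#' (`fast_cap_from_full_ssa = TRUE`, cap = stationary mean + 5 SD); otherwise
#' unbounded fast species require an explicit entry in `fast_caps`.
#'
#' @param pair A [model_pair()].
#' @param threshold Pass line on the maximal deterministic reduction error.
#' @param n_reps Reduced-model SSA replicates for the region estimate.
#' @param seed Root seed for every stochastic step.
#' @param grid_points_per_dim Region grid resolution.
#' @param T,n_out,rtol,atol Deterministic-error settings
#'   (see [deterministic_qssa_error()]).
#' @param burn_in,t_end Stationarity settings for the region estimate.
#' @param region_mode `"stationary"`, `"cycle"`, or `"auto"` (cycle when the
#'   reduced deterministic model settles into detectable oscillations);
#'   `NULL` falls back to the pair's recommended mode (oscillator pairs
#'   default to `"cycle"`).
#' @param period Oscillation period for cycle mode; estimated from the
#'   reduced deterministic model when `NULL`.
#' @param fast_caps Named list of explicit upper caps for unbounded fast
#'   species.
#' @param fast_cap_from_full_ssa Permit a short full-model SSA (`n_reps/4`
#'   replicates) to cap unbounded fast species at mean + 5 SD.
#' @return A `qssa_validation` object: region, error report, threshold,
#'   verdict, and full provenance.
#' @export
#' @examples
#' \donttest{
#' v <- validate_qssa(make_genetic_nfl(k_f = 10), seed = 1,
#'                    n_reps = 200, grid_points_per_dim = 3)
#' v$verdict
#' }
validate_qssa <- function(pair, threshold = 0.1, n_reps = NULL, seed = 1,
                          grid_points_per_dim = 5, T = NULL, n_out = NULL,
                          rtol = NULL, atol = NULL,
                          burn_in = NULL, t_end = NULL,
                          region_mode = NULL,
                          period = NULL, fast_caps = list(),
                          fast_cap_from_full_ssa = FALSE) {
  region_mode <- region_mode %||% pair$defaults$region_mode %||% "stationary"
  region_mode <- match.arg(region_mode, c("stationary", "cycle", "auto"))
  stopifnot(inherits(pair, "model_pair"))
  n_reps <- n_reps %||% pair$defaults$n_reps %||% 1000
  burn_in <- burn_in %||% pair$defaults$burn_in
  t_end <- t_end %||% pair$defaults$t_end
  reduced_ssa <- strip_prefactor(pair$reduced)

  if (region_mode == "auto") {
    region_mode <- tryCatch({
      period <- period %||% estimate_period(pair$reduced, pair$observable,
                                            t_end = 4 * (t_end %||% 20))
      "cycle"
    }, error = function(e) "stationary")
  }
  if (region_mode == "cycle" && is.null(period))
    period <- estimate_period(pair$reduced, pair$observable,
                              t_end = 4 * (t_end %||% 20))

  # fast-species ranges: full physical range, capped where unbounded
  sp_full <- pair$full$species
  fast_ranges <- list()
  cap_log <- list()
  for (f in pair$fast) {
    i <- match(f, sp_full$name)
    rng <- c(sp_full$lo[i], sp_full$hi[i])
    if (!is.finite(rng[2])) {
      if (!is.null(fast_caps[[f]])) {
        rng[2] <- fast_caps[[f]]
        cap_log[[f]] <- list(source = "explicit", cap = rng[2])
      } else if (isTRUE(fast_cap_from_full_ssa)) {
        mo <- stationary_moments(pair$full, burn_in = burn_in, t_end = t_end,
                                 n_reps = max(100, ceiling(n_reps / 4)),
                                 seed_base = seed + 15485863)
        i2 <- match(f, mo$summary$species)
        rng[2] <- (mo$summary$mean[i2] + 5 * mo$summary$sd[i2]) / pair$full$volume
        cap_log[[f]] <- list(source = "full-model SSA, mean + 5 SD", cap = rng[2])
      } else {
        stop("fast species `", f, "` is unbounded: supply fast_caps$", f,
             " or allow fast_cap_from_full_ssa", call. = FALSE)
      }
    }
    fast_ranges[[f]] <- rng
  }

  region <- estimate_ic_region(reduced_ssa, fast_ranges = fast_ranges,
                               n_reps = n_reps, burn_in = burn_in,
                               t_end = t_end, seed_base = seed,
                               grid_points_per_dim = grid_points_per_dim,
                               mode = region_mode, period = period)
  det <- deterministic_qssa_error(pair, region, T = T, n_out = n_out,
                                  rtol = rtol, atol = atol)
  verdict <- if (det$max_error <= threshold) "valid" else "invalid"
  out <- list(pair_name = pair$name, region = region, det_report = det,
              threshold = threshold, verdict = verdict,
              provenance = list(seed = seed, n_reps = n_reps,
                                T = det$T, burn_in = burn_in, t_end = t_end,
                                grid_points_per_dim = grid_points_per_dim,
                                region_mode = region_mode, period = period,
                                fast_caps = cap_log,
                                rtol = rtol, atol = atol))
  class(out) <- "qssa_validation"
  out
}

#' @export
print.qssa_validation <- function(x, ...) {
  cat("<stochastic QSSA validation>", x$pair_name %||% "", "\n")
  cat("  verdict:", toupper(x$verdict), " (max deterministic error",
      format(x$det_report$max_error, digits = 4), "vs threshold",
      format(x$threshold), ")\n")
  cat("  region mode:", x$provenance$region_mode, "|", x$provenance$n_reps,
      "reduced-model replicates | seed", x$provenance$seed, "\n")
  invisible(x)
}

#' Parameter sweep of both reduction-error measures
#'
#' For each parameter value, builds the model pair and computes the
#' deterministic reduction error over a shared initial-condition region plus
#' the stochastic CV error, with seeds shared across grid points. By default
#' the region is estimated once from the first pair's reduced model and
#' reused: the sweeps of interest hold the reduction fixed (same reduced
#' model at every grid point), which is what makes the two error measures
#' comparable along the sweep. Set `shared_region = FALSE` when the sweep
#' changes the reduced model.
#'
#' @param pair_factory Function mapping one parameter value to a
#'   [model_pair()].
#' @param values Numeric vector of parameter values.
#' @param param Name used for the output column.
#' @param n_reps_region,n_reps_stoch Replicates for the region estimate and
#'   for the stochastic error.
#' @param seed Root seed shared across grid points.
#' @param grid_points_per_dim Region grid resolution.
#' @param T,n_out,rtol,atol Deterministic-error settings.
#' @param shared_region Reuse the first pair's region for all values?
#' @param fast_caps,fast_cap_from_full_ssa See [validate_qssa()].
#' @param stochastic Also compute the stochastic CV error (set `FALSE` for a
#'   deterministic-only sweep).
#' @return A tibble with one row per value: `det_error`, `stoch_error`
#'   (relative CV error), `stoch_se`, `cv_full`, `cv_reduced`, `cv_diff`,
#'   `cv_diff_se`.
#' @export
qssa_sweep <- function(pair_factory, values, param = "value",
                       n_reps_region = 1000, n_reps_stoch = 1000, seed = 1,
                       grid_points_per_dim = 5, T = NULL, n_out = NULL,
                       rtol = NULL, atol = NULL, shared_region = TRUE,
                       fast_caps = list(), fast_cap_from_full_ssa = FALSE,
                       stochastic = TRUE) {
  stopifnot(length(values) >= 1)
  region <- NULL
  rows <- purrr::map(seq_along(values), function(i) {
    pair <- pair_factory(values[i])
    if (is.null(region) || !shared_region) {
      sp_full <- pair$full$species
      fr <- list()
      for (f in pair$fast) {
        k <- match(f, sp_full$name)
        rng <- c(sp_full$lo[k], sp_full$hi[k])
        if (!is.finite(rng[2])) {
          if (is.null(fast_caps[[f]]))
            stop("fast species `", f, "` unbounded: supply fast_caps", call. = FALSE)
          rng[2] <- fast_caps[[f]]
        }
        fr[[f]] <- rng
      }
      region <<- estimate_ic_region(strip_prefactor(pair$reduced),
                                    fast_ranges = fr, n_reps = n_reps_region,
                                    burn_in = pair$defaults$burn_in,
                                    t_end = pair$defaults$t_end,
                                    seed_base = seed,
                                    grid_points_per_dim = grid_points_per_dim)
    }
    det <- deterministic_qssa_error(pair, region, T = T, n_out = n_out,
                                    rtol = rtol, atol = atol)
    row <- tibble::tibble(!!param := values[i], det_error = det$max_error)
    if (stochastic) {
      st <- stochastic_cv_error(pair, n_reps = n_reps_stoch, seed_base = seed)
      row <- dplyr::mutate(row,
        stoch_error = st$cv_rel_error, stoch_se = st$se_rel,
        cv_full = st$cv_full, cv_reduced = st$cv_reduced,
        cv_diff = st$cv_diff, cv_diff_se = st$se_diff)
    }
    row
  })
  dplyr::bind_rows(rows)
}
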