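#' Exact stochastic simulation (Gillespie direct method)
#'
#' Simulates one realization of the chemical master equation with the direct
#' method. Propensities follow the concentration-substitution rule
#' \eqn{a_j = \Omega f_j(n/\Omega)} for elementary and non-elementary rate
#' laws alike, so Hill/Michaelis–Menten reductions can be simulated directly.
#' If every propensity vanishes before `t_end` the state is absorbing and the
#' trajectory simply continues as a constant.
#'
#' @param network A [reaction_network()] without eliminated species or
#'   prefactor.
#' @param initial_counts Named nonnegative integer molecule counts; defaults
#'   to `initial concentrations * volume` (which must be integral).
#' @param t_end Final time.
#' @param seed Integer seed: identical seeds give bit-identical realizations.
#' @param record_times Times at which the state is recorded (the value
#'   immediately before or at each time); default a uniform grid of
#'   `n_out + 1` points on `[0, t_end]`.
#' @param n_out Number of grid intervals when `record_times` is `NULL`.
#' @return A `qssa_trajectory` tibble of counts.
#' @export
#' @examples
#' pair <- make_linear_cascade()
#' tr <- gillespie_run(pair$reduced, t_end = 50, seed = 1, n_out = 100)
gillespie_run <- function(network, initial_counts = NULL, t_end, seed = 1,
                          record_times = NULL, n_out = 200) {
  check_ssa_ready(network)
  n0 <- resolve_counts(network, initial_counts)
  if (is.null(record_times)) record_times <- seq(0, t_end, length.out = n_out + 1)
  record_times <- sort(as.numeric(record_times))
  m <- ssa_traj_cpp(net_ptr(network), n0, record_times, network$volume,
                    as.numeric(seed), 1)
  out <- tibble::as_tibble(as.data.frame(cbind(record_times, m)))
  names(out) <- c("time", network$species$name)
  as_qssa_trajectory(out, network$species$name)
}

check_ssa_ready <- function(network) {
  if (has_eliminated(network))
    stop("network still contains eliminated species; call apply_conservation() first",
         call. = FALSE)
  if (is_prefactored(network))
    stop("stochastic simulation of prefactored networks is not supported; ",
         "simulate strip_prefactor(network) instead", call. = FALSE)
  invisible(TRUE)
}

resolve_counts <- function(network, initial_counts) {
  n0 <- if (is.null(initial_counts)) {
    initial_state(network) * network$volume
  } else {
    stats::setNames(match_state(network, initial_counts), network$species$name)
  }
  if (any(abs(n0 - round(n0)) > 1e-6))
    stop("initial counts are not integral (concentration * volume must be an ",
         "integer for every species); adjust the volume", call. = FALSE)
  n0 <- round(n0)
  if (any(n0 < 0)) stop("negative initial counts", call. = FALSE)
  for (cl in network$conservation) {
    v <- sum(cl$coef * n0[names(cl$coef)])
    if (abs(v - cl$total * network$volume) > 1e-9)
      stop("initial counts violate a conservation law", call. = FALSE)
  }
  n0
}

#' Ensemble of stochastic realizations
#'
#' Runs `n_reps` independent replicates (per-replicate RNG streams derived
#' from `seed_base` by a counter scheme, so the ensemble is reproducible and
#' order-independent) and returns a tidy `rep, time, <species...>` tibble.
#'
#' @inheritParams gillespie_run
#' @param n_reps Number of replicates.
#' @param seed_base Integer root seed.
#' @return A `qssa_ensemble` tibble.
#' @export
simulate_ensemble <- function(network, initial_counts = NULL, record_times,
                              n_reps, seed_base = 1) {
  check_ssa_ready(network)
  n0 <- resolve_counts(network, initial_counts)
  record_times <- sort(as.numeric(record_times))
  m <- ssa_ensemble_cpp(net_ptr(network), n0, record_times, as.integer(n_reps),
                        network$volume, as.numeric(seed_base))
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- network$species$name
  out <- dplyr::bind_cols(
    tibble::tibble(rep = rep(seq_len(n_reps), each = length(record_times)),
                   time = rep(record_times, times = n_reps)),
    out)
  structure(out, class = c("qssa_ensemble", class(tibble::tibble())),
            seed_base = seed_base)
}

# Slowest first-order decay timescale declared in the network: used for the
# default burn-in (10x that timescale).
default_burn_in <- function(network) {
  ks <- c()
  for (r in network$reactions) {
    if (r$rate$kind != "mass_action") next
    if (length(r$reactants) != 1 || r$reactants[[1]] != 1) next
    s <- names(r$reactants)
    net_s <- (if (s %in% names(r$products)) r$products[[s]] else 0) - 1
    if (net_s < 0) ks <- c(ks, r$rate$k)
  }
  if (!length(ks)) return(NULL)
  10 / min(ks)
}

#' Stationary moments from an SSA ensemble
#'
#' Runs `n_reps` replicates and takes one sample per replicate at `t_end`
#' (avoiding within-trajectory autocorrelation), then summarizes mean,
#' variance, CV (= sd/mean) and Fano factor (= variance/mean) per species.
#' `burn_in` documents the time after which the reduced-model deterministic
#' transient has decayed; by default it is ten times the slowest declared
#' first-order degradation timescale and `t_end = 1.2 * burn_in`.
#'
#' @inheritParams simulate_ensemble
#' @param burn_in Transient-decay time; must be below `t_end`.
#' @param t_end Sampling time.
#' @param pool_times If `> 1`, additionally pool this many equispaced sample
#'   times between `burn_in` and `t_end` per replicate (time-average mode;
#'   samples are then autocorrelated — use the block bootstrap for errors).
#' @return A `qssa_moments` object: `$summary` tibble plus the raw stationary
#'   samples in `$samples` (one row per replicate, ordered by replicate id).
#' @export
stationary_moments <- function(network, initial_counts = NULL, burn_in = NULL,
                               t_end = NULL, n_reps = 1e4, seed_base = 1,
                               pool_times = 1) {
  check_ssa_ready(network)
  if (is.null(burn_in)) {
    burn_in <- default_burn_in(network)
    if (is.null(burn_in))
      stop("no first-order decay found to set a default burn-in; ",
           "supply `burn_in` and `t_end` explicitly", call. = FALSE)
  }
  if (is.null(t_end)) t_end <- 1.2 * burn_in
  if (!(burn_in < t_end)) stop("`burn_in` must be smaller than `t_end`", call. = FALSE)
  n0 <- resolve_counts(network, initial_counts)
  if (pool_times > 1) {
    rec <- seq(burn_in, t_end, length.out = pool_times)
    m <- ssa_ensemble_cpp(net_ptr(network), n0, rec, as.integer(n_reps),
                          network$volume, as.numeric(seed_base))
  } else {
    m <- ssa_final_cpp(net_ptr(network), n0, t_end, as.integer(n_reps),
                       network$volume, as.numeric(seed_base))
  }
  colnames(m) <- network$species$name
  mu <- colMeans(m)
  va <- apply(m, 2, stats::var)
  summary <- tibble::tibble(
    species = network$species$name,
    mean = unname(mu),
    var = unname(va),
    sd = sqrt(unname(va)),
    cv = unname(ifelse(mu > 0, sqrt(va) / mu, NA_real_)),
    fano = unname(ifelse(mu > 0, va / mu, NA_real_)))
  structure(list(summary = summary, samples = m, n_reps = n_reps,
                 burn_in = burn_in, t_end = t_end, seed_base = seed_base,
                 volume = network$volume, pooled = pool_times > 1),
            class = "qssa_moments")
}

#' @export
print.qssa_moments <- function(x, ...) {
  cat("<stationary moments>", x$n_reps, "replicates, sampled at t =",
      format(x$t_end), "\n")
  print(x$summary)
  invisible(x)
}

#' Stationary histogram of a species
#'
#' @param moments A [stationary_moments()] result.
#' @param species Species name.
#' @return Tibble `species, count, frequency`.
#' @export
stationary_histogram <- function(moments, species) {
  v <- moments$samples[, species]
  tb <- table(v)
  tibble::tibble(species = species,
                 count = as.numeric(names(tb)),
                 frequency = as.numeric(tb) / length(v))
}

#' Block-bootstrap standard error
#'
#' Standard error of a statistic of dependent samples, obtained by resampling
#' contiguous blocks of the given length with replacement (moving-block
#' bootstrap) and recomputing the statistic on each resample.
#'
#' @param samples Numeric vector (at least `block_length` long).
#' @param block_length Length of resampled blocks.
#' @param n_boot Number of bootstrap resamples.
#' @param statistic Function of a numeric vector; default the coefficient of
#'   variation `sd(x)/mean(x)`.
#' @param seed Optional integer seed (R's RNG state is restored afterwards).
#' @return The bootstrap standard error (nonnegative scalar).
#' @export
#' @examples
#' block_bootstrap_se(rpois(1000, 10), block_length = 100, seed = 1)
block_bootstrap_se <- function(samples, block_length = 100, n_boot = 200,
                               statistic = function(x) stats::sd(x) / mean(x),
                               seed = NULL) {
  n <- length(samples)
  if (block_length > n)
    stop("`block_length` exceeds the number of samples", call. = FALSE)
  reps <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      statistic(resample_blocks(samples, block_length))
    }, numeric(1))
  })
  stats::sd(reps)
}

resample_blocks <- function(samples, block_length) {
  n <- length(samples)
  n_blocks <- ceiling(n / block_length)
  starts <- sample.int(n - block_length + 1L, n_blocks, replace = TRUE)
  idx <- as.vector(outer(0:(block_length - 1L), starts, `+`))
  samples[idx[seq_len(n)]]
}

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Write an ensemble / histogram as CSV
#'
#' @param ensemble A [simulate_ensemble()] tibble (`rep,time,<species...>`).
#' @param path File path.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  readr::write_csv(tibble::as_tibble(ensemble), path)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @param histogram A [stationary_histogram()] tibble.
#' @export
write_histogram_csv <- function(histogram, path) {
  readr::write_csv(histogram, path)
  invisible(path)
}
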