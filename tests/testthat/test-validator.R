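# The three-step validation procedure and parameter sweeps.

test_that("the IC region is stationary mean +/- 3 SD, clipped and documented", {
  pair <- make_genetic_nfl(k_f = 10)
  reg <- estimate_ic_region(pair$reduced, fast_ranges = list(D_A = c(0, 1)),
                            n_reps = 1000, burn_in = 10, t_end = 12,
                            seed_base = 2)
  prov <- attr(reg, "provenance")
  mo <- stationary_moments(pair$reduced, burn_in = 10, t_end = 12,
                           n_reps = 1000, seed_base = 2)
  m <- mo$summary$mean[mo$summary$species == "R"]
  s <- mo$summary$sd[mo$summary$species == "R"]
  expect_equal(reg$slow_intervals$R, c(m - 3 * s, m + 3 * s))
  expect_equal(reg$fast_ranges$D_A, c(0, 1))
  expect_true(all(c("sd", "sd_se", "n_reps", "mode") %in% names(prov)))
  # the region contains the reduced model's deterministic fixed point
  ss <- steady_state(pair$reduced)
  for (s2 in c("M", "R")) {
    iv <- reg$slow_intervals[[s2]]
    expect_true(ss[[s2]] >= iv[1] && ss[[s2]] <= iv[2])
  }
})

test_that("a degenerate reduced model yields single-point intervals", {
  # no reactions: SD = 0, the interval collapses onto the initial state
  frozen <- reaction_network(species = species_spec("X", "slow", 7),
                             reactions = list(), name = "frozen")
  reg <- estimate_ic_region(frozen, n_reps = 50, burn_in = 1, t_end = 2,
                            seed_base = 1)
  expect_equal(reg$slow_intervals$X, c(7, 7))
})

test_that("an identical full/reduced pair validates at any threshold", {
  pair <- identity_pair()
  v <- validate_qssa(pair, threshold = 1e-6, n_reps = 200, seed = 1,
                     burn_in = 8, t_end = 10, grid_points_per_dim = 3, T = 5,
                     n_out = 200)
  expect_equal(v$verdict, "valid")
  expect_lt(v$det_report$max_error, 1e-10)
})

test_that("validation reports are deterministic given identical settings", {
  v1 <- validate_qssa(make_genetic_nfl(k_f = 1), n_reps = 300, seed = 5,
                      grid_points_per_dim = 3, n_out = 300)
  v2 <- validate_qssa(make_genetic_nfl(k_f = 1), n_reps = 300, seed = 5,
                      grid_points_per_dim = 3, n_out = 300)
  expect_identical(glance(v1), glance(v2))
  expect_identical(v1$det_report$per_ic, v2$det_report$per_ic)
})

test_that("unbounded fast species demand a cap, explicit or from a short full run", {
  pair <- make_linear_cascade()
  expect_error(validate_qssa(pair, n_reps = 100, seed = 1), "unbounded")
  v <- validate_qssa(pair, n_reps = 200, seed = 1, grid_points_per_dim = 3,
                     T = 30, n_out = 300, fast_caps = list(M = 30))
  expect_equal(v$provenance$fast_caps$M$source, "explicit")
  expect_equal(v$region$fast_ranges$M[2], 30)
  v2 <- validate_qssa(pair, n_reps = 200, seed = 1, grid_points_per_dim = 3,
                      T = 30, n_out = 300, fast_cap_from_full_ssa = TRUE)
  expect_match(v2$provenance$fast_caps$M$source, "full-model")
  # mean + 5 SD of Poisson(10) is well below 30
  expect_lt(v2$region$fast_ranges$M[2], 30)
  expect_gt(v2$region$fast_ranges$M[2], 10)
})

test_that("a single-point sweep equals the direct metric calls", {
  tb <- qssa_sweep(function(v) make_genetic_nfl(k_f = v), 1, param = "k_f",
                   n_reps_region = 500, n_reps_stoch = 500, seed = 3,
                   grid_points_per_dim = 3, n_out = 300)
  expect_equal(nrow(tb), 1)
  pair <- make_genetic_nfl(k_f = 1)
  reg <- estimate_ic_region(pair$reduced, fast_ranges = list(D_A = c(0, 1)),
                            n_reps = 500, burn_in = pair$defaults$burn_in,
                            t_end = pair$defaults$t_end, seed_base = 3,
                            grid_points_per_dim = 3)
  det <- deterministic_qssa_error(pair, reg, n_out = 300)
  st <- stochastic_cv_error(pair, n_reps = 500, seed_base = 3)
  expect_equal(tb$det_error, det$max_error)
  expect_equal(tb$stoch_error, st$cv_rel_error)
  expect_equal(tb$cv_full, st$cv_full)
})

test_that("plots build without error", {
  pair <- make_genetic_nfl()
  tr <- integrate_network(pair$reduced, t_end = 5, n_out = 50)
  expect_s3_class(autoplot(tr), "ggplot")
  ens <- simulate_ensemble(pair$reduced, record_times = 0:3, n_reps = 5,
                           seed_base = 1)
  expect_s3_class(autoplot(ens, species = "R"), "ggplot")
  reg <- ic_region(list(M = c(40, 60), R = c(40, 60)), list(D_A = c(0, 1)),
                   grid_points_per_dim = 2)
  rep <- deterministic_qssa_error(pair, reg, T = 2, n_out = 100)
  expect_s3_class(autoplot(rep), "ggplot")
  sw <- tibble::tibble(k_f = c(1, 10), det_error = c(0.1, 0.01),
                       stoch_error = c(0.3, 0.1))
  expect_s3_class(plot_sweep(sw, "k_f"), "ggplot")
})
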