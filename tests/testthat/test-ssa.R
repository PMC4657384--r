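# Exact stochastic simulation, stationary moments and the block bootstrap.

test_that("a network with no firing reactions stays constant (absorbing)", {
  net <- decay_net(1, x0 = 0)   # nothing to decay: all propensities zero
  tr <- gillespie_run(net, t_end = 5, seed = 1, n_out = 20)
  expect_true(all(tr$X == 0))
})

test_that("linear death process matches its closed-form mean", {
  net <- decay_net(beta = 1, x0 = 1000)
  ens <- simulate_ensemble(net, record_times = 1, n_reps = 1000, seed_base = 11)
  m <- mean(ens$X)
  target <- 1000 * exp(-1)
  se <- stats::sd(ens$X) / sqrt(1000)
  expect_within_se(m, target, se)
})

test_that("birth-death stationary distribution is Poisson", {
  net <- birth_death_net(10, 1, x0 = 10)
  mo <- stationary_moments(net, burn_in = 8, t_end = 10, n_reps = 1e4,
                           seed_base = 5)
  x <- mo$samples[, "X"]
  # chi-square goodness of fit against Poisson(10), tail bins pooled
  ks <- 0:25
  p <- stats::dpois(ks, 10)
  p[length(p)] <- p[length(p)] + stats::ppois(25, 10, lower.tail = FALSE)
  obs <- tabulate(pmin(x, 25) + 1, nbins = 26)
  keep <- p * length(x) >= 5
  chi <- sum((obs[keep] - length(x) * p[keep])^2 / (length(x) * p[keep]))
  pval <- stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
  expect_equal(mo$summary$fano[1], 1, tolerance = 0.05)
})

test_that("mean first-reaction time of the direct method equals 1/a0", {
  # single zeroth-order reaction with propensity 2: first event ~ Exp(2)
  net <- birth_death_net(alpha = 2, beta = 1e-12, x0 = 0)
  waits <- vapply(1:1000, function(r) {
    tr <- gillespie_run(net, t_end = 10, seed = r,
                        record_times = seq(0, 10, by = 0.05))
    tr$time[match(TRUE, tr$X > 0)]
  }, numeric(1))
  expect_within_se(mean(waits, na.rm = TRUE), 1 / 2,
                   stats::sd(waits, na.rm = TRUE) / sqrt(sum(!is.na(waits))))
})

test_that("identical seeds give bit-identical trajectories and moments", {
  pair <- make_genetic_nfl(k_f = 1)
  a <- gillespie_run(pair$full, t_end = 5, seed = 42, n_out = 50)
  b <- gillespie_run(pair$full, t_end = 5, seed = 42, n_out = 50)
  expect_identical(a, b)
  m1 <- stationary_moments(pair$reduced, burn_in = 2, t_end = 3, n_reps = 200,
                           seed_base = 9)
  m2 <- stationary_moments(pair$reduced, burn_in = 2, t_end = 3, n_reps = 200,
                           seed_base = 9)
  expect_identical(m1$summary, m2$summary)
  c2 <- gillespie_run(pair$full, t_end = 5, seed = 43, n_out = 50)
  expect_false(identical(a, c2))
})

test_that("SSA ensemble mean converges to the ODE solution as volume grows", {
  p <- list(alpha_M = 10, alpha_P = 1, k_M = 1, k_P = 0.1)
  hand <- cascade_mean_hand(p, M0 = 2, P0 = 0, t = 2)
  for (om in c(1, 10, 100)) {
    pair <- make_linear_cascade(M0 = 2, P0 = 0, volume = om)
    ens <- simulate_ensemble(pair$full, record_times = 2,
                             n_reps = 400, seed_base = om)
    for (s in c("M", "P")) {
      conc <- ens[[s]] / om
      expect_within_se(mean(conc), hand[[s]],
                       max(stats::sd(conc) / sqrt(400), 1e-3), n_se = 4)
    }
  }
})

test_that("promoter-scaled model: more DNA copies means smaller promoter noise", {
  vars <- vapply(c(1, 10), function(DT) {
    pair <- make_genetic_nfl(k_f = 10, D_T = DT)
    mo <- stationary_moments(pair$full, burn_in = 10, t_end = 12,
                             n_reps = 2000, seed_base = 3)
    mo$summary$var[mo$summary$species == "D_A"] / DT^2  # Var(D_A / D_T)
  }, numeric(1))
  expect_lt(vars[2], vars[1])
})

test_that("block bootstrap reduces to the right limits", {
  expect_equal(block_bootstrap_se(rep(5, 500), block_length = 100, seed = 1), 0)
  expect_error(block_bootstrap_se(1:10, block_length = 100), "block_length")

  set.seed(2)
  x <- stats::rnorm(1e4, mean = 50, sd = 4)
  se_boot <- block_bootstrap_se(x, block_length = 1, n_boot = 400,
                                statistic = mean, seed = 7)
  expect_lt(abs(se_boot - stats::sd(x) / 100) / (stats::sd(x) / 100), 0.1)
  # blocks of 100 on iid data agree with the classical answer too
  se_blk <- block_bootstrap_se(x, block_length = 100, n_boot = 400,
                               statistic = mean, seed = 8)
  expect_lt(abs(se_blk - stats::sd(x) / 100) / (stats::sd(x) / 100), 0.15)
})

test_that("ensembles and histograms export to tidy CSV", {
  net <- birth_death_net(5, 1, x0 = 5)
  ens <- simulate_ensemble(net, record_times = c(1, 2), n_reps = 5, seed_base = 1)
  expect_named(ens, c("rep", "time", "X"))
  expect_equal(nrow(ens), 10)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ensemble_csv(ens, f)
  expect_equal(nrow(readr::read_csv(f, show_col_types = FALSE)), 10)

  mo <- stationary_moments(net, burn_in = 5, t_end = 6, n_reps = 500, seed_base = 2)
  h <- stationary_histogram(mo, "X")
  expect_equal(sum(h$frequency), 1)
  expect_true(all(h$count == round(h$count)))
})
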