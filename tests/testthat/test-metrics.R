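# Reduction-error metrics and the analytic validity estimates.

test_that("identical full and reduced models give zero scan error", {
  pair <- identity_pair()
  reg <- ic_region(list(X = c(5, 15)), grid_points_per_dim = 3)
  rep <- deterministic_qssa_error(pair, reg, T = 5, n_out = 200)
  expect_equal(rep$max_error, 0, tolerance = 1e-10)
  expect_equal(nrow(rep$per_ic), 3)
})

test_that("a single-point region reduces to the plain trajectory error", {
  pair <- make_genetic_nfl(k_f = 1)
  reg <- ic_region(list(M = c(80, 80), R = c(60, 60)), list(D_A = c(1, 1)))
  rep <- deterministic_qssa_error(pair, reg, T = 5, n_out = 500)
  full_tr <- integrate_network(pair$full, initial = c(M = 80, R = 60, D_A = 1),
                               t_end = 5, n_out = 500)
  red_tr <- integrate_network(pair$reduced, initial = c(M = 80, R = 60),
                              t_end = 5, n_out = 500)
  expect_equal(rep$max_error, l1_relative_error(full_tr, red_tr, "R", 5),
               tolerance = 1e-12)
  expect_equal(nrow(rep$per_ic), 1)
})

test_that("the scan error grows as the promoter kinetics slow down", {
  reg <- ic_region(list(M = c(30, 70), R = c(30, 70)), list(D_A = c(0, 1)),
                   grid_points_per_dim = 3)
  slow <- deterministic_qssa_error(make_genetic_nfl(k_f = 0.1), reg,
                                   T = 5, n_out = 500)
  fast <- deterministic_qssa_error(make_genetic_nfl(k_f = 10), reg,
                                   T = 5, n_out = 500)
  expect_gt(slow$max_error, 10 * fast$max_error)
  expect_equal(slow$argmax[["D_A"]], 1)   # worst case: promoter fully active
})

test_that("infeasible grid points are skipped, not evaluated", {
  pair <- make_coop_enzyme()
  reg <- ic_region(list(S = c(449, 449)),
                   list(E_S = c(0, 1), E_S2 = c(0, 1)), grid_points_per_dim = 3)
  rep <- deterministic_qssa_error(pair, reg, T = 100, n_out = 200)
  # of the 9 (E_S, E_S2) combinations, 3 violate E_S + E_S2 <= 1
  expect_equal(nrow(rep$per_ic), 6)
})

test_that("stochastic CV error of a model against itself is indistinguishable from zero", {
  net <- birth_death_net(20, 1, x0 = 20)
  st <- stochastic_cv_error(net, birth_death_net(20, 1, x0 = 20), "X",
                            n_reps = 2000, burn_in = 8, t_end = 10,
                            seed_base = 3)
  expect_lt(st$cv_rel_error, 3 * st$se_rel + 1e-12)
})

test_that("cascade CV error matches the closed-form prediction", {
  pair <- make_linear_cascade()
  st <- stochastic_cv_error(pair, n_reps = 4000, seed_base = 17)
  cf <- closed_form_variances()
  target_rel <- 1 - 1 / sqrt(cf$var_full / cf$mean_P)   # 1 - 1/sqrt(1.909...)
  expect_within_se(st$cv_rel_error, target_rel, st$se_rel)
  expect_within_se(st$cv_diff, cf$rel_error, st$se_diff)
})

test_that("the transient-drift estimate reproduces the worked values", {
  e1 <- it_phase_change_estimate(beta_R = 1, k_f = 10, K_D = 10, R0 = 100,
                                 DA_max = 1)
  expect_equal(e1$estimate, 1.1 / 110)     # 0.01, exactly
  expect_equal(e1$t_DA, 1 / (10 * 100 + 100))
  e2 <- it_phase_change_estimate(beta_R = 1, k_f = 0.1, K_D = 10, R0 = 100)
  expect_equal(e2$estimate, 11 / 110)      # 0.1: tenfold worse
  # monotone decreasing in R0 and K_D
  ests_R <- vapply(c(50, 100, 200), function(R0)
    it_phase_change_estimate(1, 1, 10, R0)$estimate, numeric(1))
  ests_K <- vapply(c(5, 10, 50), function(K)
    it_phase_change_estimate(1, 1, K, 100)$estimate, numeric(1))
  expect_true(all(diff(ests_R) < 0))
  expect_true(all(diff(ests_K) < 0))
})

test_that("stochastic validity terms follow the closure formula", {
  expect_equal(stochastic_validity_terms(10, 1, 10, R = 100, var_DA = 0)$closure_term, 0)
  t2 <- stochastic_validity_terms(10, 1, 10, R = 100, var_DA = 0.25)
  expect_equal(t2$closure_term, 0.25 / 110)
  expect_equal(t2$timescale_ratio, 10)
  # decreasing in K_D at fixed variance and R
  cls <- vapply(c(1, 10, 100), function(K)
    stochastic_validity_terms(10, 1, K, 100, 0.25)$closure_term, numeric(1))
  expect_true(all(diff(cls) < 0))
  # with D_T copies the closure term uses Var(D_A/D_T) * D_T
  expect_equal(stochastic_validity_terms(10, 1, 10, 100, 0.02, D_T = 5)$closure_term,
               0.02 * 5 / 110)
})

test_that("tidiers return tibbles with the reported quantities", {
  pair <- identity_pair()
  reg <- ic_region(list(X = c(5, 15)), grid_points_per_dim = 3)
  rep <- deterministic_qssa_error(pair, reg, T = 5, n_out = 100)
  expect_named(glance(rep), c("max_error", "observable", "T", "n_ic"))
  expect_equal(tidy(rep), rep$per_ic)

  st <- stochastic_cv_error(birth_death_net(10, 1, 10), birth_death_net(10, 1, 10),
                            "X", n_reps = 300, burn_in = 8, t_end = 10,
                            seed_base = 1)
  expect_true(all(c("cv_full", "cv_rel_error", "cv_diff") %in% names(glance(st))))
})
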