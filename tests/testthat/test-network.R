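# Network construction, rate-law evaluation, propensities and conservation.

test_that("rate-law grammar admits arithmetic and rejects everything else", {
  expect_s3_class(rate_expr(~ a * K / (K + R), params = c(a = 1, K = 2)), "rate_law")
  expect_s3_class(rate_expr(~ sqrt((D - T)^2 + 4 * D), params = c(D = 1)), "rate_law")
  expect_error(rate_expr(~ exp(R), params = c()), "grammar")
  expect_error(rate_expr(~ ifelse(R > 1, 1, 0)), "grammar")
  expect_error(rate_expr("sin(R)"), "grammar")
  expect_error(mass_action(-1), "positive")
  expect_error(mass_action(c(1, 2)), "positive")
})

test_that("deterministic RHS matches direct evaluation of the reduced model", {
  pair <- make_genetic_nfl(K_D = 10, alpha_M = 300, beta_M = 1)
  # transcription at R = 0 is alpha_M, minus beta_M * M
  d <- evaluate_rhs(pair$reduced, c(M = 100, R = 0))
  expect_equal(unname(d["M"]), 300 * (10 / 10) - 100)
  # at an exact fixed point all derivatives vanish
  ss <- steady_state(pair$reduced)
  expect_equal(max(abs(evaluate_rhs(pair$reduced, ss))), 0, tolerance = 1e-9)
})

test_that("full-model RHS vanishes at the independently located steady state", {
  p <- nfl_params(k_f = 10)
  ss <- nfl_steady_hand(p)
  pair <- make_genetic_nfl(k_f = 10)
  res <- evaluate_rhs(pair$full, c(M = ss[1], R = ss[2], D_A = ss[3]))
  expect_lt(max(abs(res)), 1e-10 * max(1, max(abs(ss))))
})

test_that("RHS errors on unknown species and on negative rate values", {
  pair <- make_genetic_nfl()
  expect_error(evaluate_rhs(pair$reduced, c(M = 1, Q = 2)), "unknown|missing")
  bad <- reaction_network(
    species = species_spec("X", "slow", 1),
    reactions = list(reaction("r", NULL, c(X = 1),
                              rate_expr(~ 1 - X, params = c()))))
  expect_error(evaluate_rhs(bad, c(X = 5)), "negative")
})

test_that("propensities follow the volume-substitution rule for all rate laws", {
  # mass action k * R * D_A at unit volume
  net <- reaction_network(
    species = list(species_spec("R", "slow", 100), species_spec("D_A", "fast", 1, 0, 1)),
    reactions = list(reaction("bind", c(R = 1, D_A = 1), NULL, mass_action(10))))
  expect_equal(unname(propensities(net, c(R = 100, D_A = 1))), 1000)

  # Hill propensity evaluated at counts
  hill <- reaction_network(
    species = species_spec("R", "slow", 10),
    reactions = list(reaction("tx", NULL, NULL,
                              rate_expr(~ aM * K / (K + R), params = c(aM = 300, K = 10)))))
  expect_equal(unname(propensities(hill, c(R = 10))), 150)

  # Omega = 2: a = Omega * k * (nX/Omega) * (nY/Omega)
  two <- reaction_network(
    species = list(species_spec("X", "slow", 2), species_spec("Y", "slow", 3)),
    reactions = list(reaction("r", c(X = 1, Y = 1), NULL, mass_action(1))),
    volume = 2)
  expect_equal(unname(propensities(two, c(X = 4, Y = 6))), 2 * (4 / 2) * (6 / 2))
  expect_error(propensities(two, c(X = -1, Y = 6)), "negative")
})

test_that("conservation elimination substitutes totals into rate laws", {
  # k_b * D_R becomes k_b * (1 - D_A) after eliminating D_R
  p <- nfl_params(k_f = 10)
  pair <- make_genetic_nfl(k_f = 10)
  st <- c(M = 50, R = 20, D_A = 0.3)
  d <- evaluate_rhs(pair$full, st)
  expect_equal(unname(d["D_A"]),
               -p$k_f * 20 * 0.3 + p$k_b * (1 - 0.3), tolerance = 1e-12)
  # a network with no conservation laws is returned unchanged
  net <- birth_death_net(1, 1)
  expect_identical(apply_conservation(net), net)
})

test_that("eliminating a conserved species preserves the dynamics", {
  # brute-force: integrate the UNREDUCED composite mechanism by hand
  # (7 species incl. D_R2 and E) and compare the retained coordinates with
  # the package network in which D_R2 and E were eliminated algebraically.
  prm <- list(aM = 50, bM = 1, kR = 1, k1 = 1e-5, km1 = 10, k2 = 100, km2 = 10,
              k3 = 0.1, km3 = 10, k4 = 1, DT = 0.01, ET = 1)
  rhs_hand <- function(t, y, p) {
    M <- y[1]; R <- y[2]; D <- y[3]; DR <- y[4]; ER <- y[5]; DR2 <- y[6]; E <- y[7]
    dM <- p$aM * (D + DR) - p$bM * M
    dR <- p$kR * M - p$k1 * R * D + p$km1 * DR - p$k2 * R * DR + p$km2 * DR2 -
      p$k3 * E * R + p$km3 * ER
    dD <- -p$k1 * R * D + p$km1 * DR
    dDR <- p$k1 * R * D - p$km1 * DR - p$k2 * R * DR + p$km2 * DR2
    dER <- p$k3 * E * R - p$km3 * ER - p$k4 * ER
    dDR2 <- p$k2 * R * DR - p$km2 * DR2
    dE <- -p$k3 * E * R + p$km3 * ER + p$k4 * ER
    list(c(dM, dR, dD, dDR, dER, dDR2, dE))
  }
  y0 <- c(M = 0, R = 0, D = 0, DR = 0, ER = 0, DR2 = 0.01, E = 1)
  times <- seq(0, 50, length.out = 101)
  ref <- deSolve::ode(y0, times, rhs_hand, prm, rtol = 1e-10, atol = 1e-12)

  full <- make_composite_nfl("full")
  tr <- integrate_network(full, t_end = 50, n_out = 100, rtol = 1e-10, atol = 1e-12)
  for (s in c("M", "R", "D", "D_R", "E_R")) {
    s_ref <- c(M = "M", R = "R", D = "D", D_R = "DR", E_R = "ER")[[s]]
    expect_lt(max(abs(tr[[s]] - ref[, s_ref])), 1e-8)
  }
})

test_that("conserved totals hold along ODE and SSA trajectories", {
  pair <- make_genetic_nfl(k_f = 10)
  tr <- integrate_network(pair$full, t_end = 10, n_out = 200)
  # D_A + D_R = 1 with D_R eliminated: D_A must stay within [0, 1]
  expect_true(all(tr$D_A >= -1e-8 & tr$D_A <= 1 + 1e-8))
  ssa <- gillespie_run(pair$full, t_end = 10, seed = 4, n_out = 100)
  expect_true(all(ssa$D_A %in% c(0, 1)))
  expect_true(all(as.matrix(ssa[, -1]) >= 0))
})

test_that("invalid networks are rejected at construction", {
  expect_error(reaction_network(
    species = species_spec("X", "slow", 1),
    reactions = list(reaction("r", c(Y = 1), NULL, mass_action(1)))),
    "undeclared")
  expect_error(species_spec("X", "slow", initial = -1), "nonnegative")
  expect_error(species_spec("X", "slow", initial = 5, lo = 0, hi = 2), "range")
  # conservation total inconsistent with the initial state
  expect_error(reaction_network(
    species = list(species_spec("A", "fast", 0.5, 0, 1),
                   species_spec("B", "eliminated", 0.2, 0, 1)),
    reactions = list(reaction("r", c(A = 1), c(B = 1), mass_action(1))),
    conservation = conservation_law(c(A = 1, B = 1), 1)),
    "conservation")
  # reaction breaking a conserved total
  expect_error(reaction_network(
    species = list(species_spec("A", "fast", 0.5, 0, 1),
                   species_spec("B", "eliminated", 0.5, 0, 1)),
    reactions = list(reaction("r", c(A = 1), NULL, mass_action(1))),
    conservation = conservation_law(c(A = 1, B = 1), 1)),
    "breaks")
})

test_that("prefactored networks integrate but refuse stochastic simulation", {
  pp <- make_oscillator("pqssa")
  expect_true(stoqssa:::is_prefactored(pp$reduced))
  expect_error(gillespie_run(pp$reduced, t_end = 1, seed = 1), "prefactor")
  stripped <- strip_prefactor(pp$reduced)
  expect_false(stoqssa:::is_prefactored(stripped))
  # the prefactor divides dR/dt: compare against the unprefactored RHS
  st <- c(M = 10, P = 10, R = 5)
  d_pref <- evaluate_rhs(pp$reduced, st)
  d_raw <- evaluate_rhs(stripped, st)
  K_d <- pp$params$K_d; D_T <- pp$params$D_T
  pR <- 1 + D_T * K_d / ((5 + K_d)^2)
  expect_equal(unname(d_pref["R"]), unname(d_raw["R"]) / pR, tolerance = 1e-12)
  expect_equal(unname(d_pref["M"]), unname(d_raw["M"]))
})
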