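# Independent oracles and small fixture networks, built in code.
# These deliberately do NOT use the package's evaluation machinery: the
# right-hand sides are written out by hand and integrated/solved with
# generic numerical tools, so they can check the package implementation.

# Fixed-step classical RK4 integrator for a hand-written RHS.
rk4_integrate <- function(f, y0, t_end, n_steps) {
  h <- t_end / n_steps
  y <- y0
  out <- matrix(NA_real_, n_steps + 1, length(y0))
  out[1, ] <- y0
  t <- 0
  for (i in seq_len(n_steps)) {
    k1 <- f(t, y)
    k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2)
    k4 <- f(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
    out[i + 1, ] <- y
  }
  out
}

# Hand-written RHS of the genetic negative feedback loop (promoter state
# eliminated through D_A + D_R = 1), state (M, R, D_A).
nfl_rhs_hand <- function(p) {
  function(t, y) {
    M <- y[1]; R <- y[2]; DA <- y[3]
    c(p$alpha_M * DA - p$beta_M * M,
      p$alpha_R * M - p$beta_R * R - p$k_f * R * DA + p$k_b * (1 - DA),
      -p$k_f * R * DA + p$k_b * (1 - DA))
  }
}

nfl_params <- function(k_f = 10, K_D = 10) {
  list(alpha_M = 300, beta_M = 1, alpha_R = 1, beta_R = 1,
       k_f = k_f, k_b = K_D * k_f, K_D = K_D)
}

# Steady state of the hand-written system by an independent root finder.
nfl_steady_hand <- function(p, guess = c(50, 50, 0.2)) {
  f <- function(y) nfl_rhs_hand(p)(0, y)
  as.numeric(pracma::fsolve(f, guess)$x)
}

# Simple one-species birth-death network: 0 -> X (alpha), X -> 0 (beta).
birth_death_net <- function(alpha, beta, x0 = 0, volume = 1) {
  reaction_network(
    species = species_spec("X", "slow", x0),
    reactions = list(
      reaction("birth", NULL, c(X = 1), mass_action(alpha)),
      reaction("death", c(X = 1), NULL, mass_action(beta))),
    volume = volume, name = "birth_death")
}

decay_net <- function(beta = 1, x0 = 1000) {
  reaction_network(
    species = species_spec("X", "slow", x0),
    reactions = list(reaction("death", c(X = 1), NULL, mass_action(beta))),
    name = "decay")
}

# Two-species linear cascade means, exact: M'(t) and E[P(t)] solve the same
# linear ODEs as the deterministic model.
cascade_mean_hand <- function(p, M0, P0, t) {
  Mss <- p$alpha_M / p$k_M
  M <- Mss + (M0 - Mss) * exp(-p$k_M * t)
  # dP/dt = aP*M - kP*P, solve with integrating factor
  A <- p$alpha_P * Mss / p$k_P
  B <- p$alpha_P * (M0 - Mss) / (p$k_P - p$k_M)
  Cc <- P0 - A - B
  P <- A + B * exp(-p$k_M * t) + Cc * exp(-p$k_P * t)
  list(M = M, P = P)
}

# A pair whose "reduced" model IS the full model (zero reduction error).
identity_pair <- function() {
  net <- birth_death_net(10, 1, x0 = 10)
  net2 <- birth_death_net(10, 1, x0 = 10)
  model_pair(net, net2, observable = "X")
}

expect_within_se <- function(value, target, se, n_se = 3) {
  expect_lt(abs(value - target), n_se * se)
}
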