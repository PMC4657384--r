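# Built-in model catalog: five full/reduced systems exercising the standard,
# total, prefactor and composite QSS reductions. Each constructor returns a
# model_pair whose full network is built from the elementary mechanism with
# conserved totals eliminated algebraically, so the same definition drives
# ODE integration and stochastic simulation.

#' Genetic negative feedback loop (two-state promoter)
#'
#' mRNA `M` is transcribed from active DNA `D_A`, translated into a repressor
#' `R` which reversibly binds the promoter (`D_A + D_R = 1`, concentrations
#' scaled by total DNA). The standard QSSA eliminates `D_A` through the Hill
#' function `D_A(R) = K_D/(K_D + R)`, giving the reduced model with
#' transcription rate `alpha_M * K_D/(K_D + R)`. Different `k_f` at fixed
#' `K_D = k_b/k_f` give the identical reduction, which is what makes the model
#' the canonical probe of stochastic-QSSA validity. Time unit: hours.
#'
#' @param k_f,K_D Repressor-DNA binding rate and dissociation constant;
#'   `k_b` defaults to `K_D * k_f` (supplying an inconsistent `k_b` is an error).
#' @param k_b Unbinding rate.
#' @param alpha_M,beta_M Transcription and mRNA degradation rates.
#' @param alpha_R,beta_R Translation and repressor degradation rates.
#' @param M0,R0,DA0 Initial values.
#' @param D_T Total DNA copy number for the unscaled variant. The default 1
#'   is the scaled model in which `D_A` is a binary 0/1 variable at unit
#'   volume; for `D_T > 1` the binding rate per DNA copy is `k_f / D_T` and
#'   transcription is `alpha_M / D_T` per active copy, so that the
#'   deterministic dynamics of `(M, R, D_A/D_T)` are unchanged.
#' @param volume System volume \eqn{\Omega}.
#' @return A [model_pair()] with observable `R`.
#' @export
#' @examples
#' pair <- make_genetic_nfl(k_f = 10)
#' pair$qss_map(c(M = 100, R = 10))   # D_A = 0.5 at R = K_D
make_genetic_nfl <- function(k_f = 10, K_D = 10, k_b = K_D * k_f,
                             alpha_M = 300, beta_M = 1, alpha_R = 1, beta_R = 1,
                             M0 = 100, R0 = 100, DA0 = 0, D_T = 1, volume = 1) {
  check_positive(k_f = k_f, K_D = K_D, k_b = k_b, alpha_M = alpha_M,
                 beta_M = beta_M, alpha_R = alpha_R, beta_R = beta_R, D_T = D_T)
  if (abs(k_b / k_f - K_D) > 1e-8 * K_D)
    stop("inconsistent parameters: K_D must equal k_b/k_f", call. = FALSE)

  full <- reaction_network(
    species = list(
      species_spec("M", "slow", M0),
      species_spec("R", "slow", R0),
      species_spec("D_A", "fast", DA0, 0, D_T),
      species_spec("D_R", "eliminated", D_T - DA0, 0, D_T)),
    reactions = list(
      reaction("transcription", c(D_A = 1), c(D_A = 1, M = 1), mass_action(alpha_M / D_T)),
      reaction("mRNA_decay", c(M = 1), NULL, mass_action(beta_M)),
      reaction("translation", c(M = 1), c(M = 1, R = 1), mass_action(alpha_R)),
      reaction("repressor_decay", c(R = 1), NULL, mass_action(beta_R)),
      reaction("binding", c(R = 1, D_A = 1), c(D_R = 1), mass_action(k_f / D_T)),
      reaction("unbinding", c(D_R = 1), c(R = 1, D_A = 1), mass_action(k_b))),
    conservation = conservation_law(c(D_A = 1, D_R = 1), D_T),
    volume = volume, name = "genetic_nfl_full")
  full <- apply_conservation(full)

  reduced <- reaction_network(
    species = list(species_spec("M", "slow", M0), species_spec("R", "slow", R0)),
    reactions = list(
      reaction("transcription", NULL, c(M = 1),
               rate_expr(~ alpha_M * K_D / (K_D + R),
                         params = c(alpha_M = alpha_M, K_D = K_D))),
      reaction("mRNA_decay", c(M = 1), NULL, mass_action(beta_M)),
      reaction("translation", c(M = 1), c(M = 1, R = 1), mass_action(alpha_R)),
      reaction("repressor_decay", c(R = 1), NULL, mass_action(beta_R))),
    volume = volume, name = "genetic_nfl_reduced")

  model_pair(
    full, reduced, observable = "R",
    qss_map = function(slow) c(D_A = D_T * K_D / (K_D + slow[["R"]])),
    name = "genetic_nfl",
    params = list(k_f = k_f, k_b = k_b, K_D = K_D, alpha_M = alpha_M,
                  beta_M = beta_M, alpha_R = alpha_R, beta_R = beta_R, D_T = D_T),
    defaults = list(T = 5, n_out = 2000,
                    burn_in = 10 / min(beta_M, beta_R),
                    t_end = 12 / min(beta_M, beta_R), n_reps = 1e4))
}

#' Cooperative enzyme kinetics
#'
#' Substrate `S` binds enzyme `E` sequentially (`E_S`, then `E_S2`), and the
#' doubly bound complex releases product. Concentrations are scaled by total
#' enzyme (`E + E_S + E_S2 = 1`). Under `K_m1 >> K_m2` the QSSA collapses
#' consumption into the Hill term `k_p S^2/(K_m^2 + S^2)` with
#' `K_m^2 = K_m1 * K_m2`. Changing the unbinding rates at fixed `K_m1`,
#' `K_m2` leaves the reduction untouched. Time unit: seconds.
#'
#' @param k_in Substrate influx rate.
#' @param k_minus1,k_minus2 Unbinding rates of the first and second complex.
#' @param k_p Catalytic rate.
#' @param K_m1,K_m2 Michaelis constants `k_minus1/k_1` and
#'   `(k_minus2 + k_p)/k_2`; the binding rates are derived from them.
#' @param S0,ES0,ES20 Initial values.
#' @param volume System volume.
#' @return A [model_pair()] with observable `S`.
#' @export
make_coop_enzyme <- function(k_in = 0.5, k_minus1 = 100, k_minus2 = 100,
                             k_p = 1, K_m1 = 2e6, K_m2 = 0.101,
                             S0 = 0, ES0 = 0, ES20 = 0, volume = 1) {
  check_positive(k_in = k_in, k_minus1 = k_minus1, k_minus2 = k_minus2,
                 k_p = k_p, K_m1 = K_m1, K_m2 = K_m2)
  if (K_m1 < 100 * K_m2)
    warning("K_m1 is not much larger than K_m2; the cooperative Hill reduction ",
            "may be a poor approximation", call. = FALSE)
  k_1 <- k_minus1 / K_m1
  k_2 <- (k_minus2 + k_p) / K_m2
  Km_sq <- K_m1 * K_m2

  # The accumulated product is a pure sink (nothing depends on it) and is
  # omitted from the state; the catalysis step just recycles the complex.
  full <- reaction_network(
    species = list(
      species_spec("S", "slow", S0),
      species_spec("E_S", "fast", ES0, 0, 1),
      species_spec("E_S2", "fast", ES20, 0, 1),
      species_spec("E", "eliminated", 1 - ES0 - ES20, 0, 1)),
    reactions = list(
      reaction("influx", NULL, c(S = 1), mass_action(k_in)),
      reaction("bind1", c(S = 1, E = 1), c(E_S = 1), mass_action(k_1)),
      reaction("unbind1", c(E_S = 1), c(S = 1, E = 1), mass_action(k_minus1)),
      reaction("bind2", c(S = 1, E_S = 1), c(E_S2 = 1), mass_action(k_2)),
      reaction("unbind2", c(E_S2 = 1), c(S = 1, E_S = 1), mass_action(k_minus2)),
      reaction("catalysis", c(E_S2 = 1), c(E_S = 1), mass_action(k_p))),
    conservation = conservation_law(c(E = 1, E_S = 1, E_S2 = 1), 1),
    volume = volume, name = "coop_enzyme_full")
  full <- apply_conservation(full)

  reduced <- reaction_network(
    species = list(species_spec("S", "slow", S0)),
    reactions = list(
      reaction("influx", NULL, c(S = 1), mass_action(k_in)),
      reaction("consumption", c(S = 1), NULL,
               rate_expr(~ k_p * S^2 / (Km_sq + S^2),
                         params = c(k_p = k_p, Km_sq = Km_sq)))),
    volume = volume, name = "coop_enzyme_reduced")

  model_pair(
    full, reduced, observable = "S",
    qss_map = function(slow) {
      S <- slow[["S"]]
      E <- 1 / (1 + S / K_m1 + S^2 / Km_sq)
      c(E_S = S * E / K_m1, E_S2 = S^2 * E / Km_sq)
    },
    ic_filter = function(state) state[["E_S"]] + state[["E_S2"]] <= 1 + 1e-12,
    name = "coop_enzyme",
    params = list(k_in = k_in, k_minus1 = k_minus1, k_minus2 = k_minus2,
                  k_p = k_p, k_1 = k_1, k_2 = k_2,
                  K_m1 = K_m1, K_m2 = K_m2, Km_sq = Km_sq),
    defaults = list(T = 4000, n_out = 1000, rtol = 1e-6, atol = 1e-9,
                    burn_in = 9000, t_end = 11000, n_reps = 1000))
}

# Total-QSS equilibrium of active DNA as a function of total repressor:
# the positive root of k_f (T - D_R) D_A = (k_b + beta_R) D_R, D_R = D_T - D_A.
tqss_root <- function(T, D_T, K_d) {
  (D_T - T - K_d + sqrt((D_T - T - K_d)^2 + 4 * D_T * K_d)) / 2
}

#' Transcriptional oscillator with total- and prefactor-QSSA reductions
#'
#' A negative feedback oscillator: mRNA `M` -> protein `P` -> active repressor
#' `R`, which reversibly binds DNA (`D_A + D_R = D_T`) and degrades both free
#' and bound. The total-QSSA (tQSSA) rewrites the system in the binding-
#' insensitive total `T = R + D_R` and closes it with the quadratic-root
#' equilibrium `D_A(T)`; the prefactor-QSSA (pQSSA) is the same reduction
#' transformed back to the free variable `R`, at the price of the state-
#' dependent prefactor `p(R) = 1 + D_T K_d/(R + K_d)^2` multiplying `dR/dt`.
#' The dissociation-like constant is `K_d = (k_b + beta_R)/k_f` (the value
#' solving the total-QSS balance; note the reciprocal form sometimes quoted
#' for this constant is dimensionally inconsistent with that balance).
#' Deterministically the two reductions are equivalent; stochastically only
#' the tQSSA propensities are trustworthy. Time unit: hours.
#'
#' @param reduction `"tqssa"` or `"pqssa"`.
#' @param alpha_M,beta_M Transcription/mRNA decay rates.
#' @param alpha_P,beta_P Translation/protein decay rates.
#' @param alpha_R,beta_R Repressor activation/decay rates.
#' @param k_f,k_b Repressor-DNA binding/unbinding rates.
#' @param D_T Total DNA concentration.
#' @param volume System volume.
#' @param limit_cycle_init Start on the deterministic limit cycle of the full
#'   model (located by integrating past the transient)? If `FALSE` the state
#'   starts at `M = P = R = D_R = 0`.
#' @return A [model_pair()] with observable `P`; the pQSSA reduced network is
#'   prefactored (see [strip_prefactor()] for its stochastic counterpart).
#' @export
make_oscillator <- function(reduction = c("tqssa", "pqssa"),
                            alpha_M = 15.1745, alpha_P = 1, alpha_R = 1,
                            beta_M = 1, beta_P = 1, beta_R = 1,
                            k_b = 50, k_f = 200, D_T = 164.75, volume = 1,
                            limit_cycle_init = TRUE) {
  reduction <- match.arg(reduction)
  check_positive(alpha_M = alpha_M, alpha_P = alpha_P, alpha_R = alpha_R,
                 beta_M = beta_M, beta_P = beta_P, beta_R = beta_R,
                 k_b = k_b, k_f = k_f, D_T = D_T)
  K_d <- (k_b + beta_R) / k_f

  build_full <- function(M0, P0, R0, DR0) {
    net <- reaction_network(
      species = list(
        species_spec("M", "slow", M0),
        species_spec("P", "slow", P0),
        species_spec("R", "slow", R0),
        species_spec("D_R", "fast", DR0, 0, D_T),
        species_spec("D_A", "eliminated", D_T - DR0, 0, D_T)),
      reactions = list(
        reaction("transcription", c(D_A = 1), c(D_A = 1, M = 1), mass_action(alpha_M)),
        reaction("mRNA_decay", c(M = 1), NULL, mass_action(beta_M)),
        reaction("translation", c(M = 1), c(M = 1, P = 1), mass_action(alpha_P)),
        reaction("protein_decay", c(P = 1), NULL, mass_action(beta_P)),
        reaction("activation", c(P = 1), c(P = 1, R = 1), mass_action(alpha_R)),
        reaction("repressor_decay", c(R = 1), NULL, mass_action(beta_R)),
        reaction("binding", c(R = 1, D_A = 1), c(D_R = 1), mass_action(k_f)),
        reaction("unbinding", c(D_R = 1), c(R = 1, D_A = 1), mass_action(k_b)),
        reaction("bound_decay", c(D_R = 1), c(D_A = 1), mass_action(beta_R))),
      conservation = conservation_law(c(D_A = 1, D_R = 1), D_T),
      volume = volume, name = "oscillator_full")
    apply_conservation(net)
  }

  ic <- c(M = 0, P = 0, R = 0, D_R = 0)
  if (limit_cycle_init) {
    ic <- oscillator_cycle_point(build_full(10, 10, 10, 0),
                                 alpha_M, alpha_P, alpha_R, beta_M, beta_P,
                                 beta_R, k_b, k_f, D_T)
  }
  full <- build_full(ic[["M"]], ic[["P"]], ic[["R"]], ic[["D_R"]])

  if (reduction == "tqssa") {
    T0 <- ic[["R"]] + ic[["D_R"]]
    reduced <- reaction_network(
      species = list(
        species_spec("M", "slow", ic[["M"]]),
        species_spec("P", "slow", ic[["P"]]),
        species_spec("T", "slow", T0)),
      reactions = list(
        reaction("transcription", NULL, c(M = 1),
                 rate_expr(~ alpha_M * (D_T - T - K_d + sqrt((D_T - T - K_d)^2 + 4 * D_T * K_d)) / 2,
                           params = c(alpha_M = alpha_M, D_T = D_T, K_d = K_d))),
        reaction("mRNA_decay", c(M = 1), NULL, mass_action(beta_M)),
        reaction("translation", c(M = 1), c(M = 1, P = 1), mass_action(alpha_P)),
        reaction("protein_decay", c(P = 1), NULL, mass_action(beta_P)),
        reaction("activation", c(P = 1), c(P = 1, T = 1), mass_action(alpha_R)),
        reaction("total_decay", c(T = 1), NULL, mass_action(beta_R))),
      volume = volume, name = "oscillator_tqssa")
    pair <- model_pair(
      full, reduced, observable = "P",
      qss_map = function(slow) c(D_R = D_T - tqss_root(slow[["T"]], D_T, K_d)),
      lift = function(slow, fast_vals) {
        c(M = slow[["M"]], P = slow[["P"]],
          R = slow[["T"]] - fast_vals[["D_R"]], D_R = fast_vals[["D_R"]])
      },
      ic_filter = function(state) state[["R"]] >= 0,
      fast = "D_R",
      name = "oscillator_tqssa",
      params = list(alpha_M = alpha_M, alpha_P = alpha_P, alpha_R = alpha_R,
                    beta_M = beta_M, beta_P = beta_P, beta_R = beta_R,
                    k_b = k_b, k_f = k_f, K_d = K_d, D_T = D_T),
      defaults = list(T = 100, n_out = 1000, rtol = 1e-6, atol = 1e-9,
                      burn_in = 20, t_end = 30, n_reps = 200,
                      region_mode = "cycle"))
  } else {
    reduced <- reaction_network(
      species = list(
        species_spec("M", "slow", ic[["M"]]),
        species_spec("P", "slow", ic[["P"]]),
        species_spec("R", "slow", ic[["R"]])),
      reactions = list(
        reaction("transcription", NULL, c(M = 1),
                 rate_expr(~ alpha_M * D_T * K_d / (R + K_d),
                           params = c(alpha_M = alpha_M, D_T = D_T, K_d = K_d))),
        reaction("mRNA_decay", c(M = 1), NULL, mass_action(beta_M)),
        reaction("translation", c(M = 1), c(M = 1, P = 1), mass_action(alpha_P)),
        reaction("protein_decay", c(P = 1), NULL, mass_action(beta_P)),
        reaction("activation", c(P = 1), c(P = 1, R = 1), mass_action(alpha_R)),
        reaction("free_decay", c(R = 1), NULL, mass_action(beta_R)),
        reaction("sequestered_decay", c(R = 1), NULL,
                 rate_expr(~ beta_R * D_T * R / (R + K_d),
                           params = c(beta_R = beta_R, D_T = D_T, K_d = K_d)))),
      volume = volume,
      prefactor = list(R = rate_expr(~ 1 + D_T * K_d / ((R + K_d)^2),
                                     params = c(D_T = D_T, K_d = K_d))),
      name = "oscillator_pqssa")
    pair <- model_pair(
      full, reduced, observable = "P",
      qss_map = function(slow) c(D_R = D_T * slow[["R"]] / (slow[["R"]] + K_d)),
      name = "oscillator_pqssa",
      params = list(alpha_M = alpha_M, alpha_P = alpha_P, alpha_R = alpha_R,
                    beta_M = beta_M, beta_P = beta_P, beta_R = beta_R,
                    k_b = k_b, k_f = k_f, K_d = K_d, D_T = D_T),
      defaults = list(T = 100, n_out = 1000, rtol = 1e-6, atol = 1e-9,
                      burn_in = 20, t_end = 30, n_reps = 200,
                      region_mode = "cycle"))
  }
  pair
}

# Locate a point on the deterministic limit cycle by integrating the full
# model past its transient; cached per parameter set.
oscillator_cycle_cache <- new.env(parent = emptyenv())
oscillator_cycle_point <- function(full, ...) {
  key <- paste(format(c(...), digits = 12), collapse = "|")
  if (!is.null(oscillator_cycle_cache[[key]])) return(oscillator_cycle_cache[[key]])
  tr <- integrate_network(full, initial = c(M = 10, P = 10, R = 10, D_R = 0),
                          t_end = 200, n_out = 400, rtol = 1e-8, atol = 1e-10)
  pt <- unlist(tr[nrow(tr), c("M", "P", "R", "D_R")])
  oscillator_cycle_cache[[key]] <- pt
  pt
}

#' Negative feedback loop with composite reductions
#'
#' mRNA `M` is transcribed from free DNA `D` and singly bound DNA `D_R`
#' (doubly bound `D_R2` is silent; `D + D_R + D_R2 = D_T`), and the protein
#' `R` is removed enzymatically through a complex `E_R` (`E + E_R = E_T`).
#' Two independent QSS reductions exist: the enzymatic one (Michaelis-Menten
#' degradation `k_4 E_T R/(K_M + R)`, variant `"ER"`), the DNA-binding one
#' (Hill transcription `alpha_M D_T K_D^2/(K_D^2 + R^2)`, variant `"DR"`),
#' and their composition (variant `"EDR"`). Time unit: seconds.
#'
#' The total enzyme concentration `E_T` is not pinned down by the reference
#' parameter set; the default `E_T = 1` puts the operating point near the
#' Michaelis constant (`R* ~ K_M`), the regime in which the enzymatic
#' reduction is meaningfully exercised. Override it for other regimes.
#'
#' @param variant `"ER"`, `"DR"`, `"EDR"` (each paired against the full
#'   model) or `"full"` (returns the full network alone).
#' @param alpha_M,beta_M Transcription / mRNA decay rates.
#' @param k_R Translation rate.
#' @param k_1,k_minus1 First repressor-DNA binding/unbinding rates.
#' @param k_2,k_minus2 Second repressor-DNA binding/unbinding rates.
#' @param k_minus3,k_4 Enzyme unbinding and catalytic degradation rates; the
#'   enzyme binding rate is `k_3 = (k_minus3 + k_4)/K_M`.
#' @param K_M Michaelis constant of the enzymatic degradation.
#' @param D_T,E_T Total DNA and enzyme concentrations.
#' @param M0,R0,D0,DR0,ER0 Initial values (defaults: everything empty, DNA
#'   fully repressed).
#' @param volume System volume; the default 100 makes the DNA copy number
#'   `D_T * volume = 1` integral for stochastic simulation.
#' @return A [model_pair()] with observable `R`, or a `reaction_network` for
#'   `variant = "full"`.
#' @export
make_composite_nfl <- function(variant = c("ER", "DR", "EDR", "full"),
                               alpha_M = 50, beta_M = 1, k_R = 1,
                               k_1 = 1e-5, k_minus1 = 10,
                               k_2 = 100, k_minus2 = 10,
                               k_minus3 = 10, k_4 = 1, K_M = 110,
                               D_T = 0.01, E_T = 1,
                               M0 = 0, R0 = 0, D0 = 0, DR0 = 0, ER0 = 0,
                               volume = 100) {
  variant <- match.arg(variant)
  check_positive(alpha_M = alpha_M, beta_M = beta_M, k_R = k_R, k_1 = k_1,
                 k_minus1 = k_minus1, k_2 = k_2, k_minus2 = k_minus2,
                 k_minus3 = k_minus3, k_4 = k_4, K_M = K_M, D_T = D_T, E_T = E_T)
  k_3 <- (k_minus3 + k_4) / K_M
  KD_sq <- k_minus1 * k_minus2 / (k_1 * k_2)
  K_1 <- k_minus1 / k_1

  full <- reaction_network(
    species = list(
      species_spec("M", "slow", M0),
      species_spec("R", "slow", R0),
      species_spec("D", "fast", D0, 0, D_T),
      species_spec("D_R", "fast", DR0, 0, D_T),
      species_spec("E_R", "fast", ER0, 0, E_T),
      species_spec("D_R2", "eliminated", D_T - D0 - DR0, 0, D_T),
      species_spec("E", "eliminated", E_T - ER0, 0, E_T)),
    reactions = list(
      reaction("transcription_D", c(D = 1), c(D = 1, M = 1), mass_action(alpha_M)),
      reaction("transcription_DR", c(D_R = 1), c(D_R = 1, M = 1), mass_action(alpha_M)),
      reaction("mRNA_decay", c(M = 1), NULL, mass_action(beta_M)),
      reaction("translation", c(M = 1), c(M = 1, R = 1), mass_action(k_R)),
      reaction("bind1", c(R = 1, D = 1), c(D_R = 1), mass_action(k_1)),
      reaction("unbind1", c(D_R = 1), c(R = 1, D = 1), mass_action(k_minus1)),
      reaction("bind2", c(R = 1, D_R = 1), c(D_R2 = 1), mass_action(k_2)),
      reaction("unbind2", c(D_R2 = 1), c(R = 1, D_R = 1), mass_action(k_minus2)),
      reaction("bind_E", c(R = 1, E = 1), c(E_R = 1), mass_action(k_3)),
      reaction("unbind_E", c(E_R = 1), c(R = 1, E = 1), mass_action(k_minus3)),
      reaction("degradation", c(E_R = 1), c(E = 1), mass_action(k_4))),
    conservation = list(conservation_law(c(D = 1, D_R = 1, D_R2 = 1), D_T),
                        conservation_law(c(E = 1, E_R = 1), E_T)),
    volume = volume, name = "composite_nfl_full")
  full <- apply_conservation(full)
  if (variant == "full") return(full)

  hill_transcription <- reaction(
    "transcription", NULL, c(M = 1),
    rate_expr(~ alpha_M * D_T * KD_sq / (KD_sq + R^2),
              params = c(alpha_M = alpha_M, D_T = D_T, KD_sq = KD_sq)))
  mm_degradation <- reaction(
    "degradation", c(R = 1), NULL,
    rate_expr(~ k_4 * E_T * R / (K_M + R),
              params = c(k_4 = k_4, E_T = E_T, K_M = K_M)))
  mRNA_decay <- reaction("mRNA_decay", c(M = 1), NULL, mass_action(beta_M))
  translation <- reaction("translation", c(M = 1), c(M = 1, R = 1), mass_action(k_R))

  qss_dna <- function(R) {
    D <- D_T / (1 + R / K_1 + R^2 / KD_sq)
    c(D = D, D_R = R * D / K_1)
  }
  qss_enz <- function(R) c(E_R = E_T * R / (K_M + R))

  reduced <- switch(variant,
    ER = {
      net <- reaction_network(
        species = list(
          species_spec("M", "slow", M0),
          species_spec("R", "slow", R0),
          species_spec("D", "fast", D0, 0, D_T),
          species_spec("D_R", "fast", DR0, 0, D_T),
          species_spec("D_R2", "eliminated", D_T - D0 - DR0, 0, D_T)),
        reactions = list(
          reaction("transcription_D", c(D = 1), c(D = 1, M = 1), mass_action(alpha_M)),
          reaction("transcription_DR", c(D_R = 1), c(D_R = 1, M = 1), mass_action(alpha_M)),
          mRNA_decay, translation,
          reaction("bind1", c(R = 1, D = 1), c(D_R = 1), mass_action(k_1)),
          reaction("unbind1", c(D_R = 1), c(R = 1, D = 1), mass_action(k_minus1)),
          reaction("bind2", c(R = 1, D_R = 1), c(D_R2 = 1), mass_action(k_2)),
          reaction("unbind2", c(D_R2 = 1), c(R = 1, D_R = 1), mass_action(k_minus2)),
          mm_degradation),
        conservation = conservation_law(c(D = 1, D_R = 1, D_R2 = 1), D_T),
        volume = volume, name = "composite_nfl_ER")
      apply_conservation(net)
    },
    DR = reaction_network(
      species = list(
        species_spec("M", "slow", M0),
        species_spec("R", "slow", R0),
        species_spec("E_R", "fast", ER0, 0, E_T),
        species_spec("E", "eliminated", E_T - ER0, 0, E_T)),
      reactions = list(
        hill_transcription, mRNA_decay, translation,
        reaction("bind_E", c(R = 1, E = 1), c(E_R = 1), mass_action(k_3)),
        reaction("unbind_E", c(E_R = 1), c(R = 1, E = 1), mass_action(k_minus3)),
        reaction("degradation", c(E_R = 1), c(E = 1), mass_action(k_4))),
      conservation = conservation_law(c(E = 1, E_R = 1), E_T),
      volume = volume, name = "composite_nfl_DR") |> apply_conservation(),
    EDR = reaction_network(
      species = list(species_spec("M", "slow", M0), species_spec("R", "slow", R0)),
      reactions = list(hill_transcription, mRNA_decay, translation, mm_degradation),
      volume = volume, name = "composite_nfl_EDR"))

  qss_map <- switch(variant,
    ER = function(slow) qss_enz(slow[["R"]]),
    DR = function(slow) qss_dna(slow[["R"]]),
    EDR = function(slow) c(qss_dna(slow[["R"]]), qss_enz(slow[["R"]])))

  model_pair(
    full, reduced, observable = "R",
    qss_map = qss_map,
    ic_filter = function(state) state[["D"]] + state[["D_R"]] <= D_T + 1e-12,
    name = paste0("composite_nfl_", variant),
    params = list(alpha_M = alpha_M, beta_M = beta_M, k_R = k_R,
                  k_1 = k_1, k_minus1 = k_minus1, k_2 = k_2,
                  k_minus2 = k_minus2, k_3 = k_3, k_minus3 = k_minus3,
                  k_4 = k_4, K_M = K_M, KD_sq = KD_sq, D_T = D_T, E_T = E_T),
    defaults = list(T = 200, n_out = 250, rtol = 1e-6, atol = 1e-9,
                    burn_in = 2000, t_end = 2400, n_reps = 300))
}

#' Linear transcription-translation cascade (unbounded fast variable)
#'
#' Constitutive transcription of mRNA `M` (fast, unbounded) and translation
#' into protein `P` (slow). The QSSA replaces `M` by its equilibrium
#' `alpha_M/k_M`, giving a constitutive birth-death process for `P`. Because
#' the system is linear, the stationary variance of `P` is known exactly for
#' both models (see [closed_form_variances()]), which makes this the
#' reference case for an unbounded fast species.
#'
#' @param alpha_M,k_M mRNA birth and decay rates.
#' @param alpha_P,k_P Protein birth (per mRNA) and decay rates.
#' @param M0,P0 Initial values; default to the deterministic fixed point.
#' @param volume System volume.
#' @return A [model_pair()] with observable `P`.
#' @export
make_linear_cascade <- function(alpha_M = 10, alpha_P = 1, k_M = 1, k_P = 0.1,
                                M0 = alpha_M / k_M,
                                P0 = round(alpha_M * alpha_P / (k_M * k_P)),
                                volume = 1) {
  check_positive(alpha_M = alpha_M, alpha_P = alpha_P, k_M = k_M, k_P = k_P)
  full <- reaction_network(
    species = list(
      species_spec("P", "slow", P0),
      species_spec("M", "fast", M0, 0, Inf)),
    reactions = list(
      reaction("transcription", NULL, c(M = 1), mass_action(alpha_M)),
      reaction("mRNA_decay", c(M = 1), NULL, mass_action(k_M)),
      reaction("translation", c(M = 1), c(M = 1, P = 1), mass_action(alpha_P)),
      reaction("protein_decay", c(P = 1), NULL, mass_action(k_P))),
    volume = volume, name = "linear_cascade_full")
  reduced <- reaction_network(
    species = list(species_spec("P", "slow", P0)),
    reactions = list(
      reaction("birth", NULL, c(P = 1), mass_action(alpha_M * alpha_P / k_M)),
      reaction("protein_decay", c(P = 1), NULL, mass_action(k_P))),
    volume = volume, name = "linear_cascade_reduced")
  model_pair(
    full, reduced, observable = "P",
    qss_map = function(slow) c(M = alpha_M / k_M),
    name = "linear_cascade",
    params = list(alpha_M = alpha_M, alpha_P = alpha_P, k_M = k_M, k_P = k_P),
    defaults = list(T = 100, n_out = 2000,
                    burn_in = 10 / k_P, t_end = 12 / k_P, n_reps = 1e4))
}

#' Closed-form stationary statistics of the linear cascade
#'
#' For the linear cascade the stationary mean and variance of `P` are exact:
#' `<P> = alpha_M alpha_P/(k_M k_P)`,
#' `var_full = <P> ((alpha_P/k_M)/(1 + k_P/k_M) + 1)`, `var_qssa = <P>`.
#' The relative error of the stochastic QSSA, measured as the CV difference
#' `(sqrt(var_full) - sqrt(var_qssa))/<P>`, scales as `sqrt(k_P)`; the
#' commonly quoted approximation of it is also returned.
#'
#' @inheritParams make_linear_cascade
#' @return A one-row tibble with `mean_P`, `var_full`, `var_qssa`, `cv_full`,
#'   `cv_qssa`, `rel_error` and `rel_error_approx`.
#' @export
#' @examples
#' closed_form_variances()   # var_full = 190.909..., Fano 1.909...
closed_form_variances <- function(alpha_M = 10, alpha_P = 1, k_M = 1, k_P = 0.1) {
  check_positive(alpha_M = alpha_M, alpha_P = alpha_P, k_M = k_M, k_P = k_P)
  mean_P <- alpha_M * alpha_P / (k_M * k_P)
  var_full <- mean_P * ((alpha_P / k_M) / (1 + k_P / k_M) + 1)
  var_qssa <- mean_P
  tibble::tibble(
    mean_P = mean_P, var_full = var_full, var_qssa = var_qssa,
    cv_full = sqrt(var_full) / mean_P, cv_qssa = sqrt(var_qssa) / mean_P,
    rel_error = (sqrt(var_full) - sqrt(var_qssa)) / mean_P,
    rel_error_approx = (sqrt(alpha_P / k_M + 1) - 1) /
      sqrt(alpha_M * alpha_P / (k_P * k_M)))
}

#' The built-in model catalog
#'
#' @return A tibble listing each catalog entry, its reduction variants, time
#'   unit, observable, default horizon for the reduction-error metric, and
#'   default parameters.
#' @export
qssa_catalog <- function() {
  tibble::tibble(
    name = c("genetic_nfl", "coop_enzyme", "oscillator", "composite_nfl",
             "linear_cascade"),
    variants = c("sqssa", "sqssa", "tqssa, pqssa", "ER, DR, EDR", "sqssa"),
    time_unit = c("h", "s", "h", "s", "arbitrary"),
    observable = c("R", "S", "P", "R", "P"),
    default_T = c(5, 4000, 100, 200, 100),
    default_params = c(
      "K_D=10, alpha_M=300, beta_M=beta_R=alpha_R=1, k_f=10",
      "k_in=0.5, k_minus1=k_minus2=100, k_p=1, K_m1=2e6, K_m2=0.101",
      "alpha_M=15.1745, alpha_P=alpha_R=beta_M=beta_P=beta_R=1, k_b=50, k_f=200, D_T=164.75",
      "alpha_M=50, beta_M=k_R=k_4=1, k_minus1=k_minus2=k_minus3=10, k_1=1e-5, k_2=100, K_M=110, D_T=0.01, E_T=1",
      "alpha_M=10, alpha_P=1, k_M=1, k_P=0.1"))
}

check_positive <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("parameter `", nm, "` must be a positive real", call. = FALSE)
  }
  invisible(TRUE)
}
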