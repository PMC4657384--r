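# The built-in model catalog: QSS maps, reduction invariance, closed forms.

strip_cache <- function(net) {
  net$.cache <- NULL
  net
}

test_that("genetic NFL: QSS map and reduction invariance in k_f", {
  pair <- make_genetic_nfl(K_D = 10)
  expect_equal(unname(pair$qss_map(c(M = 0, R = 0))["D_A"]), 1)
  expect_equal(unname(pair$qss_map(c(M = 0, R = 10))["D_A"]), 0.5)

  # different k_f at fixed K_D give the identical reduced network
  r1 <- strip_cache(make_genetic_nfl(k_f = 0.1)$reduced)
  r2 <- strip_cache(make_genetic_nfl(k_f = 10)$reduced)
  expect_identical(r1, r2)
  # substituting the QSS map into the fast-species RHS gives zero residual
  full <- pair$full
  for (R in seq(0, 200, by = 25)) {
    DA <- pair$qss_map(c(M = 0, R = R))[["D_A"]]
    res <- evaluate_rhs(full, c(M = 0, R = R, D_A = DA))[["D_A"]]
    expect_lt(abs(res), 1e-8)
  }
})

test_that("genetic NFL: full and reduced trajectories agree from the figure IC", {
  pair <- make_genetic_nfl(k_f = 10, K_D = 10)
  full_tr <- integrate_network(pair$full, initial = c(M = 100, R = 100, D_A = 0),
                               t_end = 20, n_out = 1000)
  red_tr <- integrate_network(pair$reduced, initial = c(M = 100, R = 100),
                              t_end = 20, n_out = 1000)
  expect_lt(l1_relative_error(full_tr, red_tr, "R", 20), 0.05)
})

test_that("cooperative enzyme: constants, half-saturation, invariances", {
  pair <- make_coop_enzyme()
  expect_equal(pair$params$Km_sq, 2e6 * 0.101)    # = 2.02e5
  # consumption at S^2 = K_m^2 is half-maximal
  S_half <- sqrt(pair$params$Km_sq)
  d <- evaluate_rhs(pair$reduced, c(S = S_half))
  expect_equal(unname(d["S"]), 0.5 - 1 / 2, tolerance = 1e-12)
  # changing k_minus1 at fixed K_m1, K_m2 leaves the reduction identical
  r1 <- strip_cache(make_coop_enzyme(k_minus1 = 10)$reduced)
  r2 <- strip_cache(make_coop_enzyme(k_minus1 = 1000)$reduced)
  expect_identical(r1, r2)
  # QSS map residual on the fast complexes
  for (S in c(0, 100, 449, 1000)) {
    fast <- pair$qss_map(c(S = S))
    res <- evaluate_rhs(pair$full, c(S = S, E_S = fast[["E_S"]],
                                     E_S2 = fast[["E_S2"]]))
    expect_lt(max(abs(res[c("E_S", "E_S2")])), 1e-8)
  }
})

test_that("oscillator: total-QSS root satisfies its defining balance", {
  pair <- make_oscillator("tqssa")
  K_d <- pair$params$K_d
  D_T <- pair$params$D_T
  expect_equal(K_d, (50 + 1) / 200)
  # algebraic limit at T = 0: all DNA active
  expect_equal(stoqssa:::tqss_root(0, D_T, K_d), D_T, tolerance = 1e-10)
  # residual of k_f (T - D_R) D_A - (k_b + beta_R) D_R across T in [0, 2 D_T]
  for (T in seq(0, 2 * D_T, length.out = 41)) {
    DA <- stoqssa:::tqss_root(T, D_T, K_d)
    DR <- D_T - DA
    res <- 200 * (T - DR) * DA - (50 + 1) * DR
    expect_lt(abs(res), 1e-8 * max(1, 200 * D_T^2))
  }
})

test_that("oscillator: prefactor limits and deterministic tQSSA/pQSSA equivalence", {
  pp <- make_oscillator("pqssa")
  K_d <- pp$params$K_d
  D_T <- pp$params$D_T
  pR <- function(R) 1 + D_T * K_d / ((R + K_d)^2)
  expect_equal(pR(0), 1 + D_T / K_d)
  expect_equal(pR(1e9), 1, tolerance = 1e-6)

  # same reduction in different variables: trajectories map onto each other
  pt <- make_oscillator("tqssa")
  R0 <- 2.5; M0 <- 280; P0 <- 190
  T0 <- R0 + D_T * R0 / (R0 + K_d)
  tr_t <- integrate_network(pt$reduced, initial = c(M = M0, P = P0, T = T0),
                            t_end = 20, n_out = 1000, rtol = 1e-10, atol = 1e-12)
  tr_p <- integrate_network(pp$reduced, initial = c(M = M0, P = P0, R = R0),
                            t_end = 20, n_out = 1000, rtol = 1e-10, atol = 1e-12)
  T_from_p <- tr_p$R + D_T * tr_p$R / (tr_p$R + K_d)
  expect_lt(max(abs(tr_t$M - tr_p$M) / pmax(abs(tr_t$M), 1e-6)), 1e-6)
  expect_lt(max(abs(tr_t$T - T_from_p) / pmax(abs(tr_t$T), 1e-6)), 1e-6)
})

test_that("composite NFL: derived constants and reduced transcription limits", {
  pair <- make_composite_nfl("EDR")
  expect_equal(pair$params$KD_sq, (10 * 10) / (1e-5 * 1e2))   # = 1e5
  expect_equal(pair$params$k_3, (10 + 1) / 110)               # = 0.1
  # Hill transcription at zero repressor equals alpha_M * D_T
  d <- evaluate_rhs(pair$reduced, c(M = 0, R = 0))
  expect_equal(unname(d["M"]), 50 * 0.01, tolerance = 1e-12)
  expect_error(make_composite_nfl("XY"), "arg")
  # QSS map residuals of all three fast species
  for (R in c(1, 50, 93, 200)) {
    fast <- pair$qss_map(c(M = 0.5, R = R))
    st <- c(M = 0.5, R = R, fast)
    res <- evaluate_rhs(pair$full, st)
    expect_lt(max(abs(res[c("D", "D_R", "E_R")])), 1e-8)
  }
})

test_that("linear cascade: closed-form moments and scaling", {
  cf <- closed_form_variances()
  expect_equal(cf$mean_P, 100)
  expect_equal(cf$var_full, 100 * (1 / 1.1 + 1))   # 190.909...
  expect_equal(cf$var_qssa, 100)
  # Poisson limit as translation burst vanishes
  cf0 <- closed_form_variances(alpha_P = 1e-9, alpha_M = 1e10)
  expect_equal(cf0$var_full / cf0$mean_P, 1, tolerance = 1e-6)
  # relative CV error scales as sqrt(k_P): exact for the printed
  # approximation, asymptotic (within ~8% at k_P = 0.1) for the exact form
  a1 <- closed_form_variances(k_P = 0.1)$rel_error_approx
  a2 <- closed_form_variances(k_P = 0.01)$rel_error_approx
  expect_equal(a1 / a2, sqrt(10), tolerance = 1e-12)
  r1 <- closed_form_variances(k_P = 0.1)$rel_error
  r2 <- closed_form_variances(k_P = 0.01)$rel_error
  expect_equal(r1 / r2, sqrt(10), tolerance = 0.08)
  # reduction invariance: alpha_M * alpha_P fixed
  expect_identical(strip_cache(make_linear_cascade(alpha_M = 1, alpha_P = 10,
                                                   M0 = 1, P0 = 100)$reduced),
                   strip_cache(make_linear_cascade(alpha_M = 10, alpha_P = 1,
                                                   M0 = 10, P0 = 100)$reduced))
})

test_that("cascade transients coincide for matched normalized mRNA", {
  # (alpha_M, alpha_P) = (1, 10) and (10, 1): same reduction; starting both
  # at the same normalized M(0)/(alpha_M/k_M), the normalized transients match
  frac <- 0.3
  p1 <- make_linear_cascade(alpha_M = 1, alpha_P = 10, M0 = frac * 1, P0 = 100)
  p2 <- make_linear_cascade(alpha_M = 10, alpha_P = 1, M0 = frac * 10, P0 = 100)
  t1 <- integrate_network(p1$full, t_end = 5, n_out = 200)
  t2 <- integrate_network(p2$full, t_end = 5, n_out = 200)
  expect_equal(t1$M / 1, t2$M / 10, tolerance = 1e-8)
  expect_equal(t1$P, t2$P, tolerance = 1e-8)
})

test_that("the catalog table lists the five systems", {
  cat_tb <- qssa_catalog()
  expect_equal(nrow(cat_tb), 5)
  expect_setequal(cat_tb$name, c("genetic_nfl", "coop_enzyme", "oscillator",
                                 "composite_nfl", "linear_cascade"))
})
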