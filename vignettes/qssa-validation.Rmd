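---
title: "Validating stochastic quasi-steady-state reductions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating stochastic quasi-steady-state reductions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoqssa)
```

## The model problem

A biochemical network with separated timescales can be reduced by the
quasi-steady-state approximation (QSSA): set the fast species' derivatives
to zero, solve the resulting algebraic balance for the fast species as a
function of the slow state, and substitute. The reduced deterministic model
carries non-elementary rate laws — Hill functions for promoter occupancy,
Michaelis–Menten terms for enzymatic degradation, a quadratic root for the
total-QSS variant. The *stochastic* QSSA goes one step further and uses
those non-elementary functions directly as propensities in Gillespie
simulation, with the concentration substitution $a_j = \Omega f_j(n/\Omega)$.

That step needs justification. The stochastic QSS of a fast species is its
conditional average given the slow state, and the deterministic QSS is only
an approximation to it. Fluctuations take the stochastic system off the slow
manifold; each excursion is, in effect, a fresh initial condition from which
the fast species must relax while the slow species should barely move. The
reduction is therefore stochastically trustworthy only if the
*deterministic* reduction is accurate from **every initial condition the
stochastic system is likely to visit**, not just from the one trajectory a
deterministic comparison would use.

## The error metric and the validation procedure

For a model pair (full network, reduced network) and an observable $X$ the
package measures

$$
E \;=\; \max_{\mathrm{IC} \in \mathcal{N}}
\frac{\int_0^T |X_{\text{full}}(t) - X_{\text{QSSA}}(t)|\,dt}
     {\int_0^T |X_{\text{QSSA}}(t)|\,dt},
$$

a relative $L^1$ trajectory distance maximized over an initial-condition
region $\mathcal{N}$. The validation procedure builds $\mathcal{N}$ in three
steps, using only the reduced model stochastically:

1. **Reduced-model SSA.** Simulate the reduced model to stationarity
   (default: one sample per replicate at `t_end`, which avoids
   autocorrelation in the moment estimates; a time-pooling mode exists
   behind `pool_times` for users who prefer it).
2. **Region.** Each slow species gets the interval mean ± 3 SD of its
   stationary samples, clipped to its physical range. Each fast species gets
   its **entire physical range** — its distribution is exactly what the
   reduced model cannot tell us. For oscillatory reduced models the
   stationary distribution is not unimodal, so the slow intervals are
   instead pooled 0.5–99.5 % quantiles of the state over one period of
   stochastic simulation (a limit-cycle neighborhood).
3. **Scan.** Evaluate $E$ on the cartesian grid over $\mathcal{N}$
   (default 5 points per dimension, endpoints included; the reduced
   trajectory is shared across the fast grid; infeasible combinations,
   e.g. violating a conserved total, are skipped). The verdict is
   `valid` iff $E \le$ threshold.

The full stochastic model is never simulated — that is the method's point.
The one exception is opt-in: an *unbounded* fast species has no "entire
physical range", so the scan demands either an explicit cap or permission to
run a short auxiliary full-model SSA, capping at mean + 5 SD; both paths are
recorded in the report's provenance.

The threshold (default **0.1**) is a convention, not a derived quantity:
the underlying relationship between the deterministic scan error and the
stochastic error is monotone but not a fixed ratio — the two are measured in
different currencies and can differ by orders of magnitude. The default was
calibrated so that the catalog's known-good reductions pass and its
known-bad ones fail; it is always reported next to the raw error, and every
report carries the full per-IC table so users can apply their own line.

## The error horizon T

$E$'s numerator is dominated by the initial transient (the window in which
the full model's fast species relax), while the denominator grows linearly
in $T$: an over-long horizon dilutes exactly the signal the test looks for,
and an over-short one truncates the response of the observable. The defaults
are therefore a few relaxation times of the relevant slow dynamics:

* genetic negative feedback loop: `T = 5` h (≈ 5 mRNA/repressor lifetimes);
* cooperative enzyme: `T = 4000` s (the standard horizon for this system);
* oscillator: `T = 100` h (many periods; phase drift accumulates any
  transient mismatch);
* composite feedback loop: `T = 200` s — long enough to cover the slowest
  eliminated mode, the ~100 s escape of DNA from the repressed
  $D_R \leftrightarrow D_{R_2}$ pool, which a shorter window would truncate;
* linear cascade: `T = 100` time units.

All horizons are plain arguments; the per-model defaults live in
`pair$defaults` and are printed by `qssa_catalog()`.

## The catalog models and their parameters

**Genetic negative feedback loop** (`make_genetic_nfl`, hours).
Transcription $\alpha_M = 300$, degradation $\beta_M = \beta_R = 1$,
translation $\alpha_R = 1$ (the translation rate is a free choice
here; 1 h⁻¹ is this package's documented default),
$K_D = k_b/k_f = 10$, initial $M = R = 100$, $D_A = 0$. The reduction
$D_A(R) = K_D/(K_D+R)$ depends only on $K_D$, so sweeping $k_f$ at fixed
$K_D$ probes stochastic validity with a *bit-identical* reduced model. At
$\Omega = 1$ the promoter is a binary 0/1 variable; `D_T > 1` gives the
unscaled multi-copy variant (binding rate $k_f/D_T$ per copy), whose
promoter-fraction variance shrinks as copies are added.

**Cooperative enzyme** (`make_coop_enzyme`, seconds). $k_{in} = 0.5$,
$k_{-1} = k_{-2} = 100$, $k_p = 1$, $K_{m_1} = 2\cdot10^6$,
$K_{m_2} = 0.101$; binding rates derived as $k_1 = k_{-1}/K_{m_1}$,
$k_2 = (k_{-2}+k_p)/K_{m_2}$. The Hill reduction depends only on
$K_m^2 = K_{m_1} K_{m_2}$, so $k_{-1}$ and $k_{-2}$ can be swept at a fixed
reduction; the scan shows the error moves with $k_{-1}$ (which controls how
fast the complexes equilibrate relative to substrate turnover) and not with
$k_{-2}$. The accumulated product is omitted from the state: it is a pure
sink and would only add a meaningless dimension to the scan.

**Oscillator** (`make_oscillator`, hours). $\alpha_M = 15.1745$, all decay
and conversion rates 1, $k_b = 50$, $k_f = 200$, $D_T = 164.75$. The
total-QSSA rewrites the system in $T = R + D_R$, closed by the quadratic
root $D_A(T)$ with $K_d = (k_b+\beta_R)/k_f$ — the value that solves the
total-QSS balance $k_f (T - D_R) D_A = (k_b + \beta_R) D_R$; note the
reciprocal form $(k_f+\beta_R)/k_b$ sometimes quoted for this constant is
dimensionally inconsistent with that balance, and the residual check in the
test suite pins the implemented choice. The prefactor-QSSA is the same
reduction transformed to the free repressor $R$, with
$p(R) = 1 + D_T K_d/(R+K_d)^2$ multiplying $\dot R$; the two are
deterministically equivalent (verified to $10^{-6}$ in the tests), but the
transformation *assumes the fast species starts on the slow manifold*,
which stochastic fluctuations constantly violate. Stochastically the
prefactored reduction is simulated as its reaction set without the
prefactor (the construction the prefactor variant inherits); its validation
runs the scan around the limit cycle and fails, while the total-QSSA
passes. Initial conditions default to a point on the deterministic limit
cycle, located by integrating the full model past its transient (200 h);
no closed-form coordinates for such a point exist, so it is computed (and
cached) at construction time.

**Composite feedback loop** (`make_composite_nfl`, seconds).
$\alpha_M = 50$, $\beta_M = k_R = k_4 = 1$, $k_{-1} = k_{-2} = k_{-3} = 10$,
$k_1 = 10^{-5}$, $k_2 = 100$, $K_M = 110$ (hence $k_3 = 0.1$),
$K_D^2 = k_{-1}k_{-2}/(k_1 k_2) = 10^5$, $D_T = 0.01$. Two independent
reductions exist — enzymatic degradation (ER), DNA binding (DR) — plus
their composition (EDR). The total enzyme $E_T$ is **not pinned down by the
standard parameter set above**; the default here is $E_T = 1$, which puts the
operating point near the Michaelis constant ($R^* \approx K_M$) — the
regime in which the enzymatic reduction is actually exercised (with the
enzyme in large excess the repressor would be pinned near zero and neither
reduction would be probed). The default volume $\Omega = 100$ makes the DNA
copy number $D_T\Omega = 1$ integral for stochastic simulation. The point this catalog
entry makes: only the ER reduction survives validation, because the
eliminated DNA-binding mode is both slow (~100 s) and, at one copy,
violently stochastic, while the enzyme pool relaxes in fractions of a
second.

**Linear cascade** (`make_linear_cascade`). $\alpha_M = 10$,
$\alpha_P = 1$, $k_M = 1$, $k_P = 0.1$. Linear, hence exactly solvable:
$\langle P\rangle = \alpha_M\alpha_P/(k_M k_P)$,
$\sigma^2_{\text{full}} = \langle P\rangle\,
(\tfrac{\alpha_P/k_M}{1+k_P/k_M}+1)$,
$\sigma^2_{\text{QSSA}} = \langle P\rangle$
(`closed_form_variances()`). The CV difference
$(\sigma_{\text{full}}-\sigma_{\text{QSSA}})/\langle P\rangle$ scales as
$\sqrt{k_P}$ — exactly so for the standard approximation, within ~8 % at
$k_P = 0.1$ for the exact formulas, which is why the simulation check
compares the measured ratio at the measured uncertainty rather than to
$\sqrt{10}$ exactly. The fast mRNA is unbounded, so this model is also the
reference case for the capping rules above.

## Stochastic error measure

`stochastic_cv_error()` reports two numbers. `cv_rel_error`
$= |CV_{\text{full}} - CV_{\text{red}}|/CV_{\text{full}}$ is the normalized
relative difference used in the sweep/correlation analyses (the
absolute-difference orientation avoids sign conventions). `cv_diff`
$= CV_{\text{full}} - CV_{\text{red}}$ is the CV difference itself, the
quantity with the clean $\sqrt{k_P}$ scaling in the cascade. The two are
not interchangeable: the normalized form divides by a quantity that itself
shrinks along a sweep, which can flatten or even invert small-rate
asymptotics. Standard errors for both come from a moving-block bootstrap
(block length 100, resampling the per-replicate stationary samples and
recomputing the statistic per resample).

## Analytic validity estimates (two-state promoter)

For the genetic loop the package also exposes the closed-form estimates:
`it_phase_change_estimate()` returns
$(\beta_R/k_f + D_A^{\max})/(R_0 + K_D)$ — the relative drift of the
repressor during the promoter's initial transient, with
$t_{D_A} = 1/(k_f R_0 + k_b)$ as companion timescale — and
`stochastic_validity_terms()` returns the timescale ratio $k_f/\beta_R$ and
the closure term $\mathrm{Var}(D_A/D_T)\,D_T/(R+K_D)$, which controls how
well the deterministic QSS approximates the conditional average.
`measure_it_phase_change()` is the estimate's measured counterpart; its
default protocol matches the derivation's assumptions — production
silenced ($M(0)=0$, otherwise translation balances decay and the drift the
estimate bounds never expresses itself), fast species at their upper bound
(the estimate's conservative $D_A^{\max}$), horizon $3\,t_{D_A}$ (the
transient is ~95 % complete). Under that protocol the estimate tracks the
measurement within a factor of ~2 across two decades of $k_f$.

## Numerical choices

* **ODE solver**: `deSolve::lsoda`, stiff-capable (the full models are
  stiff when binding is fast), defaults `rtol = 1e-8`, `atol = 1e-10`;
  the composite and oscillator scans use `1e-6`/`1e-9` with the convergence
  guard that halving tolerances moves reported errors by < 1 %.
* **Quadrature** for the error metric: trapezoid on the uniform output grid
  (default 2000 intervals); the integrand is piecewise smooth and the
  metric is a ratio, so modest grids suffice.
* **Steady states**: long relaxation integration seeding damped Newton with
  a numerical Jacobian; residual tolerance $10^{-10}$ relative to state
  scale.
* **SSA**: exact direct method in compiled code; closed-form propensities
  evaluated from a postfix bytecode compiled from the whitelisted
  expression grammar (`+ - * / ^ sqrt`); per-replicate RNG streams derived
  from the root seed by a counter scheme, so ensembles are reproducible and
  order-independent; absorbing states (all propensities zero) continue as
  constant trajectories.
* **Burn-in**: default 10× the slowest declared first-order degradation
  timescale, overridden per catalog entry where the effective relaxation is
  slower (composite: 2000 s; oscillator cycle sampling: 20 h + one period).
* **Problem sizes**: region estimates default to 10³ reduced-model
  replicates (oscillator 200, composite 300), moment comparisons to 10⁴,
  sweeps to 10³–10⁴ replicates per point; grids are 5 points per dimension
  (3 for the 4–5-dimensional oscillator and composite scans). These are
  desk-scale choices; every one is a plain argument, and the reported
  bootstrap SEs say when they are too small.

## Degenerate inputs and edge behavior

Zero-SD stationary samples give single-point intervals; empty feasible
grids are an error; a zero denominator in the error metric (degenerate
reduced trajectory) is an error rather than an infinity; negative
closed-form propensities abort the simulation (values within $-10^{-9}$ of
zero, numerical dust, are clamped). Prefactored networks integrate
deterministically but refuse stochastic simulation unless the prefactor is
stripped, which is deliberate: the two choices differ and the package picks
one explicitly.

## What the catalog does and does not show

The five systems exercise promoter switching, enzyme sequestration,
oscillations, composite reductions and unbounded fast species — the failure
modes known for the stochastic QSSA. Passing the package's checks on them
shows the machinery measures what it claims on low-dimensional networks
with a clear slow/fast split. It does not establish anything about
reductions of large networks, about systems without timescale separation,
or about distribution-level agreement beyond second moments (the CV): the
validator can produce false negatives (the fast-species range is scanned in
full even where the stochastic system never goes — normalizing fast species
helps) and false positives (accuracy inside the scanned region does not
imply accuracy outside it, should the stochastic system escape). Both
caveats are inherent to the procedure, not to this implementation.
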