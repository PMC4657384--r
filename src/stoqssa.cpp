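// Compiled core: rate-law bytecode evaluation, deterministic RHS assembly,
// and the exact (direct-method) Gillespie simulator.
//
// Closed-form rate laws arrive as a small postfix bytecode produced by the R
// compiler (rpn_compile): opcodes 1 PUSH_CONST(i), 2 PUSH_SPECIES(i),
// 3 ADD, 4 SUB, 5 MUL, 6 DIV, 7 POW, 8 SQRT, 9 NEG. The grammar is the
// whitelisted arithmetic subset, so a fixed-size value stack suffices.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

struct Expr {
  std::vector<int> code;
  std::vector<double> consts;
};

struct Rxn {
  int kind;                    // 0 = mass action, 1 = closed form
  double k;                    // mass-action rate constant
  std::vector<int> re_i;       // reactant species indices
  std::vector<int> re_m;       // reactant multiplicities
  std::vector<int> net_i;      // species with nonzero net stoichiometry
  std::vector<double> net_d;   // net stoichiometry change
  Expr expr;                   // closed-form bytecode
};

struct Net {
  int ns;
  std::vector<Rxn> rxns;
  std::vector<int> pf_i;       // species indices carrying a prefactor
  std::vector<Expr> pf;        // prefactor bytecode, parallel to pf_i
};

static Expr as_expr(List e) {
  Expr out;
  out.code = as<std::vector<int> >(e["code"]);
  out.consts = as<std::vector<double> >(e["consts"]);
  return out;
}

// [[Rcpp::export]]
SEXP net_compile_cpp(List spec) {
  Net* net = new Net();
  net->ns = as<int>(spec["n_species"]);
  List rxns = spec["reactions"];
  for (int j = 0; j < rxns.size(); ++j) {
    List r = rxns[j];
    Rxn rx;
    rx.kind = as<int>(r["kind"]);
    rx.k = as<double>(r["k"]);
    rx.re_i = as<std::vector<int> >(r["re_i"]);
    rx.re_m = as<std::vector<int> >(r["re_m"]);
    rx.net_i = as<std::vector<int> >(r["net_i"]);
    rx.net_d = as<std::vector<double> >(r["net_d"]);
    if (rx.kind == 1) rx.expr = as_expr(r["expr"]);
    net->rxns.push_back(rx);
  }
  List pf = spec["prefactor"];
  if (pf.size() > 0) {
    IntegerVector pfi = pf["idx"];
    List pfe = pf["exprs"];
    for (int i = 0; i < pfi.size(); ++i) {
      net->pf_i.push_back(pfi[i]);
      net->pf.push_back(as_expr(pfe[i]));
    }
  }
  XPtr<Net> ptr(net, true);
  return ptr;
}

static inline double eval_expr(const Expr& e, const double* x) {
  double st[64];
  int sp = 0;
  size_t i = 0;
  const size_t n = e.code.size();
  while (i < n) {
    switch (e.code[i++]) {
    case 1: st[sp++] = e.consts[e.code[i++]]; break;
    case 2: st[sp++] = x[e.code[i++]]; break;
    case 3: --sp; st[sp - 1] += st[sp]; break;
    case 4: --sp; st[sp - 1] -= st[sp]; break;
    case 5: --sp; st[sp - 1] *= st[sp]; break;
    case 6: --sp; st[sp - 1] /= st[sp]; break;
    case 7: --sp; st[sp - 1] = std::pow(st[sp - 1], st[sp]); break;
    case 8: st[sp - 1] = std::sqrt(st[sp - 1]); break;
    case 9: st[sp - 1] = -st[sp - 1]; break;
    }
  }
  return st[0];
}

static inline double rxn_rate(const Rxn& r, const double* x) {
  if (r.kind == 0) {
    double v = r.k;
    for (size_t i = 0; i < r.re_i.size(); ++i) {
      const double xi = x[r.re_i[i]];
      for (int m = 0; m < r.re_m[i]; ++m) v *= xi;
    }
    return v;
  }
  return eval_expr(r.expr, x);
}

// Macroscopic reaction rates f_j(x) at a concentration state.
// [[Rcpp::export]]
NumericVector net_rates_cpp(SEXP p, NumericVector x) {
  XPtr<Net> net(p);
  NumericVector out(net->rxns.size());
  for (size_t j = 0; j < net->rxns.size(); ++j)
    out[j] = rxn_rate(net->rxns[j], x.begin());
  return out;
}

// Deterministic RHS: sum_j net_stoich_j * f_j(x), prefactored species divided.
// [[Rcpp::export]]
NumericVector net_rhs_cpp(SEXP p, NumericVector x) {
  XPtr<Net> net(p);
  NumericVector dx(net->ns);
  for (size_t j = 0; j < net->rxns.size(); ++j) {
    const Rxn& r = net->rxns[j];
    const double v = rxn_rate(r, x.begin());
    for (size_t i = 0; i < r.net_i.size(); ++i)
      dx[r.net_i[i]] += r.net_d[i] * v;
  }
  for (size_t i = 0; i < net->pf_i.size(); ++i)
    dx[net->pf_i[i]] /= eval_expr(net->pf[i], x.begin());
  return dx;
}

// Propensities a_j = Omega * f_j(n / Omega).
// [[Rcpp::export]]
NumericVector net_propensities_cpp(SEXP p, NumericVector counts, double omega) {
  XPtr<Net> net(p);
  std::vector<double> x(net->ns);
  for (int i = 0; i < net->ns; ++i) x[i] = counts[i] / omega;
  NumericVector out(net->rxns.size());
  for (size_t j = 0; j < net->rxns.size(); ++j) {
    double a = omega * rxn_rate(net->rxns[j], x.data());
    if (a < 0) {
      if (a < -1e-9) stop("negative propensity (%g) in reaction %d", a, (int)j + 1);
      a = 0.0;
    }
    out[j] = a;
  }
  return out;
}

// --- RNG: per-replicate mt19937_64 streams via splitmix64 mixing ------------

static inline uint64_t splitmix64(uint64_t& s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct RNG64 {
  // mt19937_64 seeded from a splitmix64 mix of (seed_base, replicate id):
  // independent, order-insensitive, bit-reproducible streams per replicate.
  std::mt19937_64 gen;
  RNG64(uint64_t seed_base, uint64_t rep) {
    uint64_t s = seed_base;
    uint64_t a = splitmix64(s);
    s = a ^ (rep * 0x9E3779B97F4A7C15ULL + 0xD1B54A32D192ED03ULL);
    uint64_t b = splitmix64(s);
    gen.seed(b ^ (a << 1));
  }
  inline double unif(void) {
    // strictly inside (0,1): safe for log()
    return (((gen() >> 11)) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// One exact direct-method realization, states recorded at record_times
// (the state immediately before or at each record time).
static void ssa_one(const Net* net, std::vector<double>& n, double omega,
                    const std::vector<double>& rec, RNG64& rng,
                    double* out /* len rec.size()*ns, species-major rows */) {
  const int ns = net->ns;
  const size_t nr = net->rxns.size();
  std::vector<double> x(ns), a(nr);
  double t = 0.0;
  size_t ri = 0;
  const size_t nrec = rec.size();
  while (ri < nrec) {
    for (int i = 0; i < ns; ++i) x[i] = n[i] / omega;
    double a0 = 0.0;
    for (size_t j = 0; j < nr; ++j) {
      double aj = omega * rxn_rate(net->rxns[j], x.data());
      if (aj < 0) {
        if (aj < -1e-9) stop("negative propensity in stochastic simulation");
        aj = 0.0;
      }
      a[j] = aj;
      a0 += aj;
    }
    double tnext;
    if (a0 <= 0.0) {
      tnext = R_PosInf;  // absorbing state: trajectory continues as constant
    } else {
      tnext = t - std::log(rng.unif()) / a0;
    }
    while (ri < nrec && rec[ri] < tnext) {
      for (int i = 0; i < ns; ++i) out[ri * ns + i] = n[i];
      ++ri;
    }
    if (ri >= nrec) break;
    if (!R_FINITE(tnext)) break;
    t = tnext;
    // select reaction
    double u = rng.unif() * a0;
    size_t j = 0;
    double acc = a[0];
    while (acc < u && j + 1 < nr) acc += a[++j];
    const Rxn& r = net->rxns[j];
    for (size_t i = 0; i < r.net_i.size(); ++i) n[r.net_i[i]] += r.net_d[i];
  }
}

// [[Rcpp::export]]
NumericMatrix ssa_traj_cpp(SEXP p, NumericVector init, NumericVector record_times,
                           double omega, double seed_base, double rep_id) {
  XPtr<Net> net(p);
  const int ns = net->ns;
  std::vector<double> n(init.begin(), init.end());
  std::vector<double> rec(record_times.begin(), record_times.end());
  RNG64 rng((uint64_t)seed_base, (uint64_t)rep_id);
  std::vector<double> out(rec.size() * ns);
  ssa_one(net, n, omega, rec, rng, out.data());
  NumericMatrix m(rec.size(), ns);
  for (size_t t = 0; t < rec.size(); ++t)
    for (int i = 0; i < ns; ++i) m(t, i) = out[t * ns + i];
  return m;
}

// Ensemble of replicates recorded at shared times; returns (reps*times) x ns,
// replicate-major blocks of rows.
// [[Rcpp::export]]
NumericMatrix ssa_ensemble_cpp(SEXP p, NumericVector init, NumericVector record_times,
                               int n_reps, double omega, double seed_base) {
  XPtr<Net> net(p);
  const int ns = net->ns;
  std::vector<double> rec(record_times.begin(), record_times.end());
  const size_t nrec = rec.size();
  NumericMatrix m(n_reps * nrec, ns);
  std::vector<double> out(nrec * ns);
  for (int r = 0; r < n_reps; ++r) {
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
    std::vector<double> n(init.begin(), init.end());
    RNG64 rng((uint64_t)seed_base, (uint64_t)(r + 1));
    ssa_one(net, n, omega, rec, rng, out.data());
    for (size_t t = 0; t < nrec; ++t)
      for (int i = 0; i < ns; ++i) m(r * nrec + t, i) = out[t * ns + i];
  }
  return m;
}

// Final-state-only ensemble (one stationary sample per replicate).
// [[Rcpp::export]]
NumericMatrix ssa_final_cpp(SEXP p, NumericVector init, double t_end,
                            int n_reps, double omega, double seed_base) {
  XPtr<Net> net(p);
  const int ns = net->ns;
  std::vector<double> rec(1, t_end);
  NumericMatrix m(n_reps, ns);
  std::vector<double> out(ns);
  for (int r = 0; r < n_reps; ++r) {
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
    std::vector<double> n(init.begin(), init.end());
    RNG64 rng((uint64_t)seed_base, (uint64_t)(r + 1));
    ssa_one(net, n, omega, rec, rng, out.data());
    for (int i = 0; i < ns; ++i) m(r, i) = out[i];
  }
  return m;
}

// [[Rcpp::export]]
bool xptr_valid_cpp(SEXP p) {
  return R_ExternalPtrAddr(p) != NULL;
}
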