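// Gibbs sampler core for the Bayesian Poisson-lognormal multi-trait
// multi-environment model, via Polya-Gamma augmentation of a negative-binomial
// approximation (size r) to the Poisson likelihood.
//
// Stacking convention (law across the package): observations are ordered
// environment-major, then line, then unit, with trait innermost.  Effect
// vectors follow the Kronecker conventions G (x) Sigma_t (line outer, trait
// inner) for b1 and Sigma_E (x) G (x) Sigma_t (environment outer, line middle,
// trait inner) for b2.  All indices passed from R are 1-based and converted
// here.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

// ---------------------------------------------------------------------------
// Polya-Gamma sampling: PG(b, d) = (1/(2 pi^2)) sum_k Ga_k(b,1) /
// ((k - 1/2)^2 + d^2 / (4 pi^2)).  Leading terms are drawn exactly; the tail
// is replaced by a gamma variate matched to its exact mean and variance.
// The number of exact terms is shape-adaptive (ceil(200 / sqrt(b))): every
// term is close to Gaussian when b is large, so the moment-matched tail
// absorbs truncation error precisely where fewer terms are kept.
// ---------------------------------------------------------------------------

static double pg_mean1(double d) {
  double ad = std::fabs(d);
  if (ad < 1e-5) return 0.25 - ad * ad / 48.0;
  return std::tanh(ad / 2.0) / (2.0 * ad);
}

static double pg_var1(double d) {
  double ad = std::fabs(d);
  if (ad < 1e-4) return 1.0 / 24.0;
  double ch = std::cosh(ad / 2.0);
  return (std::sinh(ad) - ad) / (4.0 * ad * ad * ad * ch * ch);
}

static double rpg_one(double b, double d, int max_terms) {
  const double h = d * d / (4.0 * M_PI * M_PI);
  int K = (int)std::ceil(200.0 / std::sqrt(std::max(b, 1.0)));
  if (K < 6) K = 6;
  if (K > max_terms) K = max_terms;
  double x = 0.0, sa = 0.0, sa2 = 0.0;
  for (int k = 1; k <= K; ++k) {
    double km = (double)k - 0.5;
    double a = 1.0 / (2.0 * M_PI * M_PI * (km * km + h));
    x += a * R::rgamma(b, 1.0);
    sa += a;
    sa2 += a * a;
  }
  double tail_m = b * (pg_mean1(d) - sa);
  double tail_v = b * (pg_var1(d) - sa2);
  if (tail_m > 0.0 && tail_v > 0.0) {
    x += R::rgamma(tail_m * tail_m / tail_v, tail_v / tail_m);
  } else if (tail_m > 0.0) {
    x += tail_m;
  }
  return x;
}

// [[Rcpp::export]]
NumericVector cpp_rpg(NumericVector b, NumericVector d, int max_terms) {
  int n = b.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (b[i] <= 0.0) stop("PG shape parameter b must be positive");
    out[i] = rpg_one(b[i], d[i], max_terms);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Containers
// ---------------------------------------------------------------------------

struct Data {
  mat Y;       // n_units x L collapsed counts
  mat ystar;   // (Y - r) / 2
  uvec env;    // n_units, 0-based environment index
  uvec line;   // n_units, 0-based line index
  int I, J, L, n;
  double r;
  mat G, Ginv;
  vec gdiag_inv;
  bool g_diag;
};

struct Hyper {
  vec beta_m0;
  double beta_v0;  // prior variance (scalar multiple of identity)
  double nu_t, nu_E, nu_c;
  double A_t, A_E, A_c;
  int pg_trunc;
};

struct State {
  vec beta;      // I*L, environment outer, trait inner
  mat B1;        // J x L
  mat B2;        // (I*J) x L, row index i*J + j
  mat C;         // n x L
  mat Om;        // n x L
  mat St, SE, Sc;
  vec at, aE, ac;
};

static Data data_from_list(const List& d) {
  Data out;
  out.Y = as<mat>(d["Y"]);
  out.env = as<uvec>(d["env"]) - 1;
  out.line = as<uvec>(d["line"]) - 1;
  out.I = as<int>(d["I"]);
  out.J = as<int>(d["J"]);
  out.L = as<int>(d["L"]);
  out.r = as<double>(d["r"]);
  out.n = out.Y.n_rows;
  out.ystar = (out.Y - out.r) / 2.0;
  out.G = as<mat>(d["G"]);
  mat offd = out.G - diagmat(out.G.diag());
  out.g_diag = (norm(offd, "fro") == 0.0);
  if (out.g_diag) {
    out.gdiag_inv = 1.0 / out.G.diag();
    out.Ginv = diagmat(out.gdiag_inv);
  } else {
    out.Ginv = inv_sympd(symmatu(out.G));
    out.gdiag_inv = out.Ginv.diag();
  }
  return out;
}

static Hyper hyper_from_list(const List& h) {
  Hyper out;
  out.beta_m0 = as<vec>(h["beta_prior_mean"]);
  out.beta_v0 = as<double>(h["beta_prior_var"]);
  out.nu_t = as<double>(h["nu_t"]);
  out.nu_E = as<double>(h["nu_E"]);
  out.nu_c = as<double>(h["nu_c"]);
  out.A_t = as<double>(h["A_t"]);
  out.A_E = as<double>(h["A_E"]);
  out.A_c = as<double>(h["A_c"]);
  out.pg_trunc = as<int>(h["pg_trunc"]);
  return out;
}

static State state_from_list(const List& s) {
  State out;
  out.beta = as<vec>(s["beta_star"]);
  out.B1 = as<mat>(s["b1"]);
  out.B2 = as<mat>(s["b2"]);
  out.C = as<mat>(s["c"]);
  out.Om = as<mat>(s["omega"]);
  out.St = as<mat>(s["Sigma_t"]);
  out.SE = as<mat>(s["Sigma_E"]);
  out.Sc = as<mat>(s["Sigma_c"]);
  out.at = as<vec>(s["a_t"]);
  out.aE = as<vec>(s["a_E"]);
  out.ac = as<vec>(s["a_c"]);
  return out;
}

static NumericVector as_rvec(const vec& v) {
  return NumericVector(v.begin(), v.end());
}

static List state_to_list(const State& s) {
  return List::create(
      _["beta_star"] = as_rvec(s.beta), _["b1"] = s.B1, _["b2"] = s.B2,
      _["c"] = s.C, _["omega"] = s.Om, _["Sigma_t"] = s.St,
      _["Sigma_E"] = s.SE, _["Sigma_c"] = s.Sc, _["a_t"] = as_rvec(s.at),
      _["a_E"] = as_rvec(s.aE), _["a_c"] = as_rvec(s.ac));
}

// Linear predictor eta* for observation (u, l)
static inline double eta_ul(const Data& d, const State& s, int u, int l) {
  int i = d.env[u], j = d.line[u];
  return s.beta[i * d.L + l] + s.B1(j, l) + s.B2(i * d.J + j, l) + s.C(u, l);
}

static mat eta_mat(const Data& d, const State& s) {
  mat E(d.n, d.L);
  for (int u = 0; u < d.n; ++u)
    for (int l = 0; l < d.L; ++l) E(u, l) = eta_ul(d, s, u, l);
  return E;
}

// ---------------------------------------------------------------------------
// Random draws
// ---------------------------------------------------------------------------

static vec rnorm_vec(int n) {
  vec z(n);
  for (int i = 0; i < n; ++i) z[i] = R::norm_rand();
  return z;
}

// N(Q^{-1} rhs, Q^{-1}) via the precision Cholesky
static vec mvn_prec(const mat& Q, const vec& rhs) {
  mat Rm;
  if (!chol(Rm, symmatu(Q)))
    stop("non-positive-definite precision in a location update");
  vec m = solve(trimatu(Rm), solve(trimatl(Rm.t()), rhs));
  return m + solve(trimatu(Rm), rnorm_vec(rhs.n_elem));
}

// Inverse-Wishart with density |O|^{-(kappa+p+1)/2} exp(-tr(B O^{-1})/2):
// draw W ~ Wishart(kappa, B^{-1}) by Bartlett decomposition, return W^{-1}.
static mat riwish(double kappa, const mat& B) {
  int p = B.n_rows;
  mat Binv = inv_sympd(symmatu(B));
  mat Ls = chol(Binv, "lower");
  mat A(p, p, fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(kappa - (double)i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  mat W = Ls * A;
  W = W * W.t();
  return inv_sympd(symmatu(W));
}

static double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// ---------------------------------------------------------------------------
// Location-block updates.  Each computes the full-conditional precision and
// right-hand side; `draw` samples, otherwise the assembled dense (Q, rhs) is
// returned for validation against the joint posterior.
// ---------------------------------------------------------------------------

struct QuadForm {
  mat Q;
  vec rhs;
};

// beta*: X' D X is diagonal because each observation loads one intercept.
static QuadForm qf_beta(const Data& d, const State& s, const Hyper& h) {
  int p = d.I * d.L;
  vec qd(p, fill::value(1.0 / h.beta_v0));
  vec rhs = h.beta_m0 / h.beta_v0;
  mat E = eta_mat(d, s);
  for (int u = 0; u < d.n; ++u) {
    int i = d.env[u];
    for (int l = 0; l < d.L; ++l) {
      int k = i * d.L + l;
      qd[k] += s.Om(u, l);
      rhs[k] += d.ystar(u, l) - s.Om(u, l) * (E(u, l) - s.beta[k]);
    }
  }
  QuadForm out;
  out.Q = diagmat(qd);
  out.rhs = rhs;
  return out;
}

static void upd_beta(const Data& d, State& s, const Hyper& h) {
  QuadForm qf = qf_beta(d, s, h);
  vec qd = qf.Q.diag();
  for (uword k = 0; k < qd.n_elem; ++k)
    s.beta[k] = qf.rhs[k] / qd[k] + R::norm_rand() / std::sqrt(qd[k]);
}

// b1: Z1' D Z1 is diagonal (entry (j,l) accumulates omega over environments);
// the prior precision G^{-1} (x) Sigma_t^{-1} couples lines unless G is
// diagonal, in which case the update factorizes into J systems of size L.
static QuadForm qf_b1(const Data& d, const State& s) {
  mat Sti = inv_sympd(symmatu(s.St));
  mat W(d.J, d.L, fill::zeros), Rh(d.J, d.L, fill::zeros);
  mat E = eta_mat(d, s);
  for (int u = 0; u < d.n; ++u) {
    int j = d.line[u];
    for (int l = 0; l < d.L; ++l) {
      W(j, l) += s.Om(u, l);
      Rh(j, l) += d.ystar(u, l) - s.Om(u, l) * (E(u, l) - s.B1(j, l));
    }
  }
  QuadForm out;
  out.Q = kron(d.Ginv, Sti) + diagmat(vectorise(W.t()));
  out.rhs = vectorise(Rh.t());
  return out;
}

static void upd_b1(const Data& d, State& s) {
  mat Sti = inv_sympd(symmatu(s.St));
  mat W(d.J, d.L, fill::zeros), Rh(d.J, d.L, fill::zeros);
  mat E = eta_mat(d, s);
  for (int u = 0; u < d.n; ++u) {
    int j = d.line[u];
    for (int l = 0; l < d.L; ++l) {
      W(j, l) += s.Om(u, l);
      Rh(j, l) += d.ystar(u, l) - s.Om(u, l) * (E(u, l) - s.B1(j, l));
    }
  }
  if (d.g_diag) {
    for (int j = 0; j < d.J; ++j) {
      mat Qj = d.gdiag_inv[j] * Sti + diagmat(W.row(j).t());
      vec bj = mvn_prec(Qj, Rh.row(j).t());
      s.B1.row(j) = bj.t();
    }
  } else {
    mat Q = kron(d.Ginv, Sti) + diagmat(vectorise(W.t()));
    vec b = mvn_prec(Q, vectorise(Rh.t()));
    s.B1 = reshape(b, d.L, d.J).t();
  }
}

// b2: Z2' D Z2 is diagonal (each (i,j,l) coordinate is hit by at most one
// collapsed observation).  Diagonal G factorizes the update into J systems of
// size I*L with prior precision (1/g_jj) Sigma_E^{-1} (x) Sigma_t^{-1}.
static QuadForm qf_b2(const Data& d, const State& s) {
  mat Sti = inv_sympd(symmatu(s.St));
  mat SEi = inv_sympd(symmatu(s.SE));
  int m = d.I * d.J * d.L;
  vec W(m, fill::zeros), Rh(m, fill::zeros);
  mat E = eta_mat(d, s);
  for (int u = 0; u < d.n; ++u) {
    int i = d.env[u], j = d.line[u];
    for (int l = 0; l < d.L; ++l) {
      int k = i * d.J * d.L + j * d.L + l;
      W[k] += s.Om(u, l);
      Rh[k] += d.ystar(u, l) - s.Om(u, l) * (E(u, l) - s.B2(i * d.J + j, l));
    }
  }
  QuadForm out;
  out.Q = kron(SEi, kron(d.Ginv, Sti)) + diagmat(W);
  out.rhs = Rh;
  return out;
}

static void upd_b2(const Data& d, State& s) {
  mat Sti = inv_sympd(symmatu(s.St));
  mat SEi = inv_sympd(symmatu(s.SE));
  mat E = eta_mat(d, s);
  if (d.g_diag) {
    int m = d.I * d.L;
    mat P0 = kron(SEi, Sti);
    // per-line accumulators, coordinate (i, l) -> i*L + l
    mat W(d.J, m, fill::zeros), Rh(d.J, m, fill::zeros);
    for (int u = 0; u < d.n; ++u) {
      int i = d.env[u], j = d.line[u];
      for (int l = 0; l < d.L; ++l) {
        int k = i * d.L + l;
        W(j, k) += s.Om(u, l);
        Rh(j, k) += d.ystar(u, l) - s.Om(u, l) * (E(u, l) - s.B2(i * d.J + j, l));
      }
    }
    for (int j = 0; j < d.J; ++j) {
      mat Qj = d.gdiag_inv[j] * P0 + diagmat(W.row(j).t());
      vec bj = mvn_prec(Qj, Rh.row(j).t());
      for (int i = 0; i < d.I; ++i)
        for (int l = 0; l < d.L; ++l) s.B2(i * d.J + j, l) = bj[i * d.L + l];
    }
  } else {
    QuadForm qf = qf_b2(d, s);
    vec b = mvn_prec(qf.Q, qf.rhs);
    for (int i = 0; i < d.I; ++i)
      for (int j = 0; j < d.J; ++j)
        for (int l = 0; l < d.L; ++l)
          s.B2(i * d.J + j, l) = b[i * d.J * d.L + j * d.L + l];
  }
}

// c: independent L-dimensional systems per observational unit.
static QuadForm qf_c(const Data& d, const State& s) {
  mat Sci = inv_sympd(symmatu(s.Sc));
  int m = d.n * d.L;
  QuadForm out;
  out.Q = zeros<mat>(m, m);
  out.rhs = zeros<vec>(m);
  mat E = eta_mat(d, s);
  for (int u = 0; u < d.n; ++u) {
    mat Qu = Sci;
    for (int l = 0; l < d.L; ++l) {
      Qu(l, l) += s.Om(u, l);
      out.rhs[u * d.L + l] =
          d.ystar(u, l) - s.Om(u, l) * (E(u, l) - s.C(u, l));
    }
    out.Q.submat(u * d.L, u * d.L, u * d.L + d.L - 1, u * d.L + d.L - 1) = Qu;
  }
  return out;
}

static void upd_c(const Data& d, State& s) {
  mat Sci = inv_sympd(symmatu(s.Sc));
  mat E = eta_mat(d, s);
  for (int u = 0; u < d.n; ++u) {
    mat Qu = Sci;
    vec rhs(d.L);
    for (int l = 0; l < d.L; ++l) {
      Qu(l, l) += s.Om(u, l);
      rhs[l] = d.ystar(u, l) - s.Om(u, l) * (E(u, l) - s.C(u, l));
    }
    vec cu = mvn_prec(Qu, rhs);
    s.C.row(u) = cu.t();
  }
}

// ---------------------------------------------------------------------------
// Covariance and auxiliary-scale updates (Huang-Wand hierarchy)
// ---------------------------------------------------------------------------

// Scale matrix and degrees of freedom of Sigma_t's conditional: pools the
// quadratic forms of b1 ~ N(0, G (x) St) and b2 ~ N(0, SE (x) G (x) St).
static List par_sigma_t(const Data& d, const State& s, const Hyper& h) {
  mat SEi = inv_sympd(symmatu(s.SE));
  mat Bq = s.B1.t() * d.Ginv * s.B1;
  for (int i = 0; i < d.I; ++i) {
    mat GB2i = d.Ginv * s.B2.rows(i * d.J, i * d.J + d.J - 1);
    for (int i2 = 0; i2 < d.I; ++i2)
      Bq += SEi(i, i2) * GB2i.t() * s.B2.rows(i2 * d.J, i2 * d.J + d.J - 1);
  }
  mat S = 2.0 * h.nu_t * diagmat(1.0 / s.at) + symmatu(Bq);
  double kappa = h.nu_t + d.L - 1.0 + d.J + (double)d.I * d.J;
  return List::create(_["kappa"] = kappa, _["S"] = S);
}

static void upd_sigma_t(const Data& d, State& s, const Hyper& h) {
  List p = par_sigma_t(d, s, h);
  s.St = riwish(as<double>(p["kappa"]), as<mat>(p["S"]));
}

// Sigma_E conditional from b2 only: M(i,i') = tr(G^{-1} B2_i St^{-1} B2_i'^T)
static List par_sigma_e(const Data& d, const State& s, const Hyper& h) {
  mat Sti = inv_sympd(symmatu(s.St));
  mat M(d.I, d.I, fill::zeros);
  std::vector<mat> slabs(d.I);
  for (int i = 0; i < d.I; ++i)
    slabs[i] = d.Ginv * s.B2.rows(i * d.J, i * d.J + d.J - 1) * Sti;
  for (int i = 0; i < d.I; ++i)
    for (int i2 = 0; i2 <= i; ++i2) {
      double v = accu(slabs[i2] % s.B2.rows(i * d.J, i * d.J + d.J - 1));
      M(i, i2) = v;
      M(i2, i) = v;
    }
  mat S = 2.0 * h.nu_E * diagmat(1.0 / s.aE) + M;
  double kappa = h.nu_E + d.I - 1.0 + (double)d.J * d.L;
  return List::create(_["kappa"] = kappa, _["S"] = S);
}

static void upd_sigma_e(const Data& d, State& s, const Hyper& h) {
  List p = par_sigma_e(d, s, h);
  s.SE = riwish(as<double>(p["kappa"]), as<mat>(p["S"]));
}

static List par_sigma_c(const Data& d, const State& s, const Hyper& h) {
  mat S = 2.0 * h.nu_c * diagmat(1.0 / s.ac) + s.C.t() * s.C;
  double kappa = h.nu_c + d.L - 1.0 + d.n;
  return List::create(_["kappa"] = kappa, _["S"] = symmatu(S));
}

static void upd_sigma_c(const Data& d, State& s, const Hyper& h) {
  List p = par_sigma_c(d, s, h);
  s.Sc = riwish(as<double>(p["kappa"]), as<mat>(p["S"]));
}

// Auxiliary scales: a_l | Sigma ~ IG((nu + dim)/2, nu (Sigma^{-1})_ll + A^-2)
static List par_aux(const mat& Sigma, double nu, double A) {
  mat Si = inv_sympd(symmatu(Sigma));
  int p = Sigma.n_rows;
  double shape = (nu + (double)p) / 2.0;
  vec rate(p);
  for (int l = 0; l < p; ++l) rate[l] = nu * Si(l, l) + 1.0 / (A * A);
  return List::create(_["shape"] = shape, _["rate"] = as_rvec(rate));
}

static vec draw_aux(const mat& Sigma, double nu, double A) {
  List p = par_aux(Sigma, nu, A);
  double shape = as<double>(p["shape"]);
  vec rate = as<vec>(p["rate"]);
  vec out(rate.n_elem);
  for (uword l = 0; l < rate.n_elem; ++l) out[l] = rinvgamma(shape, rate[l]);
  return out;
}

static void upd_omega(const Data& d, State& s, const Hyper& h) {
  mat E = eta_mat(d, s);
  for (int u = 0; u < d.n; ++u)
    for (int l = 0; l < d.L; ++l)
      s.Om(u, l) = rpg_one(d.Y(u, l) + d.r, E(u, l), h.pg_trunc);
}

// One full Gibbs sweep in the published order:
// beta*, b1, b2, c, Sigma_t, a_t, Sigma_E, a_E, omega, Sigma_c, a_c.
static void sweep(const Data& d, State& s, const Hyper& h) {
  upd_beta(d, s, h);
  upd_b1(d, s);
  upd_b2(d, s);
  upd_c(d, s);
  upd_sigma_t(d, s, h);
  s.at = draw_aux(s.St, h.nu_t, h.A_t);
  upd_sigma_e(d, s, h);
  s.aE = draw_aux(s.SE, h.nu_E, h.A_E);
  upd_omega(d, s, h);
  upd_sigma_c(d, s, h);
  s.ac = draw_aux(s.Sc, h.nu_c, h.A_c);
}

// [[Rcpp::export]]
List cpp_gibbs_sweep(List data, List state, List hyper) {
  Data d = data_from_list(data);
  State s = state_from_list(state);
  Hyper h = hyper_from_list(hyper);
  sweep(d, s, h);
  return state_to_list(s);
}

// [[Rcpp::export]]
List cpp_update_block(List data, List state, List hyper, std::string block,
                      bool return_params) {
  Data d = data_from_list(data);
  State s = state_from_list(state);
  Hyper h = hyper_from_list(hyper);
  if (block == "beta_star") {
    if (return_params) {
      QuadForm qf = qf_beta(d, s, h);
      return List::create(_["Q"] = qf.Q, _["rhs"] = as_rvec(qf.rhs),
                          _["mean"] = as_rvec(qf.rhs / qf.Q.diag()));
    }
    upd_beta(d, s, h);
    return List::create(_["value"] = as_rvec(s.beta));
  } else if (block == "b1") {
    if (return_params) {
      QuadForm qf = qf_b1(d, s);
      return List::create(_["Q"] = qf.Q, _["rhs"] = as_rvec(qf.rhs),
                          _["mean"] = as_rvec(solve(symmatu(qf.Q), qf.rhs)));
    }
    upd_b1(d, s);
    return List::create(_["value"] = s.B1);
  } else if (block == "b2") {
    if (return_params) {
      QuadForm qf = qf_b2(d, s);
      return List::create(_["Q"] = qf.Q, _["rhs"] = as_rvec(qf.rhs),
                          _["mean"] = as_rvec(solve(symmatu(qf.Q), qf.rhs)));
    }
    upd_b2(d, s);
    return List::create(_["value"] = s.B2);
  } else if (block == "c") {
    if (return_params) {
      QuadForm qf = qf_c(d, s);
      return List::create(_["Q"] = qf.Q, _["rhs"] = as_rvec(qf.rhs),
                          _["mean"] = as_rvec(solve(symmatu(qf.Q), qf.rhs)));
    }
    upd_c(d, s);
    return List::create(_["value"] = s.C);
  } else if (block == "sigma_t") {
    if (return_params) return par_sigma_t(d, s, h);
    upd_sigma_t(d, s, h);
    return List::create(_["value"] = s.St);
  } else if (block == "sigma_e") {
    if (return_params) return par_sigma_e(d, s, h);
    upd_sigma_e(d, s, h);
    return List::create(_["value"] = s.SE);
  } else if (block == "sigma_c") {
    if (return_params) return par_sigma_c(d, s, h);
    upd_sigma_c(d, s, h);
    return List::create(_["value"] = s.Sc);
  } else if (block == "a_t") {
    if (return_params) return par_aux(s.St, h.nu_t, h.A_t);
    return List::create(_["value"] = as_rvec(draw_aux(s.St, h.nu_t, h.A_t)));
  } else if (block == "a_E") {
    if (return_params) return par_aux(s.SE, h.nu_E, h.A_E);
    return List::create(_["value"] = as_rvec(draw_aux(s.SE, h.nu_E, h.A_E)));
  } else if (block == "a_c") {
    if (return_params) return par_aux(s.Sc, h.nu_c, h.A_c);
    return List::create(_["value"] = as_rvec(draw_aux(s.Sc, h.nu_c, h.A_c)));
  } else if (block == "omega") {
    if (return_params) {
      mat E = eta_mat(d, s);
      return List::create(_["b"] = mat(d.Y + d.r), _["d"] = E);
    }
    upd_omega(d, s, h);
    return List::create(_["value"] = s.Om);
  }
  stop("unknown block '%s'", block.c_str());
}

// [[Rcpp::export]]
double cpp_log_aug_lik(List data, List state) {
  Data d = data_from_list(data);
  State s = state_from_list(state);
  mat E = eta_mat(d, s);
  double out = 0.0;
  for (int u = 0; u < d.n; ++u)
    for (int l = 0; l < d.L; ++l)
      out += d.ystar(u, l) * E(u, l) - 0.5 * s.Om(u, l) * E(u, l) * E(u, l);
  return out;
}

// [[Rcpp::export]]
List cpp_run_chain(List data, List state, List hyper, int n_iter, int burn_in,
                   int thin, bool verbose) {
  Data d = data_from_list(data);
  State s = state_from_list(state);
  Hyper h = hyper_from_list(hyper);
  int n_keep = (n_iter - burn_in) / thin;
  int p = d.I * d.L;
  mat beta_dr(n_keep, p), st_dr(n_keep, d.L * d.L), se_dr(n_keep, d.I * d.I),
      sc_dr(n_keep, d.L * d.L), b1_dr(n_keep, d.J * d.L),
      b2_dr(n_keep, d.I * d.J * d.L), c_dr(n_keep, d.n * d.L),
      at_dr(n_keep, d.L), ae_dr(n_keep, d.I), ac_dr(n_keep, d.L);
  vec ll_dr(n_keep);
  mat om_mean(d.n, d.L, fill::zeros);
  int kept = 0;
  for (int it = 1; it <= n_iter; ++it) {
    try {
      sweep(d, s, h);
    } catch (std::exception& e) {
      stop("iteration %d: %s", it, e.what());
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      beta_dr.row(kept) = s.beta.t();
      b1_dr.row(kept) = vectorise(s.B1.t()).t();
      b2_dr.row(kept) = vectorise(s.B2.t()).t();
      c_dr.row(kept) = vectorise(s.C.t()).t();
      st_dr.row(kept) = vectorise(s.St).t();
      se_dr.row(kept) = vectorise(s.SE).t();
      sc_dr.row(kept) = vectorise(s.Sc).t();
      at_dr.row(kept) = s.at.t();
      ae_dr.row(kept) = s.aE.t();
      ac_dr.row(kept) = s.ac.t();
      om_mean += s.Om;
      double ll = 0.0;
      mat E = eta_mat(d, s);
      for (int u = 0; u < d.n; ++u)
        for (int l = 0; l < d.L; ++l)
          ll += d.ystar(u, l) * E(u, l) -
                0.5 * s.Om(u, l) * E(u, l) * E(u, l);
      ll_dr[kept] = ll;
      ++kept;
    }
    if (it % 200 == 0) checkUserInterrupt();
    if (verbose && (it % std::max(1, n_iter / 10) == 0))
      Rcout << "iteration " << it << " / " << n_iter << "\n";
  }
  if (kept > 0) om_mean /= (double)kept;
  return List::create(
      _["beta_star"] = beta_dr, _["b1"] = b1_dr, _["b2"] = b2_dr,
      _["c"] = c_dr, _["Sigma_t"] = st_dr, _["Sigma_E"] = se_dr,
      _["Sigma_c"] = sc_dr, _["a_t"] = at_dr, _["a_E"] = ae_dr,
      _["a_c"] = ac_dr, _["log_aug_lik"] = ll_dr, _["omega_mean"] = om_mean,
      _["final_state"] = state_to_list(s));
}
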