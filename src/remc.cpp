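// Replica-exchange Monte Carlo core for Poisson-likelihood scattering models.
//
// The parameter vector of a K-component sphere mixture is laid out as
//   (R_1..R_K, S_1..S_K, B),  P = 2K + 1,
// with radii kept in non-increasing order (the label-switching convention).
// K = 0 denotes the flat-background model I(q) = B, P = 1.
//
// All randomness comes from R's RNG so results are reproducible via set.seed().

#include <Rcpp.h>
#include <cstring>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---- fast log ---------------------------------------------------------------
// Table-accelerated natural log for the Poisson-cost hot loop: split off the
// exponent, look up log and reciprocal of a 128-bin mantissa anchor, and
// polish with a degree-5 log1p polynomial (|r| <= 2^-8, absolute error
// ~1e-15). No division in the hot path. Validated against base log in tests.

static double LOG_TAB[128];
static double INV_TAB[128];
static struct LogTabInit {
  LogTabInit() {
    for (int i = 0; i < 128; ++i) {
      double m = 1.0 + (i + 0.5) / 128.0;
      LOG_TAB[i] = std::log(m);
      INV_TAB[i] = 1.0 / m;
    }
  }
} log_tab_init;

static inline double fast_log(double x) {
  uint64_t bits;
  std::memcpy(&bits, &x, 8);
  int64_t e = (int64_t)((bits >> 52) & 0x7ffULL) - 1023;
  int idx = (int)((bits >> 45) & 0x7fULL);
  bits = (bits & 0x000fffffffffffffULL) | 0x3ff0000000000000ULL;
  double m;
  std::memcpy(&m, &bits, 8);
  double r = m * INV_TAB[idx] - 1.0;
  double r2 = r * r;
  double p = r - 0.5 * r2 + r2 * (r * (1.0 / 3) - 0.25 * r2 + 0.2 * r2 * r);
  return LOG_TAB[idx] + p + (double)e * 0.6931471805599453;
}

// [[Rcpp::export(name = ".fast_log_cpp")]]
NumericVector fast_log_cpp(NumericVector x) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = fast_log(x[i]);
  return out;
}

// ---- sphere form factor -----------------------------------------------------
// Squared amplitude Phi(x)^2, Phi(x) = 3(sin x - x cos x)/x^3, with a series
// fallback near x = 0 to avoid catastrophic cancellation.
static inline double phi2_from_sincos(double x, double s, double c) {
  double x2 = x * x;
  if (x < 0.35) {
    // sin x - x cos x ~ x^3/3 suffers catastrophic cancellation well beyond
    // tiny x; the alternating series 3(sin x - x cos x)/x^3 =
    // sum_m (-1)^m 6(m+1) x^{2m} / (2m+3)! is exact to ~1e-16 below 0.35
    double phi = 1.0 + x2 * (-1.0 / 10 + x2 * (1.0 / 280 + x2 * (-1.0 / 15120 +
                     x2 * (1.0 / 1330560 - x2 / 172972800.0))));
    return phi * phi;
  }
  double phi = 3.0 * (s - x * c) / (x2 * x);
  return phi * phi;
}

static inline double phi2(double x) { return phi2_from_sincos(x, std::sin(x), std::cos(x)); }

// [[Rcpp::export(name = ".phi2_cpp")]]
NumericVector phi2_cpp(NumericVector x) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = phi2(x[i]);
  return out;
}

// Fill Phi^2(q_i * R) for all i and return the vector sum. On an equally
// spaced q grid the sin/cos pairs are advanced by a rotation recurrence
// instead of per-point libm calls.
static double fill_comp(std::vector<double>& comp, const std::vector<double>& q,
                        double R, bool uniform, double q0, double dq) {
  int n = (int)q.size();
  double tot = 0.0;
  if (uniform && n > 1) {
    double x = q0 * R;
    double s = std::sin(x), c = std::cos(x);
    double sd = std::sin(dq * R), cd = std::cos(dq * R);
    for (int i = 0; i < n; ++i) {
      double v = phi2_from_sincos(q[i] * R, s, c);
      comp[i] = v;
      tot += v;
      double s2 = s * cd + c * sd;
      c = c * cd - s * sd;
      s = s2;
    }
  } else {
    for (int i = 0; i < n; ++i) { comp[i] = phi2(q[i] * R); tot += comp[i]; }
  }
  return tot;
}

static inline double sphere_volume(double R) {
  return 4.18879020478639098 * R * R * R;  // 4 pi R^3 / 3
}

// ---- data and state ---------------------------------------------------------

struct PoissonData {
  std::vector<double> q, y;
  double T;
  int N;
  std::vector<int> pos;        // indices with y > 0
  std::vector<double> ypos;
  bool uniform;
  double q0, dq;
};

struct Replica {
  std::vector<double> par;                 // length P
  std::vector<std::vector<double>> comp;   // K rows of Phi^2(q R_k)
  std::vector<double> comp_sum;            // per-row sums
  std::vector<double> lam;                 // Poisson means T * I(q)
  double lam_sum;
  double E;
  double logprior;
};

struct PriorSpec {
  double shape[3], scale[3];  // R, S, B
  double lognorm[3];
};

static inline double gamma_logpdf(const PriorSpec& pr, int type, double x) {
  return pr.lognorm[type] + (pr.shape[type] - 1.0) * std::log(x) - x / pr.scale[type];
}

// coordinate type: 0 = radius, 1 = scale, 2 = background
static inline int coord_type(int j, int K) {
  if (K == 0) return 2;
  if (j < K) return 0;
  if (j < 2 * K) return 1;
  return 2;
}

static double log_prior_par(const std::vector<double>& par, int K, const PriorSpec& pr) {
  double lp = 0.0;
  int P = (int)par.size();
  for (int j = 0; j < P; ++j) lp += gamma_logpdf(pr, coord_type(j, K), par[j]);
  lp += std::lgamma((double)K + 1.0);  // ordered-radii normalization
  return lp;
}

// E = (1/N) * (sum_i lam_i - sum_{y>0} y_i log lam_i), given the lam sum.
static double cost_logpart(const PoissonData& d, const std::vector<double>& lam) {
  double s2 = 0.0;
  int np = (int)d.pos.size();
  for (int k = 0; k < np; ++k) s2 += d.ypos[k] * fast_log(lam[d.pos[k]]);
  return s2;
}

// Recompute lam, sums and E of a replica exactly from its parameters.
static void refresh_replica(Replica& r, int K, const PoissonData& d) {
  double B = r.par[2 * K];  // also correct for K = 0 (single parameter)
  double s1 = 0.0;
  for (int i = 0; i < d.N; ++i) {
    double I = B;
    for (int k = 0; k < K; ++k)
      I += r.par[K + k] * sphere_volume(r.par[k]) * r.comp[k][i];
    r.lam[i] = d.T * I;
    s1 += r.lam[i];
  }
  r.lam_sum = s1;
  r.E = (s1 - cost_logpart(d, r.lam)) / d.N;
}

static void init_replica(Replica& r, const std::vector<double>& par, int K,
                         const PoissonData& d, const PriorSpec& pr) {
  r.par = par;
  r.comp.assign(K, std::vector<double>(d.N));
  r.comp_sum.assign(K, 0.0);
  r.lam.assign(d.N, 0.0);
  for (int k = 0; k < K; ++k)
    r.comp_sum[k] = fill_comp(r.comp[k], d.q, par[k], d.uniform, d.q0, d.dq);
  refresh_replica(r, K, d);
  r.logprior = log_prior_par(par, K, pr);
}

// One Metropolis update of coordinate j of replica r at inverse temperature
// beta. Proposals are multiplicative (random walk on the log scale); the
// Jacobian eps is part of the acceptance ratio. Radius proposals that break
// the non-increasing ordering are rejected (the prior lives on the ordered
// region). Returns 1 on accept.
static int update_coord(Replica& r, int j, int K, double beta, double step,
                        const PoissonData& d, const PriorSpec& pr,
                        std::vector<double>& lam_new, std::vector<double>& comp_new) {
  double x = r.par[j];
  double eps = norm_rand() * step;
  double xn = x * std::exp(eps);
  if (!std::isfinite(xn) || xn <= 0.0) return 0;
  int type = coord_type(j, K);
  if (type == 0) {
    if (j > 0 && xn > r.par[j - 1]) return 0;
    if (j < K - 1 && xn < r.par[j + 1]) return 0;
  }
  const int N = d.N;
  const int np = (int)d.pos.size();
  double s1n, logpart, comp_new_sum = 0.0;
  bool full = false;  // lam_new holds the complete proposed vector

  if (type == 0) {
    comp_new_sum = fill_comp(comp_new, d.q, xn, d.uniform, d.q0, d.dq);
    double a_old = d.T * r.par[K + j] * sphere_volume(x);
    double a_new = d.T * r.par[K + j] * sphere_volume(xn);
    const double* c_old = r.comp[j].data();
    double s1 = 0.0;
    for (int i = 0; i < N; ++i) {
      lam_new[i] = r.lam[i] + a_new * comp_new[i] - a_old * c_old[i];
      s1 += lam_new[i];
    }
    s1n = s1;
    logpart = cost_logpart(d, lam_new);
    full = true;
  } else if (type == 1) {
    int k = j - K;
    double c = d.T * (xn - x) * sphere_volume(r.par[k]);
    const double* ck = r.comp[k].data();
    s1n = r.lam_sum + c * r.comp_sum[k];
    double s2 = 0.0;
    for (int t = 0; t < np; ++t) {
      int i = d.pos[t];
      s2 += d.ypos[t] * fast_log(r.lam[i] + c * ck[i]);
    }
    logpart = s2;
  } else {
    double c = d.T * (xn - x);
    s1n = r.lam_sum + c * N;
    double s2 = 0.0;
    for (int t = 0; t < np; ++t)
      s2 += d.ypos[t] * fast_log(r.lam[d.pos[t]] + c);
    logpart = s2;
  }
  double En = (s1n - logpart) / N;
  if (!std::isfinite(En)) return 0;
  double dlp = gamma_logpdf(pr, type, xn) - gamma_logpdf(pr, type, x);
  double loga = -beta * N * (En - r.E) + dlp + eps;
  double u = unif_rand();
  if (u <= 0.0) return 0;
  if (std::log(u) < loga) {
    if (full) {
      r.lam.swap(lam_new);
      r.comp[j].swap(comp_new);
      r.comp_sum[j] = comp_new_sum;
    } else if (type == 1) {
      int k = j - K;
      double c = d.T * (xn - x) * sphere_volume(r.par[k]);
      const double* ck = r.comp[k].data();
      for (int i = 0; i < N; ++i) r.lam[i] += c * ck[i];
    } else {
      double c = d.T * (xn - x);
      for (int i = 0; i < N; ++i) r.lam[i] += c;
    }
    r.par[j] = xn;
    r.lam_sum = s1n;
    r.E = En;
    r.logprior += dlp;
    return 1;
  }
  return 0;
}

// [[Rcpp::export(name = ".remc_core_cpp")]]
List remc_core_cpp(NumericVector q, NumericVector y, double T, int K,
                   NumericVector prior_shape, NumericVector prior_scale,
                   NumericVector betas, NumericMatrix init, NumericMatrix step_init,
                   int n_burn, int n_samples, int exchange_interval, int first_parity,
                   bool do_metropolis, bool adapt, double target_accept,
                   bool record) {
  const int L = betas.size();
  const int P = init.ncol();
  if (init.nrow() != L) stop("init must have one row per replica");
  if (K < 0 || (K > 0 && P != 2 * K + 1) || (K == 0 && P != 1))
    stop("parameter layout does not match K");

  PoissonData d;
  d.q.assign(q.begin(), q.end());
  d.y.assign(y.begin(), y.end());
  d.T = T;
  d.N = q.size();
  for (int i = 0; i < d.N; ++i)
    if (d.y[i] > 0) { d.pos.push_back(i); d.ypos.push_back(d.y[i]); }
  d.q0 = d.q[0];
  d.dq = d.N > 1 ? (d.q[d.N - 1] - d.q[0]) / (d.N - 1) : 0.0;
  d.uniform = d.N > 2;
  for (int i = 1; i < d.N && d.uniform; ++i)
    if (std::fabs(d.q[i] - (d.q0 + i * d.dq)) > 1e-9 * (1.0 + std::fabs(d.q[i])))
      d.uniform = false;

  PriorSpec pr;
  for (int t = 0; t < 3; ++t) {
    pr.shape[t] = prior_shape[t];
    pr.scale[t] = prior_scale[t];
    pr.lognorm[t] = -std::lgamma(pr.shape[t]) - pr.shape[t] * std::log(pr.scale[t]);
  }

  std::vector<Replica> rep(L);
  for (int l = 0; l < L; ++l) {
    std::vector<double> par(P);
    for (int j = 0; j < P; ++j) {
      par[j] = init(l, j);
      if (!(par[j] > 0.0)) stop("initial parameters must be positive");
    }
    init_replica(rep[l], par, K, d, pr);
    if (!std::isfinite(rep[l].E)) stop("non-finite cost at initialization");
  }

  std::vector<std::vector<double>> lstep(L, std::vector<double>(P));
  for (int l = 0; l < L; ++l)
    for (int j = 0; j < P; ++j) lstep[l][j] = std::log(step_init(l, j));

  std::vector<double> lam_new(d.N), comp_new(d.N);

  IntegerMatrix acc(L, P), prop(L, P);          // retained phase only
  IntegerVector exch_acc(std::max(L - 1, 1)), exch_att(std::max(L - 1, 1));
  NumericVector trace, E_trace, lp_trace, chi2_trace;
  if (record && n_samples > 0) {
    trace = NumericVector((R_xlen_t)n_samples * P * L);
    trace.attr("dim") = IntegerVector::create(n_samples, P, L);
    E_trace = NumericVector((R_xlen_t)n_samples * L);
    E_trace.attr("dim") = IntegerVector::create(n_samples, L);
    lp_trace = NumericVector((R_xlen_t)n_samples * L);
    lp_trace.attr("dim") = IntegerVector::create(n_samples, L);
    chi2_trace = NumericVector(n_samples);
  }

  std::vector<long> adapt_count(L * P, 0);
  long n_total = (long)n_burn + n_samples;
  int exch_phase = 0;

  for (long t = 1; t <= n_total; ++t) {
    bool burn = t <= n_burn;
    if (do_metropolis) {
      for (int l = 0; l < L; ++l) {
        double beta = betas[l];
        for (int j = 0; j < P; ++j) {
          int a = update_coord(rep[l], j, K, beta, std::exp(lstep[l][j]), d, pr,
                               lam_new, comp_new);
          if (burn && adapt) {
            long& cnt = adapt_count[l * P + j];
            ++cnt;
            double gain = 5.0 / std::sqrt((double)cnt + 10.0);
            if (gain > 0.25) gain = 0.25;
            lstep[l][j] += gain * ((double)a - target_accept);
            if (lstep[l][j] > 5.0) lstep[l][j] = 5.0;
            if (lstep[l][j] < -20.0) lstep[l][j] = -20.0;
          }
          if (!burn) { prop(l, j) += 1; acc(l, j) += a; }
        }
      }
    }
    if (exchange_interval > 0 && (t % exchange_interval) == 0) {
      int parity = (first_parity + exch_phase) % 2;
      ++exch_phase;
      for (int l = parity; l + 1 < L; l += 2) {
        exch_att[l] += 1;
        double loga = d.N * (betas[l + 1] - betas[l]) * (rep[l + 1].E - rep[l].E);
        double u = unif_rand();
        bool ok = loga >= 0.0 || (u > 0.0 && std::log(u) < loga);
        if (ok) { std::swap(rep[l], rep[l + 1]); exch_acc[l] += 1; }
      }
    }
    // guard against drift of the incrementally updated means
    if (t % 1000 == 0)
      for (int l = 0; l < L; ++l) refresh_replica(rep[l], K, d);
    if (record && !burn) {
      long s = t - n_burn - 1;
      for (int l = 0; l < L; ++l) {
        for (int j = 0; j < P; ++j)
          trace[s + (R_xlen_t)n_samples * (j + (R_xlen_t)P * l)] = rep[l].par[j];
        E_trace[s + (R_xlen_t)n_samples * l] = rep[l].E;
        lp_trace[s + (R_xlen_t)n_samples * l] = rep[l].logprior;
      }
      const Replica& top = rep[L - 1];
      double c2 = 0.0;
      for (int i = 0; i < d.N; ++i) {
        double resid = d.y[i] - top.lam[i];
        c2 += resid * resid / top.lam[i];
      }
      chi2_trace[s] = c2;
    }
  }

  NumericMatrix final_par(L, P), final_step(L, P);
  NumericVector final_E(L), final_lp(L);
  for (int l = 0; l < L; ++l) {
    for (int j = 0; j < P; ++j) {
      final_par(l, j) = rep[l].par[j];
      final_step(l, j) = std::exp(lstep[l][j]);
    }
    final_E[l] = rep[l].E;
    final_lp[l] = rep[l].logprior;
  }

  return List::create(
    _["trace"] = trace, _["E"] = E_trace, _["logprior"] = lp_trace,
    _["chi2"] = chi2_trace, _["acc"] = acc, _["prop"] = prop,
    _["exch_acc"] = exch_acc, _["exch_att"] = exch_att,
    _["final_params"] = final_par, _["final_E"] = final_E,
    _["final_logprior"] = final_lp, _["final_step"] = final_step);
}
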