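// Random-walk MCMC for the binary-division coalescent time-of-origin
// model.  The population doubles each generation from one founder to
// N = 2^G cells; a branch from time t_u to t_v carries
// Poisson(mu * (2^-t_u - 2^-t_v)) mutations (the continuum limit of mu
// population-level mutations per generation placed uniformly on 2^t
// extant lineages); pairwise coalescence intensity is ln(2) * 2^-t.
// Full log-posterior recomputation per proposal keeps the kernel simple;
// tree sizes here (hundreds of nodes) make that affordable.

#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double LN2 = 0.6931471805599453;

struct Model {
  std::vector<int> parent;     // -1 for root; tips 0..n_tips-1
  std::vector<double> m;       // mutations on edge above node
  double m_root;               // mutations above the sample MRCA
  int n_tips, n_nodes, root;
  std::vector<int> outdeg;     // children per internal node
  double g_lo, g_hi, mu_rate;  // priors
};

// t holds times of internal nodes only, indexed node - root
static double log_post(const Model& mod, const std::vector<double>& t,
                       double G, double mu) {
  if (G < mod.g_lo || G > mod.g_hi || mu <= 0) return R_NegInf;
  const int root = mod.root;
  double tr = t[0];
  if (tr < 0 || tr >= G) return R_NegInf;

  // Jeffreys-type scale prior on mu with an exponential tail:
  // p(mu) proportional to mu^-1 * exp(-mu * mu_rate)
  double lp = -std::log(mu) - mod.mu_rate * mu;

  // founder -> MRCA edge
  double lam_r = mu * (1.0 - std::exp2(-tr));
  if (mod.m_root > 0) {
    if (lam_r <= 0) return R_NegInf;
    lp += mod.m_root * std::log(lam_r) - lam_r;
  } else {
    lp += -lam_r;
  }

  // branch mutation likelihood
  for (int v = 0; v < mod.n_nodes; ++v) {
    if (v == root) continue;
    double tv = (v < mod.n_tips) ? G : t[v - root];
    double tu = (mod.parent[v] == root) ? tr : t[mod.parent[v] - root];
    if (tv < tu) return R_NegInf;
    if (v >= mod.n_tips && tv >= G) return R_NegInf;
    double lam = mu * (std::exp2(-tu) - std::exp2(-tv));
    if (lam <= 0) {
      if (mod.m[v] > 0) return R_NegInf;
    } else {
      lp += mod.m[v] * std::log(lam) - lam;
    }
  }

  // coalescent prior: events backward from the tips (s = G - t)
  int n_int = mod.n_nodes - mod.n_tips;
  std::vector<std::pair<double, int> > ev(n_int);
  for (int k = 0; k < n_int; ++k)
    ev[k] = std::make_pair(G - t[k], mod.outdeg[root + k]);
  std::sort(ev.begin(), ev.end());
  double k_lin = mod.n_tips, prev_s = 0.0;
  double pow_prev = 1.0;                       // 2^prev_s
  for (int k = 0; k < n_int; ++k) {
    double s = ev[k].first;
    int d = ev[k].second;
    double pow_s = std::exp2(s);
    // exposure: C(k,2) * Integral_prev^s ln2 * 2^(x - G) dx
    lp += -(k_lin * (k_lin - 1) / 2.0) * std::exp2(-G) * (pow_s - pow_prev);
    // event density for (d - 1) simultaneous mergers
    lp += (d - 1) * (std::log(LN2) + (s - G) * LN2);
    k_lin -= (d - 1);
    prev_s = s;
    pow_prev = pow_s;
  }
  if (k_lin < 1 - 1e-9) return R_NegInf;       // over-coalesced (defensive)
  return lp;
}

// [[Rcpp::export]]
NumericMatrix run_coalescent_chain(IntegerVector parent0, int n_tips,
                                   NumericVector m, double m_root,
                                   int n_iter, int n_warmup,
                                   double g_lo, double g_hi,
                                   double mu_rate) {
  Model mod;
  mod.n_nodes = parent0.size();
  mod.n_tips = n_tips;
  mod.root = n_tips;                           // 0-based
  mod.parent.assign(parent0.begin(), parent0.end());
  mod.m.assign(m.begin(), m.end());
  mod.m_root = m_root;
  mod.g_lo = g_lo; mod.g_hi = g_hi; mod.mu_rate = mu_rate;
  mod.outdeg.assign(mod.n_nodes, 0);
  for (int v = 0; v < mod.n_nodes; ++v)
    if (mod.parent[v] >= 0) mod.outdeg[mod.parent[v]] += 1;

  int n_int = mod.n_nodes - n_tips;

  // deterministic init: times proportional to topological depth
  std::vector<int> depth(mod.n_nodes, 0);
  int max_depth = 1;
  for (int v = 0; v < mod.n_nodes; ++v) {      // parents precede children
    if (mod.parent[v] >= 0 && v >= n_tips) {
      depth[v] = depth[mod.parent[v]] + 1;
      if (depth[v] > max_depth) max_depth = depth[v];
    }
  }
  double G = 0.5 * (g_lo + g_hi);
  double span = std::min(12.0, G - 1.0);
  std::vector<double> t(n_int);
  for (int k = 0; k < n_int; ++k)
    t[k] = 0.5 + span * depth[mod.root + k] / (max_depth + 1.0);
  double total_m = m_root;
  for (int v = 0; v < mod.n_nodes; ++v) if (v != mod.root) total_m += mod.m[v];
  double mu = std::max(total_m / 2.0, 1.0);

  double lp = log_post(mod, t, G, mu);
  if (!std::isfinite(lp)) stop("invalid MCMC initialisation");

  NumericMatrix out(n_iter, 2 + n_int);
  const double step_mu = 0.15, step_g = 0.8, step_t = 0.6;
  int total = n_iter + n_warmup;
  for (int it = 0; it < total; ++it) {
    // mu: log random walk
    {
      double mu2 = mu * std::exp(R::rnorm(0, step_mu));
      double lp2 = log_post(mod, t, G, mu2);
      if (std::isfinite(lp2) &&
          R::runif(0, 1) < std::exp(lp2 - lp + std::log(mu2) - std::log(mu))) {
        mu = mu2; lp = lp2;
      }
    }
    // G: alternate a local random walk with an independence draw from
    // the (uniform) prior -- the G posterior is nearly flat, and the
    // independence proposal traverses it in one step
    {
      double G2 = (it % 2 == 0) ? G + R::rnorm(0, step_g)
                                : R::runif(g_lo, g_hi);
      double lp2 = log_post(mod, t, G2, mu);
      if (std::isfinite(lp2) && R::runif(0, 1) < std::exp(lp2 - lp)) {
        G = G2; lp = lp2;
      }
    }
    // node times
    for (int k = 0; k < n_int; ++k) {
      double old = t[k];
      t[k] = old + R::rnorm(0, step_t);
      double lp2 = log_post(mod, t, G, mu);
      if (std::isfinite(lp2) && R::runif(0, 1) < std::exp(lp2 - lp)) {
        lp = lp2;
      } else {
        t[k] = old;
      }
    }
    if (it >= n_warmup) {
      int r = it - n_warmup;
      out(r, 0) = mu;
      out(r, 1) = G;
      for (int k = 0; k < n_int; ++k) out(r, 2 + k) = t[k];
    }
  }
  return out;
}
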