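// Single-site MCMC sweeps for the disease-mapping samplers.
// All randomness comes from R's RNG stream (RNGScope via Rcpp attributes),
// so draws are reproducible through set.seed() on the R side.

#include <Rcpp.h>
using namespace Rcpp;

// Per-site log-likelihood contribution as a function of the site's linear
// predictor part u (site total eta = rest + u, plus the log E offset which is
// absorbed into Emu for the Poisson case).
// lik = 0: Poisson,  y*u - Emu * exp(rest + u)   (constants dropped)
// lik = 1: Gaussian test hook, -0.5 * (y - rest - u)^2 / s2
static inline double site_ll(double u, double y, double Emu, double rest,
                             int lik, double s2) {
  if (lik == 0) return y * u - Emu * std::exp(rest + u);
  double r = y - rest - u;
  return -0.5 * r * r / s2;
}

// One Metropolis sweep over an iid-normal random effect (the BYM
// "unstructured" term): prior N(0, prior_var), random-walk proposal.
// [[Rcpp::export]]
List sweep_iid_re(NumericVector val, NumericVector y, NumericVector Emu,
                  NumericVector rest, double prior_var, NumericVector step,
                  int lik, double gauss_sd) {
  int n = val.size();
  NumericVector v = clone(val);
  IntegerVector acc(n);
  double s2 = gauss_sd * gauss_sd;
  for (int i = 0; i < n; ++i) {
    double cur = v[i];
    double prop = cur + step[i] * R::norm_rand();
    double la = site_ll(prop, y[i], Emu[i], rest[i], lik, s2)
              - site_ll(cur, y[i], Emu[i], rest[i], lik, s2)
              - (prop * prop - cur * cur) / (2.0 * prior_var);
    if (!R_finite(la)) la = -INFINITY;  // reject wild proposals
    if (std::log(R::unif_rand()) < la) { v[i] = prop; acc[i] = 1; }
  }
  return List::create(_["value"] = v, _["accept"] = acc);
}

// One Metropolis sweep over the ICAR structured effect phi.
// Full-conditional prior: phi_i | phi_-i ~ N(mean of neighbours, 1/(tau d_i)).
// Adjacency in compressed form: neighbours of i are adj_idx[adj_ptr[i] ..
// adj_ptr[i+1]-1] (0-based). Isolated sites (d_i = 0) are skipped; they carry
// no structured effect.
// [[Rcpp::export]]
List sweep_icar_re(NumericVector val, NumericVector y, NumericVector Emu,
                   NumericVector rest, double tau,
                   IntegerVector adj_ptr, IntegerVector adj_idx,
                   NumericVector step, int lik, double gauss_sd) {
  int n = val.size();
  NumericVector v = clone(val);
  IntegerVector acc(n);
  double s2 = gauss_sd * gauss_sd;
  for (int i = 0; i < n; ++i) {
    int a = adj_ptr[i], b = adj_ptr[i + 1];
    int d = b - a;
    if (d == 0) continue;
    double nb_sum = 0.0;
    for (int k = a; k < b; ++k) nb_sum += v[adj_idx[k]];
    double m = nb_sum / d;
    double prec = tau * d;
    double cur = v[i];
    double prop = cur + step[i] * R::norm_rand();
    double la = site_ll(prop, y[i], Emu[i], rest[i], lik, s2)
              - site_ll(cur, y[i], Emu[i], rest[i], lik, s2)
              - 0.5 * prec * ((prop - m) * (prop - m) - (cur - m) * (cur - m));
    if (!R_finite(la)) la = -INFINITY;
    if (std::log(R::unif_rand()) < la) { v[i] = prop; acc[i] = 1; }
  }
  return List::create(_["value"] = v, _["accept"] = acc);
}

// One sweep of Metropolis-adjusted updates for the latent confounder U.
// Target per site: likelihood(u) + Gaussian conditional prior
//   N(c_i, 1/q_ii), c_i = mu_i - (1/q_ii) * sum_{j != i} Q_ij (U_j - mu_j).
// Proposal: Gaussian from a local quadratic (second-order Taylor) expansion
// of the Poisson log-likelihood at the current value; MH-corrected with the
// reverse-expansion proposal density. For the Gaussian likelihood hook the
// expansion is exact, so acceptance is identically 1.
// Q is passed in column-compressed (dgCMatrix) slots; Q is symmetric so
// columns double as rows.
// [[Rcpp::export]]
List sweep_confounder(NumericVector U, NumericVector y, NumericVector Emu,
                      NumericVector rest, NumericVector mu,
                      IntegerVector Qp, IntegerVector Qi, NumericVector Qx,
                      int lik, double gauss_sd) {
  int n = U.size();
  NumericVector v = clone(U);
  IntegerVector acc(n);
  double s2 = gauss_sd * gauss_sd;
  for (int i = 0; i < n; ++i) {
    double qii = 0.0, off = 0.0;
    for (int k = Qp[i]; k < Qp[i + 1]; ++k) {
      int j = Qi[k];
      if (j == i) qii = Qx[k];
      else off += Qx[k] * (v[j] - mu[j]);
    }
    if (qii <= 0.0) stop("non-positive conditional precision at site %d", i + 1);
    double ci = mu[i] - off / qii;
    double u0 = v[i];

    // forward proposal from expansion at u0
    double w0, g0;  // -f'' and f' of the likelihood part
    if (lik == 0) {
      w0 = Emu[i] * std::exp(rest[i] + u0);
      g0 = y[i] - w0;
    } else {
      w0 = 1.0 / s2;
      g0 = (y[i] - rest[i] - u0) / s2;
    }
    double P0 = qii + w0;
    double m0 = u0 + (g0 + qii * (ci - u0)) / P0;
    double up = m0 + R::norm_rand() / std::sqrt(P0);

    // reverse proposal from expansion at up
    double w1, g1;
    if (lik == 0) {
      w1 = Emu[i] * std::exp(rest[i] + up);
      g1 = y[i] - w1;
    } else {
      w1 = 1.0 / s2;
      g1 = (y[i] - rest[i] - up) / s2;
    }
    double P1 = qii + w1;
    double m1 = up + (g1 + qii * (ci - up)) / P1;

    double la = site_ll(up, y[i], Emu[i], rest[i], lik, s2)
              - site_ll(u0, y[i], Emu[i], rest[i], lik, s2)
              - 0.5 * qii * ((up - ci) * (up - ci) - (u0 - ci) * (u0 - ci))
              + R::dnorm(u0, m1, 1.0 / std::sqrt(P1), 1)
              - R::dnorm(up, m0, 1.0 / std::sqrt(P0), 1);
    if (!R_finite(la)) {
      stop("non-finite acceptance ratio in confounder update at site %d", i + 1);
    }
    if (std::log(R::unif_rand()) < la) { v[i] = up; acc[i] = 1; }
  }
  return List::create(_["value"] = v, _["accept"] = acc);
}
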