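// Batched per-trial marginal log-likelihood of the whole-report mixture
// model.  For every trial the discrete latent structure (report-order
// permutation, swap / cyclic-swap configuration, per-object guess states)
// is summed out exactly; the per-object guess layer is marginalised in
// closed form, so each trial costs 6 permutations x 6 error configurations
// x 3 object marginals (uncued), or 6 x 3 (cued, where the observed cue
// selection fixes the mapping).
//
// All angles arrive in radians; densities are per radian.

#include <Rcpp.h>
using namespace Rcpp;

static const int PERMS3[6][3] = {
  {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}
};
static const int SWAP_PAIRS3[3][2] = {{0, 1}, {0, 2}, {1, 2}};
static const int CYCLES3[2][3] = {{1, 2, 0}, {2, 0, 1}};  // sigma[o]

static const double U = 1.0 / (2.0 * M_PI);

// log(2*pi*I0(kappa)) via the exponentially scaled Bessel function
static inline double log_norm_const(double kappa) {
  return log(2.0 * M_PI) + log(R::bessel_i(kappa, 0.0, 2.0)) + kappa;
}

// [[Rcpp::export(name = ".wr_loglik_cpp")]]
NumericVector wr_loglik_cpp(NumericMatrix stim_col, NumericMatrix stim_loc,
                            NumericMatrix resp_col, NumericMatrix resp_loc,
                            IntegerVector cond, IntegerMatrix cue_perm,
                            IntegerVector par_index, NumericMatrix params,
                            NumericMatrix orderw) {
  const int n = stim_col.nrow();
  const int m = params.nrow();
  NumericVector out(n);

  std::vector<double> lnc(m), lnl(m);
  for (int j = 0; j < m; ++j) {
    lnc[j] = log_norm_const(params(j, 0));
    lnl[j] = log_norm_const(params(j, 1));
  }

  for (int i = 0; i < n; ++i) {
    const int j = par_index[i] - 1;
    const double kc = params(j, 0), kl = params(j, 1);
    const double ps = params(j, 2), pc = params(j, 3);
    const double gf0 = params(j, 4), go0 = params(j, 5);
    const double gfn = params(j, 6), gfs = params(j, 7);
    const double gon = params(j, 8), gos = params(j, 9);
    const double gfc = params(j, 10), goc = params(j, 11);
    const double pnone = 1.0 - ps - pc;

    // densities of slot s's responses around stimulus feature k
    double vc[3][3], vl[3][3];
    for (int s = 0; s < 3; ++s) {
      for (int k = 0; k < 3; ++k) {
        vc[s][k] = exp(kc * cos(resp_col(i, s) - stim_col(i, k)) - lnc[j]);
        vl[s][k] = exp(kl * cos(resp_loc(i, s) - stim_loc(i, k)) - lnl[j]);
      }
    }

    // error configurations: 0 none, 1..3 swap pairs, 4..5 cycles
    double prior_e[6] = {pnone, ps / 3.0, ps / 3.0, ps / 3.0, pc / 2.0, pc / 2.0};
    int sigma[6][3];
    for (int o = 0; o < 3; ++o) sigma[0][o] = o;
    for (int e = 0; e < 3; ++e) {
      for (int o = 0; o < 3; ++o) sigma[1 + e][o] = o;
      sigma[1 + e][SWAP_PAIRS3[e][0]] = SWAP_PAIRS3[e][1];
      sigma[1 + e][SWAP_PAIRS3[e][1]] = SWAP_PAIRS3[e][0];
    }
    for (int c = 0; c < 2; ++c)
      for (int o = 0; o < 3; ++o) sigma[4 + c][o] = CYCLES3[c][o];
    // guessing rates per configuration and object
    double GF[6][3], GO[6][3];
    for (int o = 0; o < 3; ++o) { GF[0][o] = gf0; GO[0][o] = go0; }
    for (int e = 0; e < 3; ++e) {
      for (int o = 0; o < 3; ++o) {
        bool in_swap = (o == SWAP_PAIRS3[e][0] || o == SWAP_PAIRS3[e][1]);
        GF[1 + e][o] = in_swap ? gfs : gfn;
        GO[1 + e][o] = in_swap ? gos : gon;
      }
    }
    for (int c = 0; c < 2; ++c)
      for (int o = 0; o < 3; ++o) { GF[4 + c][o] = gfc; GO[4 + c][o] = goc; }

    double lik = 0.0;
    if (cond[i] == 0) {  // uncued: marginalise the report order
      for (int p = 0; p < 6; ++p) {
        const double wp = orderw(j, p);
        if (wp <= 0.0) continue;
        // slot of object o under permutation p
        int slot_of[3];
        for (int s = 0; s < 3; ++s) slot_of[PERMS3[p][s]] = s;
        double sum_e = 0.0;
        for (int e = 0; e < 6; ++e) {
          if (prior_e[e] <= 0.0) continue;
          double prod = 1.0;
          for (int o = 0; o < 3; ++o) {
            const int s = slot_of[o];
            const double gf = GF[e][o], go = GO[e][o];
            const double mc = gf * U + (1.0 - gf) * vc[s][sigma[e][o]];
            const double ml = gf * U + (1.0 - gf) * vl[s][o];
            prod *= go * U * U + (1.0 - go) * mc * ml;
          }
          sum_e += prior_e[e] * prod;
        }
        lik += wp * sum_e;
      }
    } else {  // cued: mapping fixed by the observed cue selection
      const bool report_colour = (cond[i] == 2);  // cued by location
      double sum_e = 0.0;
      for (int e = 0; e < 6; ++e) {
        if (prior_e[e] <= 0.0) continue;
        double prod = 1.0;
        for (int s = 0; s < 3; ++s) {
          const int o = cue_perm(i, s) - 1;
          const double gf = GF[e][o], go = GO[e][o];
          const double v = report_colour ? vc[s][sigma[e][o]] : vl[s][sigma[e][o]];
          prod *= (go + (1.0 - go) * gf) * U + (1.0 - go) * (1.0 - gf) * v;
        }
        sum_e += prior_e[e] * prod;
      }
      lik = sum_e;
    }
    out[i] = log(lik);
  }
  return out;
}
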