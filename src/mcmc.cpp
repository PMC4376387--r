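// Metropolis-Hastings sampler for the three linear-fractional model
// structures (predicted / permuted / unconstrained) fitted jointly to the
// four dose-response-parameter series.  The chain runs in log-parameter
// space (flat prior on log-parameters over a finite box, positivity by
// construction) with independent Gaussian proposals whose scales are
// adapted during burn-in only, then frozen.  Uses R's RNG so seeding from
// R gives bitwise-reproducible chains.

#include <Rcpp.h>
using namespace Rcpp;

// model codes: 0 predicted (k=8), 1 permuted (k=8), 2 unconstrained (k=12)
// data: x (n), r (n), y (n x 4), s (n x 4) with series order
//       amax, amin, ic50, ratio

static inline double chi2_model(int model, const double *p,
                                const NumericVector &x, const NumericVector &r,
                                const NumericMatrix &y, const NumericMatrix &s) {
  const int n = x.size();
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double xi = x[i], ri = r[i];
    double amax, amin, ic50, ratio;
    if (model == 0) {
      amax = p[4] * ri * (p[0] + xi) / (p[1] + xi);
      amin = p[5] * ri * (p[2] + xi) / (p[3] + xi);
      ic50 = p[6] * (p[1] + xi) / (p[3] + xi);
      ratio = p[7] * (p[0] + xi) / (p[2] + xi);
    } else if (model == 1) {
      amax = p[4] * ri * (p[0] + xi) / (p[3] + xi);
      amin = p[5] * ri * (p[1] + xi) / (p[2] + xi);
      ic50 = p[6] * (p[2] + xi) / (p[1] + xi);
      ratio = p[7] * (p[3] + xi) / (p[0] + xi);
    } else {
      amax = p[8] * ri * (p[0] + xi) / (p[4] + xi);
      amin = p[9] * ri * (p[1] + xi) / (p[5] + xi);
      ic50 = p[10] * (p[2] + xi) / (p[6] + xi);
      ratio = p[11] * (p[3] + xi) / (p[7] + xi);
    }
    const double m[4] = {amax, amin, ic50, ratio};
    for (int j = 0; j < 4; ++j) {
      double d = (y(i, j) - m[j]) / s(i, j);
      acc += d * d;
    }
  }
  return acc;
}

// [[Rcpp::export]]
double chi2_cpp(int model, NumericVector params, NumericVector x,
                NumericVector r, NumericMatrix y, NumericMatrix s) {
  return chi2_model(model, params.begin(), x, r, y, s);
}

// [[Rcpp::export]]
List mh_sample_cpp(int model, NumericVector x, NumericVector r,
                   NumericMatrix y, NumericMatrix s,
                   NumericVector init_log, int iterations, int burnin,
                   double prop_scale, int thin,
                   double log_lo, double log_hi) {
  RNGScope scope;
  const int k = init_log.size();
  std::vector<double> cur(init_log.begin(), init_log.end());
  std::vector<double> nat(k), cand(k), cand_nat(k);
  std::vector<double> scales(k, prop_scale);

  for (int j = 0; j < k; ++j) nat[j] = std::exp(cur[j]);
  double cur_chi2 = chi2_model(model, nat.data(), x, r, y, s);

  const int keep = iterations / thin;
  NumericMatrix samples(keep, k);
  NumericVector loglik(keep);
  NumericVector best_par(k);
  double best_chi2 = cur_chi2;
  for (int j = 0; j < k; ++j) best_par[j] = cur[j];

  long accepted = 0, proposed = 0;
  int adapt_window = 200, adapt_acc = 0, adapt_n = 0;
  int kept = 0;

  for (int it = -burnin; it < iterations; ++it) {
    // one full-vector proposal per iteration
    bool inbox = true;
    for (int j = 0; j < k; ++j) {
      cand[j] = cur[j] + scales[j] * norm_rand();
      if (cand[j] < log_lo || cand[j] > log_hi) inbox = false;
      cand_nat[j] = std::exp(cand[j]);
    }
    ++proposed;
    bool accept = false;
    if (inbox) {
      double c2 = chi2_model(model, cand_nat.data(), x, r, y, s);
      double logratio = 0.5 * (cur_chi2 - c2);
      if (logratio >= 0.0 || unif_rand() < std::exp(logratio)) {
        accept = true;
        cur = cand;
        cur_chi2 = c2;
        if (c2 < best_chi2) {
          best_chi2 = c2;
          for (int j = 0; j < k; ++j) best_par[j] = cur[j];
        }
      }
    }
    if (accept) ++accepted;

    if (it < 0) {
      // adapt proposal scales toward ~25% acceptance during burn-in only
      adapt_acc += accept ? 1 : 0;
      if (++adapt_n == adapt_window) {
        double rate = (double)adapt_acc / adapt_window;
        double f = std::exp(0.5 * (rate - 0.25));
        for (int j = 0; j < k; ++j) {
          scales[j] = std::min(2.0, std::max(1e-4, scales[j] * f));
        }
        adapt_acc = 0; adapt_n = 0;
      }
      accepted = 0; proposed = 0;  // acceptance rate reported post burn-in
    } else if (it % thin == 0 && kept < keep) {
      for (int j = 0; j < k; ++j) samples(kept, j) = cur[j];
      loglik[kept] = -0.5 * cur_chi2;
      ++kept;
    }
  }

  return List::create(
    _["samples"] = samples,
    _["loglik"] = loglik,
    _["acceptance_rate"] = proposed > 0 ? (double)accepted / proposed : NA_REAL,
    _["best_log_par"] = best_par,
    _["best_chi2"] = best_chi2,
    _["final_scales"] = NumericVector(scales.begin(), scales.end()));
}
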