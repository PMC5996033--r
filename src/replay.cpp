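#include <Rcpp.h>
using namespace Rcpp;

// Trial-by-trial replay of the two learning models over one learning set.
//
// Value state:
//   NRL: 16 combination values, index (arm-1)*4 + (odor-1)*2 + (led-1).
//   WAM: 8 feature values, layout l1..l4, o1, o2, c1, c2.
// Values start at zero at the beginning of the set, are carried across
// days and multiplied by `decay` at each day boundary (decay = 1: plain
// carry-over).  Predictions use the pre-update state; the chosen option's
// entries are updated after feedback with the day's learning rate.

static inline double stable_logistic(double x) {
  // p = 1 / (1 + exp(-x)) without overflow for large |x|
  if (x >= 0.0) {
    return 1.0 / (1.0 + std::exp(-x));
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

static inline double log_logistic(double x) {
  // log(1 / (1 + exp(-x))) = -log1p(exp(-x)), stable both tails
  if (x >= 0.0) {
    return -std::log1p(std::exp(-x));
  }
  return x - std::log1p(std::exp(x));
}

static inline int nrl_idx(int arm, int odor, int led) {
  return (arm - 1) * 4 + (odor - 1) * 2 + (led - 1);
}

// Decision index from the pre-trial state for trial row t.
static inline double decision_index(const IntegerMatrix& feat, int t,
                                    const std::vector<double>& v,
                                    bool wam, const double* w) {
  int aa = feat(t, 0), oa = feat(t, 1), la = feat(t, 2);
  int ab = feat(t, 3), ob = feat(t, 4), lb = feat(t, 5);
  if (!wam) {
    return v[nrl_idx(aa, oa, la)] - v[nrl_idx(ab, ob, lb)];
  }
  double dl = v[aa - 1] - v[ab - 1];
  double dod = v[4 + oa - 1] - v[4 + ob - 1];
  double dc = v[6 + la - 1] - v[6 + lb - 1];
  return w[0] * dl + w[1] * dod + w[2] * dc;
}

static inline void apply_update(const IntegerMatrix& feat, int t, int chosen,
                                double reward, double alpha,
                                std::vector<double>& v, bool wam) {
  int arm = chosen == 0 ? feat(t, 0) : feat(t, 3);
  int odor = chosen == 0 ? feat(t, 1) : feat(t, 4);
  int led = chosen == 0 ? feat(t, 2) : feat(t, 5);
  if (!wam) {
    int i = nrl_idx(arm, odor, led);
    v[i] += alpha * (reward - v[i]);
  } else {
    v[arm - 1] += alpha * (reward - v[arm - 1]);
    v[4 + odor - 1] += alpha * (reward - v[4 + odor - 1]);
    v[6 + led - 1] += alpha * (reward - v[6 + led - 1]);
  }
}

// [[Rcpp::export(rng = false)]]
List replay_cpp(IntegerMatrix feat, IntegerVector chosen, IntegerVector reward,
                IntegerVector day, NumericVector alpha, NumericMatrix w,
                double beta, double decay, bool wam, bool keep_values) {
  int n = feat.nrow();
  int n_days = alpha.size();
  int n_vals = wam ? 8 : 16;
  std::vector<double> v(n_vals, 0.0);
  NumericVector index(n), p_a(n), ll(n);
  NumericVector day_ll(n_days);
  NumericMatrix values;
  if (keep_values) values = NumericMatrix(n, n_vals);

  int cur_day = 1;
  double wrow[3] = {0.0, 0.0, 0.0};
  if (wam) {
    wrow[0] = w(0, 0); wrow[1] = w(0, 1); wrow[2] = w(0, 2);
  }
  for (int t = 0; t < n; ++t) {
    int d = day[t];
    if (d != cur_day) {
      for (int j = 0; j < n_vals; ++j) v[j] *= decay;
      cur_day = d;
      if (wam) {
        wrow[0] = w(d - 1, 0); wrow[1] = w(d - 1, 1); wrow[2] = w(d - 1, 2);
      }
    }
    double idx = decision_index(feat, t, v, wam, wrow);
    double x = beta * idx;
    index[t] = idx;
    p_a[t] = stable_logistic(x);
    ll[t] = chosen[t] == 0 ? log_logistic(x) : log_logistic(-x);
    day_ll[d - 1] += ll[t];
    apply_update(feat, t, chosen[t], (double)reward[t], alpha[d - 1], v, wam);
    if (keep_values) {
      for (int j = 0; j < n_vals; ++j) values(t, j) = v[j];
    }
  }
  List out = List::create(_["index"] = index, _["p_a"] = p_a, _["ll"] = ll,
                          _["day_ll"] = day_ll);
  if (keep_values) out["values"] = values;
  return out;
}

// Total log-likelihood only (hot path for the optimizer).
// [[Rcpp::export(rng = false)]]
double ll_cpp(IntegerMatrix feat, IntegerVector chosen, IntegerVector reward,
              IntegerVector day, NumericVector alpha, NumericMatrix w,
              double beta, double decay, bool wam) {
  int n = feat.nrow();
  int n_vals = wam ? 8 : 16;
  std::vector<double> v(n_vals, 0.0);
  int cur_day = 1;
  double wrow[3] = {0.0, 0.0, 0.0};
  if (wam) {
    wrow[0] = w(0, 0); wrow[1] = w(0, 1); wrow[2] = w(0, 2);
  }
  double total = 0.0;
  for (int t = 0; t < n; ++t) {
    int d = day[t];
    if (d != cur_day) {
      for (int j = 0; j < n_vals; ++j) v[j] *= decay;
      cur_day = d;
      if (wam) {
        wrow[0] = w(d - 1, 0); wrow[1] = w(d - 1, 1); wrow[2] = w(d - 1, 2);
      }
    }
    double x = beta * decision_index(feat, t, v, wam, wrow);
    total += chosen[t] == 0 ? log_logistic(x) : log_logistic(-x);
    apply_update(feat, t, chosen[t], (double)reward[t], alpha[d - 1], v, wam);
  }
  return total;
}

// Exhaustive grid search sharing one (alpha, weights) point across days,
// beta per set.  Candidates are visited in lexicographic order of the
// parameter vector (alpha, beta, w_l, w_o, w_c) and only strict
// improvements are kept, so ties resolve to the lexicographically
// smallest argmax.  The decision-index trajectory does not depend on
// beta, so each (alpha, w) is replayed once and all betas are scored on
// the cached trajectory.
// [[Rcpp::export(rng = false)]]
List grid_search_cpp(IntegerMatrix feat, IntegerVector chosen,
                     IntegerVector reward, IntegerVector day,
                     NumericVector alpha_grid, NumericVector beta_grid,
                     NumericMatrix w_grid, double decay, bool wam,
                     int n_days) {
  int n = feat.nrow();
  int n_vals = wam ? 8 : 16;
  int n_w = wam ? w_grid.nrow() : 1;
  std::vector<double> idx_cache(n);
  std::vector<int> sign_chosen(n);
  for (int t = 0; t < n; ++t) sign_chosen[t] = chosen[t] == 0 ? 1 : -1;

  double best_ll = R_NegInf;
  double best_alpha = NA_REAL, best_beta = NA_REAL;
  double best_w[3] = {NA_REAL, NA_REAL, NA_REAL};

  for (int ia = 0; ia < alpha_grid.size(); ++ia) {
    double a = alpha_grid[ia];
    for (int iw = 0; iw < n_w; ++iw) {
      double wrow[3] = {0.0, 0.0, 0.0};
      if (wam) {
        wrow[0] = w_grid(iw, 0); wrow[1] = w_grid(iw, 1); wrow[2] = w_grid(iw, 2);
      }
      // replay once: decision indices are beta-free
      std::vector<double> v(n_vals, 0.0);
      int cur_day = 1;
      for (int t = 0; t < n; ++t) {
        int d = day[t];
        if (d != cur_day) {
          for (int j = 0; j < n_vals; ++j) v[j] *= decay;
          cur_day = d;
        }
        idx_cache[t] = decision_index(feat, t, v, wam, wrow);
        apply_update(feat, t, chosen[t], (double)reward[t], a, v, wam);
      }
      for (int ib = 0; ib < beta_grid.size(); ++ib) {
        double b = beta_grid[ib];
        double ll = 0.0;
        for (int t = 0; t < n; ++t) {
          ll += log_logistic(sign_chosen[t] * b * idx_cache[t]);
        }
        bool better = ll > best_ll;
        if (!better && ll == best_ll) {
          // lexicographic tie-break on (alpha, beta, w)
          if (a < best_alpha) better = true;
          else if (a == best_alpha && b < best_beta) better = true;
          else if (a == best_alpha && b == best_beta && wam) {
            for (int j = 0; j < 3; ++j) {
              if (wrow[j] < best_w[j]) { better = true; break; }
              if (wrow[j] > best_w[j]) break;
            }
          }
        }
        if (better) {
          best_ll = ll;
          best_alpha = a;
          best_beta = b;
          best_w[0] = wrow[0]; best_w[1] = wrow[1]; best_w[2] = wrow[2];
        }
      }
    }
  }
  return List::create(_["ll"] = best_ll, _["alpha"] = best_alpha,
                      _["beta"] = best_beta,
                      _["w"] = NumericVector::create(best_w[0], best_w[1],
                                                     best_w[2]));
}
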