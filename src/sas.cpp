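// Simulated-annealing sample-and-select core.
//
// Metropolis chain over N-member sub-ensembles of a conformer library:
// each step proposes swapping one member for a non-member (or, a fraction
// of the time, two members for two non-members, which crosses the barriers
// of the single-swap landscape), the cost is the mean squared scaled
// residual between ensemble-averaged predictions and measurements
// (per-construct least-squares scales optionally refit at every
// evaluation), and the effective temperature is multiplied by a cooling
// factor each step down to a floor. Uses R's RNG so results are
// reproducible through set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// Cost of the ensemble whose per-record prediction sums are in `s`
// (divide by n_members for the mean). Fills `scales` when refitting.
static double ensemble_cost(const NumericVector& s, int n_members,
                            const NumericVector& dexp,
                            const IntegerVector& cidx, int n_constructs,
                            bool refit, NumericVector& scales,
                            std::vector<double>& num,
                            std::vector<double>& den) {
  const int R = s.size();
  if (refit) {
    std::fill(num.begin(), num.end(), 0.0);
    std::fill(den.begin(), den.end(), 0.0);
    for (int r = 0; r < R; ++r) {
      const double m = s[r] / n_members;
      const int j = cidx[r];
      num[j] += dexp[r] * m;
      den[j] += m * m;
    }
    for (int j = 0; j < n_constructs; ++j)
      scales[j] = den[j] > 0 ? num[j] / den[j] : 0.0;
  }
  double cost = 0.0;
  for (int r = 0; r < R; ++r) {
    const double resid = scales[cidx[r]] * (s[r] / n_members) - dexp[r];
    cost += resid * resid;
  }
  return cost / R;
}

// [[Rcpp::export(name = ".sas_core")]]
List sas_core(const NumericMatrix& pred,     // records x conformers
              const NumericVector& dexp,     // measured couplings
              const IntegerVector& cidx,     // construct index per record, 0-based
              int n_constructs,
              IntegerVector init_members,    // 1-based, length N
              int n_steps, double t0, double cool, double t_floor,
              bool refit, NumericVector fixed_scales,
              int checkpoint_every, double pair_move_prob) {
  const int R = pred.nrow(), C = pred.ncol();
  const int N = init_members.size();
  RNGScope scope;

  std::vector<int> members(N);
  std::vector<bool> in_set(C, false);
  NumericVector s(R, 0.0);
  for (int k = 0; k < N; ++k) {
    members[k] = init_members[k] - 1;
    in_set[members[k]] = true;
    for (int r = 0; r < R; ++r) s[r] += pred(r, members[k]);
  }

  NumericVector scales(n_constructs);
  if (!refit)
    for (int j = 0; j < n_constructs; ++j) scales[j] = fixed_scales[j];
  std::vector<double> num(n_constructs), den(n_constructs);

  double cost = ensemble_cost(s, N, dexp, cidx, n_constructs, refit,
                              scales, num, den);
  double best_cost = cost;
  std::vector<int> best_members(members);
  std::vector<double> trace;
  trace.reserve(n_steps / checkpoint_every + 2);
  trace.push_back(best_cost);

  double temp = t0;
  NumericVector s_new(R);
  const bool pair_ok = (N >= 2) && (C - N >= 2);
  for (int step = 0; step < n_steps; ++step) {
    const bool pair_move = pair_ok && unif_rand() < pair_move_prob;
    // replace one (or two) members with uniformly chosen non-members
    const int slot = (int)(unif_rand() * N);
    int slot2 = -1;
    if (pair_move) {
      do { slot2 = (int)(unif_rand() * N); } while (slot2 == slot);
    }
    int cand;
    do { cand = (int)(unif_rand() * C); } while (in_set[cand]);
    int cand2 = -1;
    if (pair_move) {
      do {
        cand2 = (int)(unif_rand() * C);
      } while (in_set[cand2] || cand2 == cand);
    }
    const int old = members[slot];
    const int old2 = pair_move ? members[slot2] : -1;
    for (int r = 0; r < R; ++r) {
      double v = s[r] - pred(r, old) + pred(r, cand);
      if (pair_move) v += pred(r, cand2) - pred(r, old2);
      s_new[r] = v;
    }
    const double new_cost = ensemble_cost(s_new, N, dexp, cidx,
                                          n_constructs, refit, scales,
                                          num, den);
    const double dc = new_cost - cost;
    if (dc <= 0 || unif_rand() < std::exp(-dc / temp)) {
      members[slot] = cand;
      in_set[old] = false;
      in_set[cand] = true;
      if (pair_move) {
        members[slot2] = cand2;
        in_set[old2] = false;
        in_set[cand2] = true;
      }
      std::copy(s_new.begin(), s_new.end(), s.begin());
      cost = new_cost;
      if (cost < best_cost) {
        best_cost = cost;
        best_members.assign(members.begin(), members.end());
      }
    }
    temp *= cool;
    if (temp < t_floor) temp = t_floor;
    if ((step + 1) % checkpoint_every == 0) trace.push_back(best_cost);
  }

  IntegerVector out_members(N);
  for (int k = 0; k < N; ++k) out_members[k] = best_members[k] + 1;
  return List::create(_["members"] = out_members,
                      _["best_cost"] = best_cost,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}
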