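#include <Rcpp.h>
using namespace Rcpp;

// Draw one index (0-based) from an unnormalised weight vector using R's RNG.
static int draw_cat(const std::vector<double>& w, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  int n = (int)w.size();
  for (int i = 0; i < n; ++i) {
    acc += w[i];
    if (u <= acc) return i;
  }
  return n - 1; // guard against rounding
}

// One choice under the (first_probs, trans, m) policy.
// current < 0 means "first choice of the bout".
static int one_choice(int current,
                      const std::vector<bool>& visited,
                      const NumericVector& first_probs,
                      const NumericMatrix& trans,
                      double m,
                      int n_flowers) {
  std::vector<double> base(n_flowers);
  if (current < 0) {
    for (int j = 0; j < n_flowers; ++j) base[j] = first_probs[j];
  } else {
    for (int j = 0; j < n_flowers; ++j) base[j] = trans(current, j);
  }
  bool avoid = (m > 0.0) && (unif_rand() < m);
  if (avoid) {
    // renormalise base mass over unvisited flowers; if the base policy puts
    // no mass there, fall back to uniform over unvisited
    std::vector<double> w(n_flowers, 0.0);
    double tot = 0.0;
    for (int j = 0; j < n_flowers; ++j)
      if (!visited[j]) { w[j] = base[j]; tot += base[j]; }
    if (tot <= 0.0) {
      tot = 0.0;
      for (int j = 0; j < n_flowers; ++j)
        if (!visited[j]) { w[j] = 1.0; tot += 1.0; }
    }
    return draw_cat(w, tot);
  }
  double tot = 0.0;
  for (int j = 0; j < n_flowers; ++j) tot += base[j];
  return draw_cat(base, tot);
}

// Simulate n_bouts foraging bouts and return per-bout RAM metrics.
// Columns: n_visits, total_revisits, correct_before_first_revisit,
//          correct_in_first_eight (NA when n_visits < 8), complete (0/1).
// [[Rcpp::export]]
NumericMatrix sim_bouts_metrics_cpp(int n_bouts,
                                    NumericVector first_probs,
                                    NumericMatrix trans,
                                    double m,
                                    int max_visits) {
  int n_flowers = first_probs.size();
  NumericMatrix out(n_bouts, 5);
  for (int b = 0; b < n_bouts; ++b) {
    std::vector<bool> visited(n_flowers, false);
    int current = -1, distinct = 0, n_visits = 0;
    int revisits = 0, first_revisit = 0, correct8 = 0;
    while (distinct < n_flowers && n_visits < max_visits) {
      int j = one_choice(current, visited, first_probs, trans, m, n_flowers);
      ++n_visits;
      if (visited[j]) {
        ++revisits;
        if (first_revisit == 0) first_revisit = n_visits;
      } else {
        visited[j] = true;
        ++distinct;
        if (n_visits <= 8) ++correct8;
      }
      current = j;
    }
    out(b, 0) = n_visits;
    out(b, 1) = revisits;
    out(b, 2) = (first_revisit > 0) ? (first_revisit - 1) : n_visits;
    out(b, 3) = (n_visits >= 8) ? correct8 : NA_REAL;
    out(b, 4) = (distinct == n_flowers) ? 1.0 : 0.0;
  }
  return out;
}

// Simulate n_bouts bouts and return the visit sequences (1-based flower ids).
// [[Rcpp::export]]
List sim_bouts_seq_cpp(int n_bouts,
                       NumericVector first_probs,
                       NumericMatrix trans,
                       double m,
                       int max_visits,
                       double quit_hazard) {
  int n_flowers = first_probs.size();
  List out(n_bouts);
  for (int b = 0; b < n_bouts; ++b) {
    std::vector<bool> visited(n_flowers, false);
    std::vector<int> seq;
    seq.reserve(2 * n_flowers);
    int current = -1, distinct = 0;
    while (distinct < n_flowers && (int)seq.size() < max_visits) {
      if (quit_hazard > 0.0 && !seq.empty() && unif_rand() < quit_hazard)
        break;
      int j = one_choice(current, visited, first_probs, trans, m, n_flowers);
      seq.push_back(j + 1);
      if (!visited[j]) { visited[j] = true; ++distinct; }
      current = j;
    }
    out[b] = IntegerVector(seq.begin(), seq.end());
  }
  return out;
}
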