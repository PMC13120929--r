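#include <Rcpp.h>
using namespace Rcpp;

// Any date in [s, e) within dates[from, to) (sorted ascending)?
static inline bool has_in_window(const int *dates, int from, int to,
                                 int s, int e) {
  int lo = from, hi = to;
  while (lo < hi) {
    int mid = lo + (hi - lo) / 2;
    if (dates[mid] < s) lo = mid + 1; else hi = mid;
  }
  return lo < to && dates[lo] < e;
}

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Vectorized membership test: for each i, does patient pat[i] (1-based) have
// an event date in [start[i], end[i])? dates/offsets form a CSR layout over
// patients (offsets 0-based, length n_patients + 1).
// [[Rcpp::export]]
LogicalVector window_hit(IntegerVector dates, IntegerVector offsets,
                         IntegerVector pat, IntegerVector start,
                         IntegerVector end) {
  int n = pat.size();
  LogicalVector out(n);
  const int *d = dates.begin();
  for (int i = 0; i < n; ++i) {
    int p = pat[i] - 1;
    out[i] = has_in_window(d, offsets[p], offsets[p + 1], start[i], end[i]);
  }
  return out;
}

// Matched-control resampling kernel for one ordered event pair.
//
// For each of n_resamples draws: visit the exposed cases in random order and
// assign each a control sampled uniformly from the lowest non-empty
// relaxation tier of its candidate list (sampling without replacement across
// the whole control set unless with_replacement). The control's pseudo-anchor
// is the date at which its age equals the case's age at exposure, clamped
// into the control's follow-up; the control scores an outcome if it has a
// B event within [anchor + lo, anchor + hi). Returns the per-resample count
// of controls with an outcome plus the first draw's control assignment.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List pair_resample(List cand, List tier_ends, IntegerVector anchor_age_days,
                   IntegerVector birth, IntegerVector first_visit,
                   IntegerVector last_visit, IntegerVector b_dates,
                   IntegerVector b_offsets, int lo, int hi, int n_resamples,
                   bool with_replacement) {
  int n_cases = cand.size();
  int n_patients = birth.size();
  IntegerVector k_out(n_resamples);
  IntegerVector first_controls(n_cases, NA_INTEGER);
  LogicalVector first_outcome(n_cases);
  std::vector<char> used(n_patients, 0);
  std::vector<int> order(n_cases), avail;
  const int *bd = b_dates.begin();

  // pre-extract candidate structures
  std::vector<IntegerVector> cvec(n_cases), tends(n_cases);
  for (int i = 0; i < n_cases; ++i) {
    cvec[i] = as<IntegerVector>(cand[i]);
    tends[i] = as<IntegerVector>(tier_ends[i]);
  }

  for (int r = 0; r < n_resamples; ++r) {
    std::fill(used.begin(), used.end(), 0);
    for (int i = 0; i < n_cases; ++i) order[i] = i;
    // Fisher-Yates with R's RNG
    for (int i = n_cases - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    int k = 0;
    for (int oi = 0; oi < n_cases; ++oi) {
      int i = order[oi];
      const IntegerVector &cv = cvec[i];
      const IntegerVector &te = tends[i];
      int chosen = -1;
      int from = 0;
      for (int t = 0; t < te.size(); ++t) {
        int to = te[t];
        if (with_replacement) {
          if (to > from) {
            int j = from + (int)(unif_rand() * (to - from));
            if (j >= to) j = to - 1;
            chosen = cv[j];
            break;
          }
        } else {
          avail.clear();
          for (int j = from; j < to; ++j) {
            if (!used[cv[j] - 1]) avail.push_back(cv[j]);
          }
          if (!avail.empty()) {
            int j = (int)(unif_rand() * avail.size());
            if (j >= (int)avail.size()) j = (int)avail.size() - 1;
            chosen = avail[j];
            break;
          }
        }
        from = to;
      }
      if (chosen < 0) {
        return List::create(_["exhausted"] = true, _["case"] = i + 1,
                            _["resample"] = r + 1);
      }
      if (!with_replacement) used[chosen - 1] = 1;
      int p = chosen - 1;
      int anchor = clampi(birth[p] + anchor_age_days[i], first_visit[p],
                          last_visit[p]);
      bool out = has_in_window(bd, b_offsets[p], b_offsets[p + 1],
                               anchor + lo, anchor + hi);
      if (out) ++k;
      if (r == 0) {
        first_controls[i] = chosen;
        first_outcome[i] = out;
      }
    }
    k_out[r] = k;
  }
  return List::create(_["exhausted"] = false, _["k"] = k_out,
                      _["first_controls"] = first_controls,
                      _["first_outcome"] = first_outcome);
}
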