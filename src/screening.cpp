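#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Retrospective active-learning screening loop over a precomputed feature
// matrix. Each iteration: query = mean(relevant rows read) - mean(irrelevant
// rows read); score unscreened rows by cosine to the query; read the
// top-scoring row (ties -> smallest id_rank; zero-norm cosines are
// undefined and rank below every defined score, encoded NaN).
//
// F: m x n feature matrix; relevant: per-row label; seed_rows: 1-based rows
// of the two relevant seeds; budget <= 0 means none (run to full recall);
// id_rank: 1-based lexicographic rank of each row's article id.
// keep_scores: retain the pre-selection score snapshot of every post-seed
// step (steps x m; NA = already screened, NaN = undefined).
// [[Rcpp::export]]
List cpp_run_screening(NumericMatrix F, LogicalVector relevant,
                       IntegerVector seed_rows, int budget, bool keep_scores,
                       IntegerVector id_rank) {
  const int m = F.nrow(), n = F.ncol();

  // row-major copy for cache-friendly row dot products
  std::vector<double> R((size_t)m * n), rownorm(m);
  for (int i = 0; i < m; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      double v = F(i, j);
      R[(size_t)i * n + j] = v;
      s += v * v;
    }
    rownorm[i] = std::sqrt(s);
  }

  int P = 0;
  for (int i = 0; i < m; ++i) P += relevant[i] ? 1 : 0;

  std::vector<bool> screened(m, false);
  std::vector<double> sum_rel(n, 0.0), sum_irr(n, 0.0), q(n);
  int n_rel = 0, n_irr = 0, rel_remaining = P;

  std::vector<int> order;
  std::vector<double> sel_score;
  std::vector<double> history;
  order.reserve(m);

  for (int s = 0; s < 2; ++s) {
    int i = seed_rows[s] - 1;
    screened[i] = true;
    for (int j = 0; j < n; ++j) sum_rel[j] += R[(size_t)i * n + j];
    ++n_rel;
    --rel_remaining;
    order.push_back(i + 1);
    sel_score.push_back(NA_REAL);
  }

  int reads = 2;
  int unscreened = m - 2;
  while (rel_remaining > 0 && unscreened > 0 &&
         (budget <= 0 || reads < budget)) {
    double qn = 0.0;
    for (int j = 0; j < n; ++j) {
      q[j] = sum_rel[j] / n_rel - (n_irr > 0 ? sum_irr[j] / n_irr : 0.0);
      qn += q[j] * q[j];
    }
    qn = std::sqrt(qn);

    int best = -1;
    bool best_defined = false;
    double best_score = 0.0;
    for (int i = 0; i < m; ++i) {
      if (screened[i]) {
        if (keep_scores) history.push_back(NA_REAL);
        continue;
      }
      bool defined = qn > 0.0 && rownorm[i] > 0.0;
      double sc = R_NaN;
      if (defined) {
        double dot = 0.0;
        const double* row = &R[(size_t)i * n];
        for (int j = 0; j < n; ++j) dot += q[j] * row[j];
        sc = dot / (qn * rownorm[i]);
      }
      if (keep_scores) history.push_back(sc);
      bool take;
      if (best < 0)
        take = true;
      else if (defined != best_defined)
        take = defined;
      else if (defined && sc != best_score)
        take = sc > best_score;
      else
        take = id_rank[i] < id_rank[best];
      if (take) {
        best = i;
        best_defined = defined;
        best_score = sc;
      }
    }

    screened[best] = true;
    if (relevant[best]) {
      for (int j = 0; j < n; ++j) sum_rel[j] += R[(size_t)best * n + j];
      ++n_rel;
      --rel_remaining;
    } else {
      for (int j = 0; j < n; ++j) sum_irr[j] += R[(size_t)best * n + j];
      ++n_irr;
    }
    order.push_back(best + 1);
    sel_score.push_back(best_defined ? best_score : R_NaN);
    ++reads;
    --unscreened;
  }

  int stop_reason = rel_remaining == 0 ? 1 : 2;

  SEXP hist = R_NilValue;
  if (keep_scores) {
    int nsteps = (int)(history.size() / m);
    NumericMatrix H(nsteps, m);
    for (int s = 0; s < nsteps; ++s)
      for (int i = 0; i < m; ++i) H(s, i) = history[(size_t)s * m + i];
    hist = H;
  }
  return List::create(_["order"] = wrap(order), _["score"] = wrap(sel_score),
                      _["stop_reason"] = stop_reason, _["history"] = hist);
}
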