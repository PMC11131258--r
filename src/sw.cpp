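#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman, Gotoh). Sequences arrive as
// 1-based integer codes into the substitution matrix; a gap of length L
// costs gap_open + L * gap_extend (NCBI blastp convention for open=11,
// extend=1). Traceback tie-break at an H cell: diagonal > up > left > stop;
// inside a gap state, closing the gap (coming from H) is preferred on ties
// so reported gaps are as short as possible.

static inline double subscore(const NumericMatrix& mat, int qi, int si) {
  return mat(qi - 1, si - 1);
}

// [[Rcpp::export]]
List sw_align_c(IntegerVector q, IntegerVector s, NumericMatrix mat,
                double gap_open, double gap_extend, bool traceback) {
  const int m = q.size(), n = s.size();
  const double gopen1 = gap_open + gap_extend;  // cost of a length-1 gap
  if (m == 0 || n == 0) {
    return List::create(_["score"] = 0.0,
                        _["q_span"] = IntegerVector::create(0, 0),
                        _["s_span"] = IntegerVector::create(0, 0),
                        _["q_aln"] = IntegerVector(0),
                        _["s_aln"] = IntegerVector(0));
  }
  std::vector<double> H((m + 1) * (n + 1), 0.0);
  std::vector<double> E((m + 1) * (n + 1), R_NegInf);  // gap in query (left)
  std::vector<double> F((m + 1) * (n + 1), R_NegInf);  // gap in subject (up)
  auto idx = [n](int i, int j) { return i * (n + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int k = idx(i, j);
      double e = std::max(H[idx(i, j - 1)] - gopen1, E[idx(i, j - 1)] - gap_extend);
      double f = std::max(H[idx(i - 1, j)] - gopen1, F[idx(i - 1, j)] - gap_extend);
      double d = H[idx(i - 1, j - 1)] + subscore(mat, q[i - 1], s[j - 1]);
      double h = std::max(0.0, std::max(d, std::max(e, f)));
      E[k] = e; F[k] = f; H[k] = h;
      if (h > best) { best = h; bi = i; bj = j; }  // first maximum kept
    }
  }

  IntegerVector qspan(2), sspan(2);
  std::vector<int> qa, sa;
  if (best > 0.0 && traceback) {
    int i = bi, j = bj;
    int state = 0;  // 0 = H, 1 = E (left), 2 = F (up)
    while (i > 0 && j > 0) {
      const int k = idx(i, j);
      if (state == 0) {
        if (H[k] == 0.0) break;
        double d = H[idx(i - 1, j - 1)] + subscore(mat, q[i - 1], s[j - 1]);
        if (H[k] == d) {
          qa.push_back(i); sa.push_back(j); --i; --j;
        } else if (H[k] == F[k]) {
          state = 2;
        } else {
          state = 1;
        }
      } else if (state == 1) {  // gap in query, consume subject char j
        const int k2 = idx(i, j - 1);
        qa.push_back(NA_INTEGER); sa.push_back(j);
        if (E[k] == H[k2] - gopen1) state = 0; else state = 1;
        --j;
      } else {  // gap in subject, consume query char i
        const int k2 = idx(i - 1, j);
        qa.push_back(i); sa.push_back(NA_INTEGER);
        if (F[k] == H[k2] - gopen1) state = 0; else state = 2;
        --i;
      }
    }
    std::reverse(qa.begin(), qa.end());
    std::reverse(sa.begin(), sa.end());
    qspan[0] = i + 1; qspan[1] = bi;
    sspan[0] = j + 1; sspan[1] = bj;
  } else if (best > 0.0) {
    qspan[0] = qspan[1] = bi;
    sspan[0] = sspan[1] = bj;
  } else {
    qspan[0] = qspan[1] = 0;
    sspan[0] = sspan[1] = 0;
  }
  return List::create(_["score"] = best,
                      _["q_span"] = qspan,
                      _["s_span"] = sspan,
                      _["q_aln"] = wrap(qa),
                      _["s_aln"] = wrap(sa));
}

// Score-only pass over many subjects with rolling rows; used to scan ORF
// databases before the (more expensive) traceback on significant hits.
// [[Rcpp::export]]
NumericVector sw_score_many_c(IntegerVector q, List subjects, NumericMatrix mat,
                              double gap_open, double gap_extend) {
  const int m = q.size();
  const double gopen1 = gap_open + gap_extend;
  const int nsub = subjects.size();
  NumericVector out(nsub);
  for (int t = 0; t < nsub; ++t) {
    IntegerVector s = subjects[t];
    const int n = s.size();
    if (m == 0 || n == 0) { out[t] = 0.0; continue; }
    std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
    std::vector<double> Eprev(n + 1, R_NegInf), Ecur(n + 1, R_NegInf);
    std::vector<double> Fcur(n + 1, R_NegInf), Fprev(n + 1, R_NegInf);
    double best = 0.0;
    for (int i = 1; i <= m; ++i) {
      Hcur[0] = 0.0; Ecur[0] = R_NegInf; Fcur[0] = R_NegInf;
      for (int j = 1; j <= n; ++j) {
        double e = std::max(Hcur[j - 1] - gopen1, Ecur[j - 1] - gap_extend);
        double f = std::max(Hprev[j] - gopen1, Fprev[j] - gap_extend);
        double d = Hprev[j - 1] + subscore(mat, q[i - 1], s[j - 1]);
        double h = std::max(0.0, std::max(d, std::max(e, f)));
        Ecur[j] = e; Fcur[j] = f; Hcur[j] = h;
        if (h > best) best = h;
      }
      std::swap(Hprev, Hcur);
      std::swap(Eprev, Ecur);
      std::swap(Fprev, Fcur);
    }
    out[t] = best;
  }
  return out;
}
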