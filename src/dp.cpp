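#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Profile-HMM dynamic programming over a glocal ("Plan-7-lite") architecture:
// the model is traversed in full through match/delete states, while sequence
// residues outside the aligned core are absorbed by free flanking loop states
// that emit at the null frequency (zero log-odds contribution, unit-probability
// loop transitions).  Scores are log-odds against the null model, computed in
// natural log and converted to bits by the R wrappers.
//
// Transition matrix layout (rows 0..M, columns):
//   0 MM: M_k -> M_{k+1}   (row 0: B -> M_1; row M: M_M -> E)
//   1 MI: M_k -> I_k       (row 0: B -> I_0)
//   2 MD: M_k -> D_{k+1}   (row 0: B -> D_1; row M unused, -Inf)
//   3 IM: I_k -> M_{k+1}   (row M: I_M -> E)
//   4 II: I_k -> I_k
//   5 DM: D_k -> M_{k+1}   (row M: D_M -> E)
//   6 DD: D_k -> D_{k+1}
// All inputs are natural-log probabilities (-Inf encodes probability zero).
// I_0 emits at null frequency (log-odds 0), matching the HMMER3 node-0 block.
// B may fire after any number of flank residues, so entry terms re-enter at
// every sequence position; likewise E exits at every position.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double logadd(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  if (a < b) std::swap(a, b);
  return a + log1p(std::exp(b - a));
}

static inline double max3(double a, double b, double c) {
  return std::max(a, std::max(b, c));
}

// match_lodds(k, a) = log match_emission - log null, M x K, precomputed in R;
// ins_lodds likewise; seq holds 0-based residue codes.

// [[Rcpp::export]]
double forward_lodds_cpp(NumericMatrix match_lodds, NumericMatrix ins_lodds,
                         NumericMatrix ltr, IntegerVector seq) {
  const int M = match_lodds.nrow();
  const int L = seq.size();
  std::vector<double> vm(M + 1, NEG_INF), vi(M + 1, NEG_INF), vd(M + 1, NEG_INF);
  std::vector<double> pm(M + 1, NEG_INF), pi(M + 1, NEG_INF), pd(M + 1, NEG_INF);
  double vi0 = NEG_INF, pi0;

  // i = 0: nothing consumed; only the B -> D_1 -> ... -> D_M chain is live
  vd[1] = ltr(0, 2);
  for (int k = 2; k <= M; ++k) vd[k] = vd[k - 1] + ltr(k - 1, 6);
  double end = vd[M] + ltr(M, 5);  // all-delete traversal

  for (int i = 1; i <= L; ++i) {
    pm.swap(vm); pi.swap(vi); pd.swap(vd); pi0 = vi0;
    const int a = seq[i - 1];
    vi0 = logadd(ltr(0, 1), pi0 + ltr(0, 4));
    for (int k = 1; k <= M; ++k) {
      double m = logadd(logadd(pm[k - 1] + ltr(k - 1, 0), pi[k - 1] + ltr(k - 1, 3)),
                        pd[k - 1] + ltr(k - 1, 5));
      if (k == 1) m = logadd(m, logadd(ltr(0, 0), pi0 + ltr(0, 3)));
      vm[k] = m + match_lodds(k - 1, a);
      vi[k] = logadd(pm[k] + ltr(k, 1), pi[k] + ltr(k, 4)) + ins_lodds(k - 1, a);
      // D_k is silent: fed from the current column; D_1 only from B
      vd[k] = (k == 1) ? ltr(0, 2)
                       : logadd(vm[k - 1] + ltr(k - 1, 2), vd[k - 1] + ltr(k - 1, 6));
    }
    double e = logadd(logadd(vm[M] + ltr(M, 0), vi[M] + ltr(M, 3)), vd[M] + ltr(M, 5));
    end = logadd(end, e);  // exit after i residues; C flank absorbs the rest
  }
  return end;
}

// [[Rcpp::export]]
List viterbi_lodds_cpp(NumericMatrix match_lodds, NumericMatrix ins_lodds,
                       NumericMatrix ltr, IntegerVector seq) {
  const int M = match_lodds.nrow();
  const int L = seq.size();
  NumericMatrix VM(L + 1, M + 1), VI(L + 1, M + 1), VD(L + 1, M + 1);
  NumericVector VI0(L + 1);
  std::fill(VM.begin(), VM.end(), NEG_INF);
  std::fill(VI.begin(), VI.end(), NEG_INF);
  std::fill(VD.begin(), VD.end(), NEG_INF);
  std::fill(VI0.begin(), VI0.end(), NEG_INF);

  VD(0, 1) = ltr(0, 2);
  for (int k = 2; k <= M; ++k) VD(0, k) = VD(0, k - 1) + ltr(k - 1, 6);

  for (int i = 1; i <= L; ++i) {
    const int a = seq[i - 1];
    VI0[i] = std::max(ltr(0, 1), VI0[i - 1] + ltr(0, 4));
    for (int k = 1; k <= M; ++k) {
      double m = max3(VM(i - 1, k - 1) + ltr(k - 1, 0),
                      VI(i - 1, k - 1) + ltr(k - 1, 3),
                      VD(i - 1, k - 1) + ltr(k - 1, 5));
      if (k == 1)
        m = std::max(m, std::max(ltr(0, 0), VI0[i - 1] + ltr(0, 3)));
      VM(i, k) = m + match_lodds(k - 1, a);
      VI(i, k) = std::max(VM(i - 1, k) + ltr(k, 1), VI(i - 1, k) + ltr(k, 4)) +
                 ins_lodds(k - 1, a);
      VD(i, k) = (k == 1)
                   ? ltr(0, 2)
                   : std::max(VM(i, k - 1) + ltr(k - 1, 2), VD(i, k - 1) + ltr(k - 1, 6));
    }
  }

  double best = NEG_INF; int best_i = 0, best_s = 0;  // 0=M, 1=I, 2=D
  for (int i = 0; i <= L; ++i) {
    double em = VM(i, M) + ltr(M, 0);
    double ei = VI(i, M) + ltr(M, 3);
    double ed = VD(i, M) + ltr(M, 5);
    if (em > best) { best = em; best_i = i; best_s = 0; }
    if (ei > best) { best = ei; best_i = i; best_s = 1; }
    if (ed > best) { best = ed; best_i = i; best_s = 2; }
  }

  // traceback: state type (0=M, 1=I, 2=D, 3=I_0), model position, and the
  // 1-based index of the residue emitted there (0 for silent states)
  std::vector<int> st_type, st_pos, st_res;
  int i = best_i, k = M, s = best_s;
  const double tol = 1e-9;
  bool done = false;
  while (!done) {
    st_type.push_back((s == 1 && k == 0) ? 3 : s);
    st_pos.push_back(k);
    st_res.push_back((s == 0 || (s == 1)) ? i : 0);
    if (s == 0) {
      double cur = VM(i, k) - match_lodds(k - 1, seq[i - 1]);
      if (k == 1) {
        if (std::fabs(cur - ltr(0, 0)) < tol) { done = true; continue; }
        if (std::fabs(cur - (VI0[i - 1] + ltr(0, 3))) < tol) { s = 1; k = 0; --i; continue; }
      }
      if (std::fabs(cur - (VM(i - 1, k - 1) + ltr(k - 1, 0))) < tol) { s = 0; --k; --i; continue; }
      if (std::fabs(cur - (VI(i - 1, k - 1) + ltr(k - 1, 3))) < tol) { s = 1; --k; --i; continue; }
      s = 2; --k; --i; continue;
    } else if (s == 1) {
      if (k == 0) {
        if (std::fabs(VI0[i] - ltr(0, 1)) < tol) { done = true; continue; }
        --i; continue;  // I_0 self loop
      }
      double cur = VI(i, k) - ins_lodds(k - 1, seq[i - 1]);
      if (std::fabs(cur - (VM(i - 1, k) + ltr(k, 1))) < tol) { s = 0; --i; continue; }
      s = 1; --i; continue;
    } else {
      if (k == 1) { done = true; continue; }  // D_1 is only reachable from B
      if (std::fabs(VD(i, k) - (VM(i, k - 1) + ltr(k - 1, 2))) < tol) { s = 0; --k; continue; }
      s = 2; --k; continue;
    }
  }
  std::reverse(st_type.begin(), st_type.end());
  std::reverse(st_pos.begin(), st_pos.end());
  std::reverse(st_res.begin(), st_res.end());
  return List::create(_["score"] = best,
                      _["type"] = IntegerVector(st_type.begin(), st_type.end()),
                      _["pos"] = IntegerVector(st_pos.begin(), st_pos.end()),
                      _["res"] = IntegerVector(st_res.begin(), st_res.end()));
}

static double viterbi_score_only(const NumericMatrix &match_lodds,
                                 const NumericMatrix &ins_lodds,
                                 const NumericMatrix &ltr,
                                 const IntegerVector &seq) {
  const int M = match_lodds.nrow();
  const int L = seq.size();
  std::vector<double> vm(M + 1, NEG_INF), vi(M + 1, NEG_INF), vd(M + 1, NEG_INF);
  std::vector<double> pm(M + 1, NEG_INF), pi(M + 1, NEG_INF), pd(M + 1, NEG_INF);
  double vi0 = NEG_INF, pi0;
  vd[1] = ltr(0, 2);
  for (int k = 2; k <= M; ++k) vd[k] = vd[k - 1] + ltr(k - 1, 6);
  double end = vd[M] + ltr(M, 5);
  for (int i = 1; i <= L; ++i) {
    pm.swap(vm); pi.swap(vi); pd.swap(vd); pi0 = vi0;
    const int a = seq[i - 1];
    vi0 = std::max(ltr(0, 1), pi0 + ltr(0, 4));
    for (int k = 1; k <= M; ++k) {
      double m = max3(pm[k - 1] + ltr(k - 1, 0), pi[k - 1] + ltr(k - 1, 3),
                      pd[k - 1] + ltr(k - 1, 5));
      if (k == 1) m = std::max(m, std::max(ltr(0, 0), pi0 + ltr(0, 3)));
      vm[k] = m + match_lodds(k - 1, a);
      vi[k] = std::max(pm[k] + ltr(k, 1), pi[k] + ltr(k, 4)) + ins_lodds(k - 1, a);
      vd[k] = (k == 1) ? ltr(0, 2)
                       : std::max(vm[k - 1] + ltr(k - 1, 2), vd[k - 1] + ltr(k - 1, 6));
    }
    end = std::max(end, max3(vm[M] + ltr(M, 0), vi[M] + ltr(M, 3), vd[M] + ltr(M, 5)));
  }
  return end;
}

// Batch forward scoring of many sequences against one model with a Viterbi
// prefilter: the exact forward score is computed only when the cheap Viterbi
// bound comes within `margin` of `floor_lodds` (forward >= viterbi always, so
// no sequence that could pass the floor is ever skipped); otherwise the
// Viterbi score is returned as a conservative stand-in for a failing score.

// [[Rcpp::export]]
NumericVector batch_forward_cpp(NumericMatrix match_lodds, NumericMatrix ins_lodds,
                                NumericMatrix ltr, List seqs, double floor_lodds,
                                double margin) {
  const int n = seqs.size();
  NumericVector out(n);
  for (int j = 0; j < n; ++j) {
    IntegerVector s = seqs[j];
    double v = viterbi_score_only(match_lodds, ins_lodds, ltr, s);
    out[j] = (v >= floor_lodds - margin)
               ? forward_lodds_cpp(match_lodds, ins_lodds, ltr, s)
               : v;
  }
  return out;
}
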