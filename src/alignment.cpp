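// Dynamic-programming kernels for protein alignment.
//
// Sequences arrive as 1-based integer codes into the scoring matrix; code 0 is
// reserved for "masked" (scores -inf against everything). Gap model is affine:
// a gap of length L costs gap_open + (L-1) * gap_extend.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -1e30;

// traceback codes
enum { TB_STOP = 0, TB_M = 1, TB_X = 2, TB_Y = 3 };

// One Smith-Waterman pass over (a, b) honouring masks; returns best cell and
// fills traceback matrices. M = a_i aligned to b_j; X = gap in b (consumes a);
// Y = gap in a (consumes b).
static double sw_pass(const std::vector<int>& a, const std::vector<int>& b,
                      const IntegerMatrix& S,
                      const std::vector<char>& maskA, const std::vector<char>& maskB,
                      double go, double ge,
                      std::vector<double>& M, std::vector<double>& X,
                      std::vector<double>& Y,
                      std::vector<char>& tbM, std::vector<char>& tbX,
                      std::vector<char>& tbY,
                      int& bi, int& bj) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  std::fill(M.begin(), M.end(), NEG_INF);
  std::fill(X.begin(), X.end(), NEG_INF);
  std::fill(Y.begin(), Y.end(), NEG_INF);
  double best = 0.0; bi = -1; bj = -1;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      // X: gap in b (consumes a_i); masked residues cannot be traversed at all,
      // so that successive hits occupy disjoint spans
      if (maskA[i - 1]) {
        X[idx] = NEG_INF; tbX[idx] = TB_M;
      } else {
        double xm = M[(i - 1) * W + j] - go;
        double xx = X[(i - 1) * W + j] - ge;
        if (xm >= xx) { X[idx] = xm; tbX[idx] = TB_M; } else { X[idx] = xx; tbX[idx] = TB_X; }
      }
      // Y: gap in a (consumes b_j)
      if (maskB[j - 1]) {
        Y[idx] = NEG_INF; tbY[idx] = TB_M;
      } else {
        double ym = M[i * W + (j - 1)] - go;
        double yy = Y[i * W + (j - 1)] - ge;
        if (ym >= yy) { Y[idx] = ym; tbY[idx] = TB_M; } else { Y[idx] = yy; tbY[idx] = TB_Y; }
      }
      // M
      double s;
      if (maskA[i - 1] || maskB[j - 1]) {
        s = NEG_INF;
      } else {
        s = S(a[i - 1] - 1, b[j - 1] - 1);
      }
      const int d = (i - 1) * W + (j - 1);
      double prev = 0.0; char tb = TB_STOP;
      if (M[d] > prev) { prev = M[d]; tb = TB_M; }
      if (X[d] > prev) { prev = X[d]; tb = TB_X; }
      if (Y[d] > prev) { prev = Y[d]; tb = TB_Y; }
      double mv = prev + s;
      if (mv < NEG_INF) mv = NEG_INF;
      M[idx] = mv; tbM[idx] = tb;
      if (mv > best) { best = mv; bi = i; bj = j; }
    }
  }
  return best;
}

// [[Rcpp::export(name = ".cpp_sw_hits")]]
List cpp_sw_hits(IntegerVector a_, IntegerVector b_, IntegerMatrix S,
                 double gap_open, double gap_extend,
                 int max_hits, double min_score) {
  std::vector<int> a(a_.begin(), a_.end()), b(b_.begin(), b_.end());
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  std::vector<char> maskA(n, 0), maskB(m, 0);
  std::vector<double> M((n + 1) * W), X((n + 1) * W), Y((n + 1) * W);
  std::vector<char> tbM((n + 1) * W, 0), tbX((n + 1) * W, 0), tbY((n + 1) * W, 0);

  std::vector<double> scores;
  std::vector<int> qs, qe, ss, se, idents, cols;

  for (int h = 0; h < max_hits; ++h) {
    int bi, bj;
    double best = sw_pass(a, b, S, maskA, maskB, gap_open, gap_extend,
                          M, X, Y, tbM, tbX, tbY, bi, bj);
    if (best <= 0.0 || best < min_score || bi < 0) break;
    // traceback from (bi, bj) in state M
    int i = bi, j = bj, state = TB_M;
    int q_end = bi, s_end = bj;   // 1-based inclusive ends
    int ident = 0, ncol = 0;
    int q_start = bi, s_start = bj;
    while (true) {
      const int idx = i * W + j;
      if (state == TB_M) {
        ++ncol;
        if (a[i - 1] == b[j - 1]) ++ident;
        q_start = i; s_start = j;
        char prev = tbM[idx];
        --i; --j;
        if (prev == TB_STOP) break;
        state = prev;
      } else if (state == TB_X) {
        ++ncol;
        char prev = tbX[idx];
        --i;
        state = prev;
      } else { // TB_Y
        ++ncol;
        char prev = tbY[idx];
        --j;
        state = prev;
      }
    }
    scores.push_back(best);
    qs.push_back(q_start); qe.push_back(q_end);
    ss.push_back(s_start); se.push_back(s_end);
    idents.push_back(ident); cols.push_back(ncol);
    // mask the consumed spans in both sequences
    for (int k = q_start - 1; k < q_end; ++k) maskA[k] = 1;
    for (int k = s_start - 1; k < s_end; ++k) maskB[k] = 1;
  }
  return List::create(
    _["raw_score"] = NumericVector(scores.begin(), scores.end()),
    _["q_start"] = IntegerVector(qs.begin(), qs.end()),
    _["q_end"] = IntegerVector(qe.begin(), qe.end()),
    _["s_start"] = IntegerVector(ss.begin(), ss.end()),
    _["s_end"] = IntegerVector(se.begin(), se.end()),
    _["identities"] = IntegerVector(idents.begin(), idents.end()),
    _["aligned_columns"] = IntegerVector(cols.begin(), cols.end()));
}

// Global (Needleman-Wunsch) affine alignment; returns score, identity over
// alignment columns, and the aligned index paths (0 = gap).
// [[Rcpp::export(name = ".cpp_nw_global")]]
List cpp_nw_global(IntegerVector a_, IntegerVector b_, IntegerMatrix S,
                   double gap_open, double gap_extend) {
  std::vector<int> a(a_.begin(), a_.end()), b(b_.begin(), b_.end());
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  std::vector<char> tbM((n + 1) * W, 0), tbX((n + 1) * W, 0), tbY((n + 1) * W, 0);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -gap_open - (i - 1) * gap_extend;
    tbX[i * W] = (i == 1) ? TB_M : TB_X;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -gap_open - (j - 1) * gap_extend;
    tbY[j] = (j == 1) ? TB_M : TB_Y;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      double xm = M[(i - 1) * W + j] - gap_open;
      double xx = X[(i - 1) * W + j] - gap_extend;
      if (xm >= xx) { X[idx] = xm; tbX[idx] = TB_M; } else { X[idx] = xx; tbX[idx] = TB_X; }
      double ym = M[i * W + (j - 1)] - gap_open;
      double yy = Y[i * W + (j - 1)] - gap_extend;
      if (ym >= yy) { Y[idx] = ym; tbY[idx] = TB_M; } else { Y[idx] = yy; tbY[idx] = TB_Y; }
      const int d = (i - 1) * W + (j - 1);
      double prev = M[d]; char tb = TB_M;
      if (X[d] > prev) { prev = X[d]; tb = TB_X; }
      if (Y[d] > prev) { prev = Y[d]; tb = TB_Y; }
      M[idx] = prev + S(a[i - 1] - 1, b[j - 1] - 1);
      tbM[idx] = tb;
    }
  }
  const int end = n * W + m;
  double score = M[end]; int state = TB_M;
  if (X[end] > score) { score = X[end]; state = TB_X; }
  if (Y[end] > score) { score = Y[end]; state = TB_Y; }
  // traceback
  std::vector<int> pa, pb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int idx = i * W + j;
    if (state == TB_M && i > 0 && j > 0) {
      pa.push_back(i); pb.push_back(j);
      state = tbM[idx]; --i; --j;
    } else if (state == TB_X || (j == 0 && i > 0)) {
      pa.push_back(i); pb.push_back(0);
      state = (i > 0) ? tbX[idx] : TB_M; --i;
    } else {
      pa.push_back(0); pb.push_back(j);
      state = (j > 0) ? tbY[idx] : TB_M; --j;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  int ident = 0;
  for (size_t k = 0; k < pa.size(); ++k)
    if (pa[k] > 0 && pb[k] > 0 && a[pa[k] - 1] == b[pb[k] - 1]) ++ident;
  return List::create(_["score"] = score,
                      _["identity"] = (double)ident / (double)pa.size(),
                      _["columns"] = (int)pa.size(),
                      _["path_a"] = IntegerVector(pa.begin(), pa.end()),
                      _["path_b"] = IntegerVector(pb.begin(), pb.end()));
}

// Profile-profile global affine alignment with sum-of-pairs match scores.
// A, B: (n_states x L) column frequency matrices (gap mass carries no score).
// Returns the two gapped column paths (0 = gap column).
// [[Rcpp::export(name = ".cpp_profile_align")]]
List cpp_profile_align(NumericMatrix A, NumericMatrix B, NumericMatrix S,
                       double gap_open, double gap_extend) {
  const int K = A.nrow();
  const int n = A.ncol(), m = B.ncol();
  // SB[k, j] = sum_l S[k, l] * B[l, j]
  NumericMatrix SB(K, m);
  for (int j = 0; j < m; ++j)
    for (int l = 0; l < K; ++l) {
      double blj = B(l, j);
      if (blj == 0.0) continue;
      for (int k = 0; k < K; ++k) SB(k, j) += S(k, l) * blj;
    }
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  std::vector<char> tbM((n + 1) * W, 0), tbX((n + 1) * W, 0), tbY((n + 1) * W, 0);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -gap_open - (i - 1) * gap_extend;
    tbX[i * W] = (i == 1) ? TB_M : TB_X;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -gap_open - (j - 1) * gap_extend;
    tbY[j] = (j == 1) ? TB_M : TB_Y;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      double xm = M[(i - 1) * W + j] - gap_open;
      double xx = X[(i - 1) * W + j] - gap_extend;
      if (xm >= xx) { X[idx] = xm; tbX[idx] = TB_M; } else { X[idx] = xx; tbX[idx] = TB_X; }
      double ym = M[i * W + (j - 1)] - gap_open;
      double yy = Y[i * W + (j - 1)] - gap_extend;
      if (ym >= yy) { Y[idx] = ym; tbY[idx] = TB_M; } else { Y[idx] = yy; tbY[idx] = TB_Y; }
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double aki = A(k, i - 1);
        if (aki != 0.0) s += aki * SB(k, j - 1);
      }
      const int d = (i - 1) * W + (j - 1);
      double prev = M[d]; char tb = TB_M;
      if (X[d] > prev) { prev = X[d]; tb = TB_X; }
      if (Y[d] > prev) { prev = Y[d]; tb = TB_Y; }
      M[idx] = prev + s;
      tbM[idx] = tb;
    }
  }
  const int end = n * W + m;
  double score = M[end]; int state = TB_M;
  if (X[end] > score) { score = X[end]; state = TB_X; }
  if (Y[end] > score) { score = Y[end]; state = TB_Y; }
  std::vector<int> pa, pb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int idx = i * W + j;
    if (state == TB_M && i > 0 && j > 0) {
      pa.push_back(i); pb.push_back(j);
      state = tbM[idx]; --i; --j;
    } else if (state == TB_X || (j == 0 && i > 0)) {
      pa.push_back(i); pb.push_back(0);
      state = (i > 0) ? tbX[idx] : TB_M; --i;
    } else {
      pa.push_back(0); pb.push_back(j);
      state = (j > 0) ? tbY[idx] : TB_M; --j;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = score,
                      _["path_a"] = IntegerVector(pa.begin(), pa.end()),
                      _["path_b"] = IntegerVector(pb.begin(), pb.end()));
}
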