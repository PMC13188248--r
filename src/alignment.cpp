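#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh), local (Smith-Waterman) or global
// (Needleman-Wunsch) mode.  Sequences arrive as 1-based integer codes into
// the scoring matrix S.  Gap cost convention: a gap of length k costs
// gap_open + k * gap_ext, i.e. the transition into a gap state costs
// gap_open + gap_ext and each further gap column costs gap_ext.
//
// Traceback state codes per cell, packed into one byte:
//   bits 0-1: predecessor of M  (0 = diag from M/X/Y best, encoded below)
// We store, for each of M, X, Y, which matrix the optimal predecessor was in.

static inline double max3(double a, double b, double c) {
  return std::max(a, std::max(b, c));
}

// [[Rcpp::export]]
List cpp_pair_align(IntegerVector a, IntegerVector b, NumericMatrix S,
                    double gap_open, double gap_ext, bool global) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e18;
  // flatten inputs: Rcpp element accessors are too slow for the inner loop
  const int A = S.nrow();
  std::vector<double> Sf(S.begin(), S.end());     // column-major A x A
  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
  // rolling rows for scores, full byte matrices for traceback
  std::vector<double> Mprev(m + 1), Mcur(m + 1), Xprev(m + 1), Xcur(m + 1),
      Yprev(m + 1), Ycur(m + 1);
  // tb[state][i*(m+1)+j]: for M: 0 diagM 1 diagX 2 diagY 3 start(local)
  // for X (gap in a, consumes b): 0 fromM 1 fromX ; for Y: 0 fromM 1 fromY
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);
  // pack: bits 0-1 M-pred, bit 2 X-pred, bit 3 Y-pred

  double best = global ? NEG : 0.0;
  int bi = 0, bj = 0;

  for (int j = 0; j <= m; ++j) {
    Mprev[j] = (j == 0) ? 0.0 : NEG;
    Xprev[j] = global ? (j == 0 ? NEG : -(gap_open + gap_ext * j)) : NEG;
    Yprev[j] = NEG;
  }

  for (int i = 1; i <= n; ++i) {
    Mcur[0] = NEG;
    Xcur[0] = NEG;
    Ycur[0] = global ? -(gap_open + gap_ext * i) : NEG;
    const double *Srow = &Sf[(size_t)(av[i - 1] - 1)];  // + A*col per lookup
    uint8_t *tbrow = &tb[(size_t)i * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      const double sub = Srow[(size_t)A * (bv[j - 1] - 1)];
      // M: diagonal from best of M/X/Y at (i-1, j-1)
      double dM = Mprev[j - 1], dX = Xprev[j - 1], dY = Yprev[j - 1];
      double dbest = max3(dM, dX, dY);
      uint8_t mpred = (dbest == dM) ? 0 : (dbest == dX ? 1 : 2);
      double mval = dbest + sub;
      if (!global && mval < sub) { /* keep */ }
      if (!global) {
        // local: may start fresh at this cell
        if (dbest < 0.0) { mval = sub; mpred = 3; }
      }
      // X: gap in a (consume b[j-1]); from M(i, j-1) open or X(i, j-1) extend
      double xo = Mcur[j - 1] - (gap_open + gap_ext);
      double xe = Xcur[j - 1] - gap_ext;
      double xval; uint8_t xpred;
      if (xo >= xe) { xval = xo; xpred = 0; } else { xval = xe; xpred = 1; }
      // Y: gap in b (consume a[i-1]); from M(i-1, j) open or Y(i-1, j) extend
      double yo = Mprev[j] - (gap_open + gap_ext);
      double ye = Yprev[j] - gap_ext;
      double yval; uint8_t ypred;
      if (yo >= ye) { yval = yo; ypred = 0; } else { yval = ye; ypred = 1; }

      Mcur[j] = mval; Xcur[j] = xval; Ycur[j] = yval;
      tbrow[j] = (uint8_t)(mpred | (xpred << 2) | (ypred << 3));
      if (!global) {
        if (mval > best) { best = mval; bi = i; bj = j; }
      }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  uint8_t end_state = 0; // 0 = M, 1 = X, 2 = Y
  if (global) {
    double eM = Mprev[m], eX = Xprev[m], eY = Yprev[m];
    best = max3(eM, eX, eY);
    end_state = (best == eM) ? 0 : (best == eX ? 1 : 2);
    bi = n; bj = m;
  }

  // local with no positive score: empty alignment
  if (!global && best <= 0.0) {
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0,
                        _["a_aln"] = IntegerVector(0),
                        _["b_aln"] = IntegerVector(0));
  }

  // The packed predecessor codes fully determine the path.
  std::vector<int> arev, brev;
  int i = bi, j = bj;
  int state = end_state;
  for (;;) {
    if (i == 0 && j == 0) break;
    if (i == 0) { // leading gap in a (global only)
      arev.push_back(0); brev.push_back(b[j - 1]); --j; continue;
    }
    if (j == 0) {
      arev.push_back(a[i - 1]); brev.push_back(0); --i; continue;
    }
    uint8_t byte = tb[(size_t)i * (m + 1) + j];
    if (state == 0) {
      arev.push_back(a[i - 1]); brev.push_back(b[j - 1]);
      uint8_t code = byte & 3u;
      --i; --j;
      if (code == 3) break; // local start
      state = code;
    } else if (state == 1) { // X: gap in a
      arev.push_back(0); brev.push_back(b[j - 1]);
      state = ((byte >> 2) & 1u) ? 1 : 0;
      --j;
    } else { // Y: gap in b
      arev.push_back(a[i - 1]); brev.push_back(0);
      state = ((byte >> 3) & 1u) ? 2 : 0;
      --i;
    }
  }
  const int L = (int)arev.size();
  IntegerVector aa(L), ba(L);
  for (int k = 0; k < L; ++k) { aa[k] = arev[L - 1 - k]; ba[k] = brev[L - 1 - k]; }
  return List::create(_["score"] = best, _["a_start"] = i, _["a_end"] = bi,
                      _["b_start"] = j, _["b_end"] = bj,
                      _["a_aln"] = aa, _["b_aln"] = ba);
}

// Local affine-gap alignment of an integer-coded query against a PSSM
// (ncol-position profile; column scores pssm(pos, residue)).  Returns the
// best local score (floored at 0) and 0-based half-open coordinates.
// [[Rcpp::export]]
List cpp_profile_align(IntegerVector q, NumericMatrix pssm,
                       double gap_open, double gap_ext) {
  const int n = q.size(), m = pssm.nrow();
  const double NEG = -1e18;
  std::vector<double> Pf(pssm.begin(), pssm.end());  // column-major m x 21
  std::vector<int> qv(q.begin(), q.end());
  std::vector<double> Mprev(m + 1, 0.0), Mcur(m + 1), Xprev(m + 1, NEG),
      Xcur(m + 1), Yprev(m + 1, NEG), Ycur(m + 1);
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int j = 0; j <= m; ++j) { Mprev[j] = 0.0; Xprev[j] = NEG; Yprev[j] = NEG; }
  for (int i = 1; i <= n; ++i) {
    Mcur[0] = 0.0; Xcur[0] = NEG; Ycur[0] = NEG;
    const double *Pcol = &Pf[(size_t)(qv[i - 1] - 1) * m];
    uint8_t *tbrow = &tb[(size_t)i * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      const double sub = Pcol[j - 1];
      double dM = Mprev[j - 1], dX = Xprev[j - 1], dY = Yprev[j - 1];
      double dbest = max3(dM, dX, dY);
      uint8_t mpred = (dbest == dM) ? 0 : (dbest == dX ? 1 : 2);
      double mval = dbest + sub;
      if (dbest < 0.0) { mval = sub; mpred = 3; }
      if (mval < sub) { mval = sub; mpred = 3; }
      double xo = Mcur[j - 1] - (gap_open + gap_ext);
      double xe = Xcur[j - 1] - gap_ext;
      double xval; uint8_t xpred;
      if (xo >= xe) { xval = xo; xpred = 0; } else { xval = xe; xpred = 1; }
      double yo = Mprev[j] - (gap_open + gap_ext);
      double ye = Yprev[j] - gap_ext;
      double yval; uint8_t ypred;
      if (yo >= ye) { yval = yo; ypred = 0; } else { yval = ye; ypred = 1; }
      Mcur[j] = mval; Xcur[j] = xval; Ycur[j] = yval;
      tbrow[j] = (uint8_t)(mpred | (xpred << 2) | (ypred << 3));
      if (mval > best) { best = mval; bi = i; bj = j; }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["q_start"] = 0, _["q_end"] = 0,
                        _["col_start"] = 0, _["col_end"] = 0);
  int i = bi, j = bj, state = 0;
  while (i > 0 && j > 0) {
    uint8_t byte = tb[(size_t)i * (m + 1) + j];
    if (state == 0) {
      uint8_t code = byte & 3u;
      --i; --j;
      if (code == 3) break;
      state = code;
    } else if (state == 1) {
      state = ((byte >> 2) & 1u) ? 1 : 0; --j;
    } else {
      state = ((byte >> 3) & 1u) ? 2 : 0; --i;
    }
  }
  return List::create(_["score"] = best, _["q_start"] = i, _["q_end"] = bi,
                      _["col_start"] = j, _["col_end"] = bj);
}

// Global affine-gap path over a precomputed column-vs-column score matrix C
// (profile-profile alignment for the progressive aligner).  Returns the merge
// path: 1 = advance both, 2 = gap in B (A column alone), 3 = gap in A.
// [[Rcpp::export]]
List cpp_global_path(NumericMatrix C, double gap_open, double gap_ext) {
  const int n = C.nrow(), m = C.ncol();
  const double NEG = -1e18;
  std::vector<double> Cf(C.begin(), C.end());     // column-major n x m
  std::vector<double> Mprev(m + 1), Mcur(m + 1), Xprev(m + 1), Xcur(m + 1),
      Yprev(m + 1), Ycur(m + 1);
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);
  Mprev[0] = 0.0; Xprev[0] = NEG; Yprev[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG; Xprev[j] = -(gap_open + gap_ext * j); Yprev[j] = NEG;
  }
  for (int i = 1; i <= n; ++i) {
    Mcur[0] = NEG; Xcur[0] = NEG; Ycur[0] = -(gap_open + gap_ext * i);
    for (int j = 1; j <= m; ++j) {
      double dM = Mprev[j - 1], dX = Xprev[j - 1], dY = Yprev[j - 1];
      double dbest = max3(dM, dX, dY);
      uint8_t mpred = (dbest == dM) ? 0 : (dbest == dX ? 1 : 2);
      double mval = dbest + Cf[(size_t)(j - 1) * n + (i - 1)];
      double xo = Mcur[j - 1] - (gap_open + gap_ext);
      double xe = Xcur[j - 1] - gap_ext;
      double xval; uint8_t xpred;
      if (xo >= xe) { xval = xo; xpred = 0; } else { xval = xe; xpred = 1; }
      double yo = Mprev[j] - (gap_open + gap_ext);
      double ye = Yprev[j] - gap_ext;
      double yval; uint8_t ypred;
      if (yo >= ye) { yval = yo; ypred = 0; } else { yval = ye; ypred = 1; }
      Mcur[j] = mval; Xcur[j] = xval; Ycur[j] = yval;
      tb[(size_t)i * (m + 1) + j] = (uint8_t)(mpred | (xpred << 2) | (ypred << 3));
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }
  double eM = Mprev[m], eX = Xprev[m], eY = Yprev[m];
  double best = max3(eM, eX, eY);
  int state = (best == eM) ? 0 : (best == eX ? 1 : 2);
  std::vector<int> path;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) { path.push_back(3); --j; continue; }
    if (j == 0) { path.push_back(2); --i; continue; }
    uint8_t byte = tb[(size_t)i * (m + 1) + j];
    if (state == 0) {
      path.push_back(1);
      state = byte & 3u;
      --i; --j;
    } else if (state == 1) {
      path.push_back(3);
      state = ((byte >> 2) & 1u) ? 1 : 0;
      --j;
    } else {
      path.push_back(2);
      state = ((byte >> 3) & 1u) ? 2 : 0;
      --i;
    }
  }
  const int L = (int)path.size();
  IntegerVector out(L);
  for (int k = 0; k < L; ++k) out[k] = path[L - 1 - k];
  return List::create(_["score"] = best, _["path"] = out);
}

// Pairwise p-distances over an integer-coded alignment matrix (rows = taxa,
// 0 = gap).  Returns proportion different and count of comparable columns.
// [[Rcpp::export]]
List cpp_pdist(IntegerMatrix aln) {
  const int n = aln.nrow(), m = aln.ncol();
  NumericMatrix p(n, n);
  IntegerMatrix comp(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int nc = 0, nd = 0;
      for (int k = 0; k < m; ++k) {
        int x = aln(i, k), y = aln(j, k);
        if (x > 0 && y > 0) { ++nc; if (x != y) ++nd; }
      }
      comp(i, j) = comp(j, i) = nc;
      double d = nc > 0 ? (double)nd / nc : NA_REAL;
      p(i, j) = p(j, i) = d;
    }
  }
  return List::create(_["p"] = p, _["comparable"] = comp);
}
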