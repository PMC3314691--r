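#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap (Gotoh) local and global aligners over integer-coded residues
// (1..21; 21 = X). Gap state Ix consumes a (an "up" move), Iy consumes b
// ("left"). Tie-breaks are fixed: the optimal cell is the highest-scoring
// one with smallest (end_i, end_j); traceback prefers diagonal, then up,
// then left. A k-residue gap costs gap_open + k * gap_extend.

static const double NEG = -1e18;

static inline int sub(const IntegerMatrix& S, int a, int b) {
  return S(a - 1, b - 1);
}

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, IntegerMatrix S,
                  double gap_open, double gap_extend) {
  int m = a.size(), n = b.size();
  NumericMatrix M(m + 1, n + 1), Ix(m + 1, n + 1), Iy(m + 1, n + 1);
  for (int j = 0; j <= n; ++j) { M(0, j) = NEG; Ix(0, j) = NEG; Iy(0, j) = NEG; }
  for (int i = 0; i <= m; ++i) { M(i, 0) = NEG; Ix(i, 0) = NEG; Iy(i, 0) = NEG; }
  double best = 0.0; int bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double h = 0.0;  // best zero-clamped score at (i-1, j-1)
      if (M(i - 1, j - 1) > h) h = M(i - 1, j - 1);
      if (Ix(i - 1, j - 1) > h) h = Ix(i - 1, j - 1);
      if (Iy(i - 1, j - 1) > h) h = Iy(i - 1, j - 1);
      M(i, j) = h + sub(S, a[i - 1], b[j - 1]);
      double x1 = M(i - 1, j) - gap_open - gap_extend;
      double x2 = Ix(i - 1, j) - gap_extend;
      Ix(i, j) = x1 >= x2 ? x1 : x2;
      double y1 = M(i, j - 1) - gap_open - gap_extend;
      double y2 = Iy(i, j - 1) - gap_extend;
      Iy(i, j) = y1 >= y2 ? y1 : y2;
      if (M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }
  std::vector<int> pa, pb;  // aligned positions, 0 = gap
  int a_start = 0, a_end = -1, b_start = 0, b_end = -1;
  if (bi > 0) {
    a_end = bi; b_end = bj;
    int i = bi, j = bj, state = 0;  // 0 = M, 1 = Ix, 2 = Iy
    while (true) {
      if (state == 0) {
        pa.push_back(i); pb.push_back(j);
        double h = M(i, j) - sub(S, a[i - 1], b[j - 1]);
        --i; --j;
        if (i == 0 || j == 0) break;
        // prefer stopping at 0 (canonical SW), then diagonal, up, left
        if (h <= 0.0) break;
        if (M(i, j) == h) state = 0;
        else if (Ix(i, j) == h) state = 1;
        else state = 2;
      } else if (state == 1) {
        pa.push_back(i); pb.push_back(0);
        double v = Ix(i, j);
        --i;
        if (M(i, j) - gap_open - gap_extend == v) state = 0; else state = 1;
      } else {
        pa.push_back(0); pb.push_back(j);
        double v = Iy(i, j);
        --j;
        if (M(i, j) - gap_open - gap_extend == v) state = 0; else state = 2;
      }
    }
    a_start = i + 1; b_start = j + 1;
    std::reverse(pa.begin(), pa.end());
    std::reverse(pb.begin(), pb.end());
  }
  return List::create(_["score"] = best,
                      _["a_start"] = a_start, _["a_end"] = a_end,
                      _["b_start"] = b_start, _["b_end"] = b_end,
                      _["pa"] = wrap(pa), _["pb"] = wrap(pb));
}

// [[Rcpp::export]]
List nw_align_cpp(IntegerVector a, IntegerVector b, IntegerMatrix S,
                  double gap_open, double gap_extend) {
  int m = a.size(), n = b.size();
  NumericMatrix M(m + 1, n + 1), Ix(m + 1, n + 1), Iy(m + 1, n + 1);
  M(0, 0) = 0.0; Ix(0, 0) = NEG; Iy(0, 0) = NEG;
  for (int i = 1; i <= m; ++i) {
    M(i, 0) = NEG; Iy(i, 0) = NEG;
    Ix(i, 0) = -gap_open - i * gap_extend;
  }
  for (int j = 1; j <= n; ++j) {
    M(0, j) = NEG; Ix(0, j) = NEG;
    Iy(0, j) = -gap_open - j * gap_extend;
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double h = M(i - 1, j - 1);
      if (Ix(i - 1, j - 1) > h) h = Ix(i - 1, j - 1);
      if (Iy(i - 1, j - 1) > h) h = Iy(i - 1, j - 1);
      M(i, j) = h + sub(S, a[i - 1], b[j - 1]);
      double x1 = M(i - 1, j) - gap_open - gap_extend;
      double x2 = Ix(i - 1, j) - gap_extend;
      Ix(i, j) = x1 >= x2 ? x1 : x2;
      double y1 = M(i, j - 1) - gap_open - gap_extend;
      double y2 = Iy(i, j - 1) - gap_extend;
      Iy(i, j) = y1 >= y2 ? y1 : y2;
    }
  }
  double fin = M(m, n); int state = 0;
  if (Ix(m, n) > fin) { fin = Ix(m, n); state = 1; }
  if (Iy(m, n) > fin) { fin = Iy(m, n); state = 2; }
  std::vector<int> pa, pb;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (state == 0) {
      pa.push_back(i); pb.push_back(j);
      double h = M(i, j) - sub(S, a[i - 1], b[j - 1]);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (i == 0) { state = 2; continue; }
      if (j == 0) { state = 1; continue; }
      if (M(i, j) == h) state = 0;
      else if (Ix(i, j) == h) state = 1;
      else state = 2;
    } else if (state == 1) {
      pa.push_back(i); pb.push_back(0);
      double v = Ix(i, j);
      --i;
      if (i == 0 && j == 0) break;
      if (i == 0) { state = 2; continue; }
      if (M(i, j) - gap_open - gap_extend == v) state = 0;
      else state = 1;
    } else {
      pa.push_back(0); pb.push_back(j);
      double v = Iy(i, j);
      --j;
      if (i == 0 && j == 0) break;
      if (j == 0) { state = 1; continue; }
      if (M(i, j) - gap_open - gap_extend == v) state = 0;
      else state = 2;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = fin,
                      _["pa"] = wrap(pa), _["pb"] = wrap(pb));
}

// Pairwise distance (1 - identity) from an integer-coded MSA (0 = gap),
// over a given multiset of columns; gap-containing pairs of cells are
// excluded pairwise. Pairs with no comparable columns get distance 1.
// [[Rcpp::export]]
NumericMatrix msa_dist_cpp(IntegerMatrix msa, IntegerVector cols) {
  int ns = msa.nrow(), nc = cols.size();
  NumericMatrix D(ns, ns);
  for (int i = 0; i < ns; ++i) {
    for (int j = i + 1; j < ns; ++j) {
      int valid = 0, same = 0;
      for (int k = 0; k < nc; ++k) {
        int c = cols[k] - 1;
        int x = msa(i, c), y = msa(j, c);
        if (x > 0 && y > 0) { ++valid; if (x == y) ++same; }
      }
      double d = valid > 0 ? 1.0 - (double)same / valid : 1.0;
      D(i, j) = d; D(j, i) = d;
    }
  }
  return D;
}

// Profile-profile global alignment (Gotoh). Profiles are (22 x L) column
// frequency matrices: rows 1..21 residue frequencies (21 = X), row 22 gap
// frequency. Existing gap vs residue scores -gap_extend, gap vs gap 0;
// newly introduced gaps pay the affine penalty.
// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix A, NumericMatrix B, IntegerMatrix S,
                       double gap_open, double gap_extend) {
  int m = A.ncol(), n = B.ncol();
  // column-column expected scores
  NumericMatrix CS(m, n);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0.0, fAres = 0.0, fBres = 0.0;
      for (int x = 0; x < 21; ++x) {
        double fa = A(x, i);
        if (fa == 0.0) continue;
        fAres += fa;
        for (int y = 0; y < 21; ++y) {
          double fb = B(y, j);
          if (fb == 0.0) continue;
          s += fa * fb * S(x, y);
        }
      }
      for (int y = 0; y < 21; ++y) fBres += B(y, j);
      s += (A(21, i) * fBres + B(21, j) * fAres) * (-gap_extend);
      CS(i, j) = s;
    }
  }
  NumericMatrix M(m + 1, n + 1), Ix(m + 1, n + 1), Iy(m + 1, n + 1);
  M(0, 0) = 0.0; Ix(0, 0) = NEG; Iy(0, 0) = NEG;
  for (int i = 1; i <= m; ++i) {
    M(i, 0) = NEG; Iy(i, 0) = NEG; Ix(i, 0) = -gap_open - i * gap_extend;
  }
  for (int j = 1; j <= n; ++j) {
    M(0, j) = NEG; Ix(0, j) = NEG; Iy(0, j) = -gap_open - j * gap_extend;
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double h = M(i - 1, j - 1);
      if (Ix(i - 1, j - 1) > h) h = Ix(i - 1, j - 1);
      if (Iy(i - 1, j - 1) > h) h = Iy(i - 1, j - 1);
      M(i, j) = h + CS(i - 1, j - 1);
      double x1 = M(i - 1, j) - gap_open - gap_extend;
      double x2 = Ix(i - 1, j) - gap_extend;
      Ix(i, j) = x1 >= x2 ? x1 : x2;
      double y1 = M(i, j - 1) - gap_open - gap_extend;
      double y2 = Iy(i, j - 1) - gap_extend;
      Iy(i, j) = y1 >= y2 ? y1 : y2;
    }
  }
  double fin = M(m, n); int state = 0;
  if (Ix(m, n) > fin) { fin = Ix(m, n); state = 1; }
  if (Iy(m, n) > fin) { fin = Iy(m, n); state = 2; }
  std::vector<int> pa, pb;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (state == 0) {
      pa.push_back(i); pb.push_back(j);
      double h = M(i, j) - CS(i - 1, j - 1);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (i == 0) { state = 2; continue; }
      if (j == 0) { state = 1; continue; }
      if (M(i, j) == h) state = 0;
      else if (Ix(i, j) == h) state = 1;
      else state = 2;
    } else if (state == 1) {
      pa.push_back(i); pb.push_back(0);
      double v = Ix(i, j);
      --i;
      if (i == 0 && j == 0) break;
      if (i == 0) { state = 2; continue; }
      if (j > 0 && M(i, j) - gap_open - gap_extend == v) state = 0;
      else if (Ix(i, j) - gap_extend == v) state = 1;
      else state = 0;
    } else {
      pa.push_back(0); pb.push_back(j);
      double v = Iy(i, j);
      --j;
      if (i == 0 && j == 0) break;
      if (j == 0) { state = 1; continue; }
      if (i > 0 && M(i, j) - gap_open - gap_extend == v) state = 0;
      else if (Iy(i, j) - gap_extend == v) state = 2;
      else state = 0;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = fin,
                      _["pa"] = wrap(pa), _["pb"] = wrap(pb));
}
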