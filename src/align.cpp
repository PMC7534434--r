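#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state recursion).
// A gap of length g costs open + g * extend, i.e. the first gapped
// residue costs open + extend and each further one costs extend.
// Scores come from a substitution matrix passed in from R (typically
// BLOSUM50 as shipped by Biostrings).

namespace {

const double NEG_INF = -1e30;

struct SubLookup {
  int idx[256];
  NumericMatrix mat;
  SubLookup(const NumericMatrix& m) : mat(m) {
    for (int i = 0; i < 256; ++i) idx[i] = -1;
    CharacterVector rn = rownames(m);
    for (int i = 0; i < rn.size(); ++i) {
      std::string s = as<std::string>(rn[i]);
      if (s.size() == 1) idx[(unsigned char)s[0]] = i;
    }
  }
  double score(char a, char b) const {
    int ia = idx[(unsigned char)a], ib = idx[(unsigned char)b];
    if (ia < 0 || ib < 0) stop("residue not covered by substitution matrix");
    return mat(ia, ib);
  }
};

} // namespace

// Smith-Waterman local alignment; returns best score and the 1-based
// spans of the optimal local alignment on both sequences.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string a, std::string b, NumericMatrix sub,
              double open, double extend) {
  SubLookup S(sub);
  int n = a.size(), m = b.size();
  // state matrices: 0 = M (match), 1 = Ix (gap in b), 2 = Iy (gap in a)
  std::vector<double> M((n + 1) * (m + 1), 0.0);
  std::vector<double> Ix((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Iy((n + 1) * (m + 1), NEG_INF);
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 0); // 0 start,1 M,2 Ix,3 Iy
  std::vector<unsigned char> tbX((n + 1) * (m + 1), 0); // 1 from M, 2 extend
  std::vector<unsigned char> tbY((n + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int c = i * (m + 1) + j, up = (i - 1) * (m + 1) + j,
          lf = i * (m + 1) + j - 1, dg = (i - 1) * (m + 1) + j - 1;
      double gx1 = M[up] - (open + extend), gx2 = Ix[up] - extend;
      Ix[c] = gx1 >= gx2 ? gx1 : gx2;
      tbX[c] = gx1 >= gx2 ? 1 : 2;
      double gy1 = M[lf] - (open + extend), gy2 = Iy[lf] - extend;
      Iy[c] = gy1 >= gy2 ? gy1 : gy2;
      tbY[c] = gy1 >= gy2 ? 1 : 2;
      double s = S.score(a[i - 1], b[j - 1]);
      double dM = M[dg], dX = Ix[dg], dY = Iy[dg];
      double d = dM; unsigned char t = 1;
      if (dX > d) { d = dX; t = 2; }
      if (dY > d) { d = dY; t = 3; }
      double v = d + s;
      if (v < 0) { v = 0; t = 0; }
      M[c] = v; tbM[c] = t;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  int qe = bi, se = bj, qs = bi, ss = bj;
  if (best > 0) {
    // walk back through states; tbM == 0 marks a fresh local start
    int i = bi, j = bj, st = 0; // st: 0=M, 1=Ix, 2=Iy
    while (true) {
      int c = i * (m + 1) + j;
      if (st == 0) {
        unsigned char t = tbM[c];
        if (t == 0) break;      // this cell restarted at zero
        qs = i; ss = j;         // cell consumes a[i-1], b[j-1]
        st = (t == 1) ? 0 : (t == 2 ? 1 : 2);
        --i; --j;
      } else if (st == 1) {
        unsigned char t = tbX[c];
        st = (t == 1) ? 0 : 1;
        --i;
      } else {
        unsigned char t = tbY[c];
        st = (t == 1) ? 0 : 2;
        --j;
      }
    }
  } else {
    qs = qe = ss = se = 0;
  }
  return List::create(_["score"] = best,
                      _["q_start"] = qs, _["q_end"] = qe,
                      _["s_start"] = ss, _["s_end"] = se);
}

// Needleman-Wunsch global alignment; returns score and the two gapped
// alignment rows.
// [[Rcpp::export(name = ".nw_align")]]
List nw_align(std::string a, std::string b, NumericMatrix sub,
              double open, double extend) {
  SubLookup S(sub);
  int n = a.size(), m = b.size();
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ix((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Iy((n + 1) * (m + 1), NEG_INF);
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbX((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbY((n + 1) * (m + 1), 0);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    int c = i * (m + 1);
    Ix[c] = -(open + extend * i);
    tbX[c] = (i == 1) ? 1 : 2;
  }
  for (int j = 1; j <= m; ++j) {
    Iy[j] = -(open + extend * j);
    tbY[j] = (j == 1) ? 1 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int c = i * (m + 1) + j, up = (i - 1) * (m + 1) + j,
          lf = i * (m + 1) + j - 1, dg = (i - 1) * (m + 1) + j - 1;
      double gx1 = M[up] - (open + extend), gx2 = Ix[up] - extend;
      Ix[c] = gx1 >= gx2 ? gx1 : gx2;
      tbX[c] = gx1 >= gx2 ? 1 : 2;
      double gy1 = M[lf] - (open + extend), gy2 = Iy[lf] - extend;
      Iy[c] = gy1 >= gy2 ? gy1 : gy2;
      tbY[c] = gy1 >= gy2 ? 1 : 2;
      double s = S.score(a[i - 1], b[j - 1]);
      double dM = M[dg], dX = Ix[dg], dY = Iy[dg];
      double d = dM; unsigned char t = 1;
      if (dX > d) { d = dX; t = 2; }
      if (dY > d) { d = dY; t = 3; }
      M[c] = d + s; tbM[c] = t;
    }
  }
  int cN = n * (m + 1) + m;
  double sc = M[cN]; int st = 0;
  if (Ix[cN] > sc) { sc = Ix[cN]; st = 1; }
  if (Iy[cN] > sc) { sc = Iy[cN]; st = 2; }
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int c = i * (m + 1) + j;
    if (st == 0) {
      unsigned char t = tbM[c];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
      st = (t == 1) ? 0 : (t == 2 ? 1 : 2);
    } else if (st == 1) {
      unsigned char t = tbX[c];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i;
      st = (t == 1) ? 0 : 1;
    } else {
      unsigned char t = tbY[c];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j;
      st = (t == 1) ? 0 : 2;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = sc, _["aligned_a"] = ra, _["aligned_b"] = rb);
}
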