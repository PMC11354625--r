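#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap pairwise aligners (Gotoh). Gap cost convention: a gap of
// length n costs open + extend*(n-1), i.e. `open` is charged for the
// first gapped position. Traceback ties resolve diagonal > up > left,
// so results are deterministic.

static const double NEG_INF = -1e18;

struct SubLookup {
  int idx[256];
  NumericMatrix m;
  SubLookup(NumericMatrix mat) : m(mat) {
    for (int i = 0; i < 256; ++i) idx[i] = -1;
    CharacterVector rn = rownames(mat);
    for (int i = 0; i < rn.size(); ++i) {
      std::string s = as<std::string>(rn[i]);
      idx[(unsigned char)s[0]] = i;
    }
  }
  double score(char a, char b) const {
    int ia = idx[(unsigned char)a], ib = idx[(unsigned char)b];
    if (ia < 0 || ib < 0) stop("residue not present in the scoring matrix");
    return m(ia, ib);
  }
};

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b, NumericMatrix submat,
                  double gap_open, double gap_extend) {
  SubLookup S(submat);
  int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  int w = m + 1;
  std::vector<double> M((n + 1) * w, NEG_INF), X((n + 1) * w, NEG_INF),
      Y((n + 1) * w, NEG_INF);
  std::vector<signed char> pM((n + 1) * w, 0), pX((n + 1) * w, 0),
      pY((n + 1) * w, 0);
  double best = 0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // gap states
      double xo = M[(i - 1) * w + j] - gap_open;
      double xe = X[(i - 1) * w + j] - gap_extend;
      if (xo >= xe) { X[i * w + j] = xo; pX[i * w + j] = 1; }
      else          { X[i * w + j] = xe; pX[i * w + j] = 2; }
      double yo = M[i * w + (j - 1)] - gap_open;
      double ye = Y[i * w + (j - 1)] - gap_extend;
      if (yo >= ye) { Y[i * w + j] = yo; pY[i * w + j] = 1; }
      else          { Y[i * w + j] = ye; pY[i * w + j] = 2; }
      // match state, preference diag(M) > up(X) > left(Y) > fresh start
      double dM = M[(i - 1) * w + (j - 1)];
      double dX = X[(i - 1) * w + (j - 1)];
      double dY = Y[(i - 1) * w + (j - 1)];
      double mx = dM; signed char p = 1;
      if (dX > mx) { mx = dX; p = 2; }
      if (dY > mx) { mx = dY; p = 3; }
      if (mx <= 0) { mx = 0; p = 0; }
      double v = S.score(a[i - 1], b[j - 1]) + mx;
      M[i * w + j] = v;
      pM[i * w + j] = p;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0.0, _["a_aln"] = "", _["b_aln"] = "",
                        _["a_start"] = 0, _["a_end"] = 0, _["b_start"] = 0,
                        _["b_end"] = 0, _["matches"] = 0, _["columns"] = 0);
  // local traceback: walk M until a fresh-start pointer
  int i = bi, j = bj, state = 0;
  std::string aa, bb;
  while (true) {
    if (state == 0) {
      signed char p = pM[i * w + j];
      aa.push_back(a[i - 1]);
      bb.push_back(b[j - 1]);
      --i; --j;
      if (p == 0) break;
      state = p - 1;
    } else if (state == 1) {
      signed char p = pX[i * w + j];
      aa.push_back(a[i - 1]);
      bb.push_back('-');
      --i;
      state = (p == 1) ? 0 : 1;
    } else {
      signed char p = pY[i * w + j];
      aa.push_back('-');
      bb.push_back(b[j - 1]);
      --j;
      state = (p == 1) ? 0 : 2;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  int matches = 0, columns = (int)aa.size();
  for (int c = 0; c < columns; ++c)
    if (aa[c] != '-' && bb[c] != '-' && aa[c] == bb[c]) ++matches;
  return List::create(_["score"] = best, _["a_aln"] = aa, _["b_aln"] = bb,
                      _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj,
                      _["matches"] = matches, _["columns"] = columns);
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b, NumericMatrix submat,
                  double gap_open, double gap_extend) {
  SubLookup S(submat);
  int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  int w = m + 1;
  std::vector<double> M((n + 1) * w, NEG_INF), X((n + 1) * w, NEG_INF),
      Y((n + 1) * w, NEG_INF);
  std::vector<signed char> pM((n + 1) * w, 0), pX((n + 1) * w, 0),
      pY((n + 1) * w, 0);
  M[0] = 0;
  for (int i = 1; i <= n; ++i) {
    X[i * w] = -(gap_open + gap_extend * (i - 1));
    pX[i * w] = (i == 1) ? 1 : 2;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -(gap_open + gap_extend * (j - 1));
    pY[j] = (j == 1) ? 1 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double xo = M[(i - 1) * w + j] - gap_open;
      double xe = X[(i - 1) * w + j] - gap_extend;
      if (xo >= xe) { X[i * w + j] = xo; pX[i * w + j] = 1; }
      else          { X[i * w + j] = xe; pX[i * w + j] = 2; }
      double yo = M[i * w + (j - 1)] - gap_open;
      double ye = Y[i * w + (j - 1)] - gap_extend;
      if (yo >= ye) { Y[i * w + j] = yo; pY[i * w + j] = 1; }
      else          { Y[i * w + j] = ye; pY[i * w + j] = 2; }
      double dM = M[(i - 1) * w + (j - 1)];
      double dX = X[(i - 1) * w + (j - 1)];
      double dY = Y[(i - 1) * w + (j - 1)];
      double mx = dM; signed char p = 1;
      if (dX > mx) { mx = dX; p = 2; }
      if (dY > mx) { mx = dY; p = 3; }
      M[i * w + j] = S.score(a[i - 1], b[j - 1]) + mx;
      pM[i * w + j] = p;
    }
  }
  double sM = M[n * w + m], sX = X[n * w + m], sY = Y[n * w + m];
  int state = 0;
  double best = sM;
  if (sX > best) { best = sX; state = 1; }
  if (sY > best) { best = sY; state = 2; }
  // global traceback to (0,0)
  int i = n, j = m;
  std::string aa, bb;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char p = pM[i * w + j];
      aa.push_back(a[i - 1]);
      bb.push_back(b[j - 1]);
      --i; --j;
      state = p - 1;  // p==1 -> M, 2 -> X, 3 -> Y
    } else if (state == 1) {
      signed char p = pX[i * w + j];
      aa.push_back(a[i - 1]);
      bb.push_back('-');
      --i;
      state = (p == 1) ? 0 : 1;
    } else {
      signed char p = pY[i * w + j];
      aa.push_back('-');
      bb.push_back(b[j - 1]);
      --j;
      state = (p == 1) ? 0 : 2;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  int matches = 0, columns = (int)aa.size();
  for (int c = 0; c < columns; ++c)
    if (aa[c] != '-' && bb[c] != '-' && aa[c] == bb[c]) ++matches;
  return List::create(_["score"] = best, _["a_aln"] = aa, _["b_aln"] = bb,
                      _["a_start"] = 1, _["a_end"] = n,
                      _["b_start"] = 1, _["b_end"] = m,
                      _["matches"] = matches, _["columns"] = columns);
}
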