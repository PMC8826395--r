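#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap alignment kernels. Sequences arrive as 0-based integer codes
// into the rows/columns of the substitution matrix. A gap of length L costs
// open + L * extend (the open penalty does not include the first extension).

// [[Rcpp::export]]
int sw_score_cpp(IntegerVector a, IntegerVector b, IntegerMatrix mat,
                 int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  const int NEG = INT_MIN / 4;
  const int gi = gap_open + gap_extend; // cost of opening a length-1 gap
  // Rolling rows: Hrow[j] holds H[i-1][j] until overwritten with H[i][j];
  // Ev[j] is the vertical gap state (gap in b, consuming a).
  std::vector<int> Hrow(m + 1, 0), Ev(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int Hdiag = Hrow[0]; // H[i-1][0]
    Hrow[0] = 0;
    int Eh = NEG; // horizontal gap state (gap in a, consuming b), row-local
    for (int j = 1; j <= m; ++j) {
      Ev[j] = std::max(Hrow[j] - gi, Ev[j] - gap_extend);
      Eh = std::max(Hrow[j - 1] - gi, Eh - gap_extend); // Hrow[j-1] = H[i][j-1]
      int diag = Hdiag + mat(a[i - 1], b[j - 1]);
      int h = std::max(std::max(diag, 0), std::max(Ev[j], Eh));
      Hdiag = Hrow[j];
      Hrow[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
NumericVector nw_identity_cpp(IntegerVector a, IntegerVector b,
                              NumericMatrix mat, double gap_open,
                              double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  const double gi = gap_open + gap_extend;
  // Gotoh with full matrices (traceback needed for the identity count).
  // X: gap in a (consumes b, moves along j); Y: gap in b (consumes a).
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  M(0, 0) = 0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; Y(0, j) = NEG;
    X(0, j) = -(gap_open + j * gap_extend);
  }
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; X(i, 0) = NEG;
    Y(i, 0) = -(gap_open + i * gap_extend);
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double pm = std::max(M(i - 1, j - 1),
                           std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = pm + mat(a[i - 1], b[j - 1]);
      X(i, j) = std::max(std::max(M(i, j - 1), Y(i, j - 1)) - gi,
                         X(i, j - 1) - gap_extend);
      Y(i, j) = std::max(std::max(M(i - 1, j), X(i - 1, j)) - gi,
                         Y(i - 1, j) - gap_extend);
    }
  }
  int i = n, j = m;
  double s0 = M(n, m), s1 = X(n, m), s2 = Y(n, m);
  double scr = std::max(s0, std::max(s1, s2));
  int state = (scr == s0) ? 0 : (scr == s1 ? 1 : 2);
  long ident = 0, len = 0;
  while (i > 0 || j > 0) {
    if (i == 0) state = 1;
    else if (j == 0) state = 2;
    if (state == 0) {
      len++;
      if (a[i - 1] == b[j - 1]) ident++;
      double pm = M(i, j) - mat(a[i - 1], b[j - 1]);
      i--; j--;
      if (pm == M(i, j)) state = 0;
      else if (pm == X(i, j)) state = 1;
      else state = 2;
    } else if (state == 1) { // gap column consuming b[j-1]
      len++;
      double v = X(i, j);
      if (v == X(i, j - 1) - gap_extend) state = 1;
      else if (v == M(i, j - 1) - gi) state = 0;
      else state = 2;
      j--;
    } else { // gap column consuming a[i-1]
      len++;
      double v = Y(i, j);
      if (v == Y(i - 1, j) - gap_extend) state = 2;
      else if (v == M(i - 1, j) - gi) state = 0;
      else state = 1;
      i--;
    }
  }
  return NumericVector::create(_["score"] = scr, _["identical"] = (double)ident,
                               _["length"] = (double)len);
}
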