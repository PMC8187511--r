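#include <Rcpp.h>
using namespace Rcpp;

// Gotoh global alignment of two alignment profiles with affine gaps.
// Profiles are residue-frequency matrices (alphabet x columns); gaps
// contribute nothing to the column frequencies, so the match score of two
// columns is sum_ab fa[a]*fb[b]*S[a,b]. A gap of length L costs
// open + L * ext (Biostrings' gapOpening/gapExtension convention).
// Returns a 2 x m path matrix of 1-based column indices, 0 = gap.

// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix fa, NumericMatrix fb, NumericMatrix S,
                       double open, double ext) {
  const int na = fa.ncol(), nb = fb.ncol(), K = S.nrow();
  if (fa.nrow() != K || fb.nrow() != K)
    stop("profile rows must match the scoring alphabet");
  const double NEG = -1e30;

  // pre-compute column-vs-column scores
  NumericMatrix cs(na, nb);
  // Sfa[k, i] = sum_a fa[a,i] * S[a,k]
  NumericMatrix Sfa(K, na);
  for (int i = 0; i < na; ++i)
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int a = 0; a < K; ++a) s += fa(a, i) * S(a, k);
      Sfa(k, i) = s;
    }
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += Sfa(k, i) * fb(k, j);
      cs(i, j) = s;
    }

  NumericMatrix M(na + 1, nb + 1), X(na + 1, nb + 1), Y(na + 1, nb + 1);
  // X: gap in B (consumes A column); Y: gap in A (consumes B column)
  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= na; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -open - ext * i;
  }
  for (int j = 1; j <= nb; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -open - ext * j;
  }
  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      double best = M(i - 1, j - 1);
      if (X(i - 1, j - 1) > best) best = X(i - 1, j - 1);
      if (Y(i - 1, j - 1) > best) best = Y(i - 1, j - 1);
      M(i, j) = best + cs(i - 1, j - 1);
      double xo = M(i - 1, j) - open - ext, xe = X(i - 1, j) - ext;
      X(i, j) = xo > xe ? xo : xe;
      double yo = M(i, j - 1) - open - ext, ye = Y(i, j - 1) - ext;
      Y(i, j) = yo > ye ? yo : ye;
    }
  }

  // traceback; ties prefer match > gap-in-B > gap-in-A
  std::vector<int> pa, pb;
  int i = na, j = nb;
  int state;  // 0 = M, 1 = X, 2 = Y
  {
    double m = M(na, nb), x = X(na, nb), y = Y(na, nb);
    state = (m >= x && m >= y) ? 0 : (x >= y ? 1 : 2);
  }
  while (i > 0 || j > 0) {
    if (i == 0) { pa.push_back(0); pb.push_back(j--); continue; }
    if (j == 0) { pa.push_back(i--); pb.push_back(0); continue; }
    if (state == 0) {
      pa.push_back(i); pb.push_back(j);
      double prev = M(i, j) - cs(i - 1, j - 1);
      --i; --j;
      double m = M(i, j), x = X(i, j), y = Y(i, j);
      (void)prev;
      state = (m >= x && m >= y) ? 0 : (x >= y ? 1 : 2);
    } else if (state == 1) {
      pa.push_back(i); pb.push_back(0);
      bool from_m = std::abs(X(i, j) - (M(i - 1, j) - open - ext)) < 1e-9;
      --i;
      state = from_m ? 0 : 1;
    } else {
      pa.push_back(0); pb.push_back(j);
      bool from_m = std::abs(Y(i, j) - (M(i, j - 1) - open - ext)) < 1e-9;
      --j;
      state = from_m ? 0 : 2;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  double sc = std::max(M(na, nb), std::max(X(na, nb), Y(na, nb)));
  return List::create(_["a"] = wrap(pa), _["b"] = wrap(pb), _["score"] = sc);
}

// Pairwise p-distances on an integer-coded alignment (rows = sequences).
// gap_code marks gaps/unknowns; pairs with no comparable column get
// distance 1 and are flagged.

// [[Rcpp::export]]
List pdist_cpp(IntegerMatrix seqs, int gap_code) {
  const int n = seqs.nrow(), L = seqs.ncol();
  NumericMatrix d(n, n);
  LogicalMatrix empty(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int comp = 0, mis = 0;
      for (int c = 0; c < L; ++c) {
        int a = seqs(i, c), b = seqs(j, c);
        if (a == gap_code || b == gap_code) continue;
        ++comp;
        if (a != b) ++mis;
      }
      double v;
      if (comp == 0) { v = 1.0; empty(i, j) = empty(j, i) = true; }
      else v = (double)mis / comp;
      d(i, j) = d(j, i) = v;
    }
  }
  return List::create(_["d"] = d, _["empty"] = empty);
}
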