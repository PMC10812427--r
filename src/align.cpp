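#include <Rcpp.h>
using namespace Rcpp;

// Global pairwise alignment with affine gap penalties.
//
// Scoring convention: a gap run of length g costs open + (g - 1) * ext
// (open and ext are negative). End gaps are penalized like internal gaps
// when end_gaps is true; otherwise leading and trailing gap runs are free
// (semiglobal). A column may not contain gaps in both rows, but a gap run
// in one sequence may be immediately followed by one in the other (the
// second run pays open again).
//
// a and b hold 0-based row/column indices into sub. Returns the optimal
// score and a deterministic traceback (tie order: diagonal > up > left,
// applied to both the final state and every predecessor choice).

static const double NEG = -1e30;

static inline int argmax3(double c0, double c1, double c2) {
  // preference order: 0 (diag/M), 1 (up/Ix), 2 (left/Iy)
  double best = c0;
  int arg = 0;
  if (c1 > best) { best = c1; arg = 1; }
  if (c2 > best) { best = c2; arg = 2; }
  return arg;
}

// [[Rcpp::export]]
List nw_affine_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                   double open, double ext, bool end_gaps) {
  const int m = a.size(), n = b.size();
  NumericMatrix M(m + 1, n + 1), Ix(m + 1, n + 1), Iy(m + 1, n + 1);

  M(0, 0) = 0.0; Ix(0, 0) = NEG; Iy(0, 0) = NEG;
  for (int i = 1; i <= m; ++i) {
    M(i, 0) = NEG; Iy(i, 0) = NEG;
    Ix(i, 0) = end_gaps ? open + (i - 1) * ext : 0.0;
  }
  for (int j = 1; j <= n; ++j) {
    M(0, j) = NEG; Ix(0, j) = NEG;
    Iy(0, j) = end_gaps ? open + (j - 1) * ext : 0.0;
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = sub(a[i - 1], b[j - 1]);
      double d0 = M(i - 1, j - 1), d1 = Ix(i - 1, j - 1), d2 = Iy(i - 1, j - 1);
      M(i, j) = s + std::max(d0, std::max(d1, d2));
      Ix(i, j) = std::max(M(i - 1, j) + open,
                 std::max(Ix(i - 1, j) + ext, Iy(i - 1, j) + open));
      Iy(i, j) = std::max(M(i, j - 1) + open,
                 std::max(Ix(i, j - 1) + open, Iy(i, j - 1) + ext));
    }
  }

  // Pick the end cell and state.
  int ei = m, ej = n;
  int state = argmax3(M(m, n), Ix(m, n), Iy(m, n));
  double score = std::max(M(m, n), std::max(Ix(m, n), Iy(m, n)));
  if (!end_gaps) {
    // Free trailing gaps: best over the last row and column.
    for (int i = 0; i <= m; ++i) {
      double v = std::max(M(i, n), std::max(Ix(i, n), Iy(i, n)));
      if (v > score) { score = v; ei = i; ej = n; }
    }
    for (int j = 0; j <= n; ++j) {
      double v = std::max(M(m, j), std::max(Ix(m, j), Iy(m, j)));
      if (v > score) { score = v; ei = m; ej = j; }
    }
    state = argmax3(M(ei, ej), Ix(ei, ej), Iy(ei, ej));
  }

  std::vector<int> qa, qb; // reversed aligned indices; -1 encodes a gap
  // Trailing free gaps (semiglobal only).
  for (int i = m; i > ei; --i) { qa.push_back(i - 1); qb.push_back(-1); }
  for (int j = n; j > ej; --j) { qa.push_back(-1); qb.push_back(j - 1); }

  int i = ei, j = ej;
  while (i > 0 || j > 0) {
    if (i == 0) { qa.push_back(-1); qb.push_back(--j); continue; }
    if (j == 0) { qa.push_back(--i); qb.push_back(-1); continue; }
    if (state == 0) {
      qa.push_back(i - 1); qb.push_back(j - 1);
      state = argmax3(M(i - 1, j - 1), Ix(i - 1, j - 1), Iy(i - 1, j - 1));
      --i; --j;
    } else if (state == 1) {
      qa.push_back(i - 1); qb.push_back(-1);
      state = argmax3(M(i - 1, j) + open, Ix(i - 1, j) + ext,
                      Iy(i - 1, j) + open);
      --i;
    } else {
      qa.push_back(-1); qb.push_back(j - 1);
      state = argmax3(M(i, j - 1) + open, Ix(i, j - 1) + open,
                      Iy(i, j - 1) + ext);
      --j;
    }
  }

  std::reverse(qa.begin(), qa.end());
  std::reverse(qb.begin(), qb.end());
  return List::create(
    _["score"] = score,
    _["a_idx"] = IntegerVector(qa.begin(), qa.end()),
    _["b_idx"] = IntegerVector(qb.begin(), qb.end())
  );
}

// Exhaustive-enumeration reference scorer: explores every global alignment
// (every monotone interleaving of diagonal, up and left moves with no
// gap-gap columns) and returns the best affine-gap score. Exponential in
// the sequence lengths; intended for validating the dynamic program on
// short sequences. End gaps are always penalized.

static void enum_rec(const int *a, const int *b, int i, int j, int m, int n,
                     const double *sub, int nrow, double open, double ext,
                     int last, double acc, double &best) {
  if (i == m && j == n) {
    if (acc > best) best = acc;
    return;
  }
  if (i < m && j < n) {
    enum_rec(a, b, i + 1, j + 1, m, n, sub, nrow, open, ext, 0,
             acc + sub[a[i] + nrow * b[j]], best);
  }
  if (i < m) {
    double g = (last == 1) ? ext : open;
    enum_rec(a, b, i + 1, j, m, n, sub, nrow, open, ext, 1, acc + g, best);
  }
  if (j < n) {
    double g = (last == 2) ? ext : open;
    enum_rec(a, b, i, j + 1, m, n, sub, nrow, open, ext, 2, acc + g, best);
  }
}

// [[Rcpp::export]]
double enumerate_global_score_cpp(IntegerVector a, IntegerVector b,
                                  NumericMatrix sub, double open, double ext) {
  if (a.size() > 10 || b.size() > 10)
    stop("enumeration oracle is limited to sequences of length <= 10");
  double best = NEG;
  enum_rec(a.begin(), b.begin(), 0, 0, a.size(), b.size(),
           sub.begin(), sub.nrow(), open, ext, -1, 0.0, best);
  return best;
}
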