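#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment of a sequence to the columns of a
// position-specific scoring model. Three states per cell:
//   M: column i paired with residue j (adds the column's score for the
//      residue),
//   D: column i paired with a gap (deletion relative to the profile),
//   I: residue j not assigned to any column (insertion in the sequence).
// Gap runs are charged `gap_open` for their first position and
// `gap_extend` for each further position; switching between D and I runs
// opens a new gap.
//
// scores: 20 x C matrix of per-column residue scores (bits).
// seq_idx: 1-based residue indices into the score rows; 0 marks a residue
// outside the 20-letter alphabet, scored as the column minimum.
// [[Rcpp::export(name = ".align_profile_cpp")]]
List align_profile_cpp(NumericMatrix scores, IntegerVector seq_idx,
                       double gap_open, double gap_extend) {
  const int C = scores.ncol();
  const int n = seq_idx.size();
  const double NEG = -1e100;

  NumericMatrix M(C + 1, n + 1), D(C + 1, n + 1), I(C + 1, n + 1);
  IntegerMatrix pM(C + 1, n + 1), pD(C + 1, n + 1), pI(C + 1, n + 1);
  // predecessor codes: 0 = M, 1 = D, 2 = I

  // column minima for out-of-alphabet residues
  std::vector<double> colmin(C);
  for (int i = 0; i < C; ++i) {
    double m = scores(0, i);
    for (int r = 1; r < 20; ++r) m = std::min(m, scores(r, i));
    colmin[i] = m;
  }

  M(0, 0) = 0.0; D(0, 0) = NEG; I(0, 0) = NEG;
  for (int i = 1; i <= C; ++i) {
    M(i, 0) = NEG;
    D(i, 0) = -(gap_open + (i - 1) * gap_extend);
    pD(i, 0) = 1;
    I(i, 0) = NEG;
  }
  for (int j = 1; j <= n; ++j) {
    M(0, j) = NEG;
    I(0, j) = -(gap_open + (j - 1) * gap_extend);
    pI(0, j) = 2;
    D(0, j) = NEG;
  }
  pD(1, 0) = 0;  // first deletion opens from the origin (M state)
  if (n > 0) pI(0, 1) = 0;

  for (int i = 1; i <= C; ++i) {
    for (int j = 1; j <= n; ++j) {
      int r = seq_idx[j - 1];
      double s = (r >= 1 && r <= 20) ? scores(r - 1, i - 1) : colmin[i - 1];
      // M
      double best = M(i - 1, j - 1); int arg = 0;
      if (D(i - 1, j - 1) > best) { best = D(i - 1, j - 1); arg = 1; }
      if (I(i - 1, j - 1) > best) { best = I(i - 1, j - 1); arg = 2; }
      M(i, j) = s + best; pM(i, j) = arg;
      // D (consume column i, gap in sequence)
      best = M(i - 1, j) - gap_open; arg = 0;
      if (D(i - 1, j) - gap_extend > best) { best = D(i - 1, j) - gap_extend; arg = 1; }
      if (I(i - 1, j) - gap_open > best) { best = I(i - 1, j) - gap_open; arg = 2; }
      D(i, j) = best; pD(i, j) = arg;
      // I (consume residue j, no column)
      best = M(i, j - 1) - gap_open; arg = 0;
      if (I(i, j - 1) - gap_extend > best) { best = I(i, j - 1) - gap_extend; arg = 2; }
      if (D(i, j - 1) - gap_open > best) { best = D(i, j - 1) - gap_open; arg = 1; }
      I(i, j) = best; pI(i, j) = arg;
    }
  }

  double score = M(C, n); int state = 0;
  if (D(C, n) > score) { score = D(C, n); state = 1; }
  if (I(C, n) > score) { score = I(C, n); state = 2; }

  // traceback: for every profile column, the 1-based residue index or NA
  IntegerVector map(C, NA_INTEGER);
  int i = C, j = n;
  while (i > 0 || j > 0) {
    if (state == 0) {            // M consumed column i and residue j
      map[i - 1] = j;
      int prev = pM(i, j); --i; --j; state = prev;
    } else if (state == 1) {     // D consumed column i
      int prev = pD(i, j); --i; state = prev;
    } else {                     // I consumed residue j
      int prev = pI(i, j); --j; state = prev;
    }
  }
  return List::create(_["score"] = score, _["column_map"] = map);
}
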