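#include <Rcpp.h>
using namespace Rcpp;

// Profile Smith-Waterman with affine gaps.
//
// logodds: profile-length x 21 matrix of per-column residue scores (nats).
// query:   1-based residue indices into the 21-letter alphabet.
// A gap of length L costs gap_open + L * gap_extend (both negative).
// States: M (query i aligned to profile column j), Ix (gap in profile:
// query residue consumed, "up"), Iy (gap in query: profile column
// consumed, "left"). Local: M is floored at 0 and alignments end in M.
// Tie-break: among equal-scoring end cells the smallest (query_end,
// profile_end) pair wins; traceback prefers diagonal > up > left.

// [[Rcpp::export]]
List sw_align_cpp(NumericMatrix logodds, IntegerVector query,
                  double gap_open, double gap_extend,
                  IntegerVector modal) {
  const int L = logodds.nrow();   // profile columns
  const int n = query.size();     // query residues
  const double NEG = -1e100;

  std::vector<double> M((n + 1) * (L + 1), 0.0);
  std::vector<double> Ix((n + 1) * (L + 1), NEG);
  std::vector<double> Iy((n + 1) * (L + 1), NEG);
  auto at = [L](int i, int j) { return i * (L + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= L; ++j) {
      double diag = std::max(std::max(M[at(i - 1, j - 1)], Ix[at(i - 1, j - 1)]),
                             Iy[at(i - 1, j - 1)]);
      if (diag < 0.0) diag = 0.0; // local restart
      double s = logodds(j - 1, query[i - 1] - 1);
      M[at(i, j)] = diag + s;
      if (M[at(i, j)] < 0.0) M[at(i, j)] = NEG / 2; // cannot end here usefully

      double upo = M[at(i - 1, j)] + gap_open + gap_extend;
      double upe = Ix[at(i - 1, j)] + gap_extend;
      Ix[at(i, j)] = std::max(upo, upe);
      double lfo = M[at(i, j - 1)] + gap_open + gap_extend;
      double lfe = Iy[at(i, j - 1)] + gap_extend;
      Iy[at(i, j)] = std::max(lfo, lfe);

      if (M[at(i, j)] > best) { // strict: keeps smallest (i, j) on ties
        best = M[at(i, j)];
        bi = i; bj = j;
      }
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0,
                        _["q_start"] = NA_INTEGER, _["q_end"] = NA_INTEGER,
                        _["p_start"] = NA_INTEGER, _["p_end"] = NA_INTEGER,
                        _["n_aligned"] = 0, _["n_modal_match"] = 0);
  }

  // traceback from (bi, bj) in state M
  int i = bi, j = bj, state = 0; // 0 = M, 1 = Ix(up), 2 = Iy(left)
  int n_aligned = 0, n_match = 0;
  int qs = bi, ps = bj;
  while (true) {
    if (state == 0) {
      ++n_aligned;
      if (query[i - 1] == modal[j - 1]) ++n_match;
      qs = i; ps = j;
      double diag = std::max(std::max(M[at(i - 1, j - 1)], Ix[at(i - 1, j - 1)]),
                             Iy[at(i - 1, j - 1)]);
      if (diag <= 0.0) break; // local alignment start
      // preference: diagonal > up > left
      if (M[at(i - 1, j - 1)] == diag) state = 0;
      else if (Ix[at(i - 1, j - 1)] == diag) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      double cur = Ix[at(i, j)];
      if (M[at(i - 1, j)] + gap_open + gap_extend == cur) state = 0;
      else state = 1;
      --i;
    } else {
      double cur = Iy[at(i, j)];
      if (M[at(i, j - 1)] + gap_open + gap_extend == cur) state = 0;
      else state = 2;
      --j;
    }
  }

  return List::create(_["score"] = best,
                      _["q_start"] = qs, _["q_end"] = bi,
                      _["p_start"] = ps, _["p_end"] = bj,
                      _["n_aligned"] = n_aligned,
                      _["n_modal_match"] = n_match);
}

// Brute-force oracle: enumerate every gapped local alignment (path of
// diagonal / up / left moves that starts and ends with a diagonal move --
// flanking gaps only subtract score and are dominated) and return the
// maximum score, floored at 0. Exponential; only for tiny inputs.

static double enum_best;

static void enum_dfs(const NumericMatrix &lo, const IntegerVector &q,
                     double go, double ge, int i, int j, double score,
                     int last /*0=diag,1=up,2=left*/) {
  const int n = q.size(), L = lo.nrow();
  if (last == 0 && score > enum_best) enum_best = score;
  // extend with a diagonal move
  if (i + 1 <= n && j + 1 <= L)
    enum_dfs(lo, q, go, ge, i + 1, j + 1,
             score + lo(j, q[i] - 1), 0);
  // up: consume a query residue (gap in profile)
  if (i + 1 <= n)
    enum_dfs(lo, q, go, ge, i + 1, j,
             score + (last == 1 ? ge : go + ge), 1);
  // left: consume a profile column (gap in query)
  if (j + 1 <= L)
    enum_dfs(lo, q, go, ge, i, j + 1,
             score + (last == 2 ? ge : go + ge), 2);
}

// [[Rcpp::export]]
double sw_enum_cpp(NumericMatrix logodds, IntegerVector query,
                   double gap_open, double gap_extend) {
  const int L = logodds.nrow(), n = query.size();
  if (n > 8 || L > 8) stop("enumeration oracle limited to 8 x 8");
  enum_best = 0.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= L; ++j) {
      enum_dfs(logodds, query, gap_open, gap_extend,
               i, j, logodds(j - 1, query[i - 1] - 1), 0);
    }
  }
  return enum_best;
}
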