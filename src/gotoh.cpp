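#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// Affine-gap Needleman-Wunsch (Gotoh three-state recurrence).
//
// States: M  -- P[i] aligned to Q[j];
//         IX -- P[i] aligned to a gap (gap in the Q row);
//         IY -- Q[j] aligned to a gap (gap in the P row).
// A gap run of length k costs open + k * extend (open charged once at the
// start of the run, extend per gap symbol), matching the NCBI BLAST
// convention for "-11 open / -1 extend".
//
// Semiglobal mode: leading and trailing gap runs in either row are free --
// first row/column initialized to zero, optimum taken over the last row
// and last column, trailing gaps appended outside the DP.
//
// Determinism: when states tie, prefer M over IX over IY; within a gap
// state prefer extension over opening.  Among equal-scoring semiglobal end
// cells, prefer (m, n), then the end cell with the fewest trailing gaps.
// Every tie encountered on the chosen path is reported via `ties`.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(NumericMatrix S, double gap_open, double gap_extend,
                 bool semiglobal) {
  const int m = S.nrow();   // |P|
  const int n = S.ncol();   // |Q|
  const double go = gap_open, ge = gap_extend;

  std::vector<double> M((m + 1) * (n + 1), NEG_INF);
  std::vector<double> IX((m + 1) * (n + 1), NEG_INF);
  std::vector<double> IY((m + 1) * (n + 1), NEG_INF);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= m; ++i)
    IX[at(i, 0)] = semiglobal ? 0.0 : go + i * ge;
  for (int j = 1; j <= n; ++j)
    IY[at(0, j)] = semiglobal ? 0.0 : go + j * ge;

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int ij = at(i, j), up = at(i - 1, j), lf = at(i, j - 1),
                dg = at(i - 1, j - 1);
      double best = std::max(M[dg], std::max(IX[dg], IY[dg]));
      M[ij] = best + S(i - 1, j - 1);
      IX[ij] = std::max(IX[up] + ge,
                        std::max(M[up], IY[up]) + go + ge);
      IY[ij] = std::max(IY[lf] + ge,
                        std::max(M[lf], IX[lf]) + go + ge);
    }
  }

  bool ties = false;
  auto cell_best = [&](int i, int j) {
    return std::max(M[at(i, j)], std::max(IX[at(i, j)], IY[at(i, j)]));
  };

  // End cell selection.
  int ei = m, ej = n;
  double score = cell_best(m, n);
  if (semiglobal) {
    // candidates: whole last column and last row, including the corner
    // cells (0, n) / (m, 0) whose paths are pure free leading gaps
    // (every column of such an alignment lies in a terminal gap run)
    for (int i = 0; i < m; ++i) score = std::max(score, cell_best(i, n));
    for (int j = 0; j < n; ++j) score = std::max(score, cell_best(m, j));
    int hits = (cell_best(m, n) == score) ? 1 : 0;
    bool found = hits > 0;
    // fewest trailing gaps first: walk outward from (m, n)
    for (int d = 1; d <= std::max(m, n); ++d) {
      int i = m - d, j = n - d;
      if (i >= 0 && cell_best(i, n) == score) {
        ++hits;
        if (!found) { ei = i; ej = n; found = true; }
      }
      if (j >= 0 && cell_best(m, j) == score) {
        ++hits;
        if (!found) { ei = m; ej = j; found = true; }
      }
    }
    if (hits > 1) ties = true;
  }

  // Pick a state at a cell with preference M > IX > IY, flagging ties.
  auto pick_state = [&](double vm, double vx, double vy) {
    double b = std::max(vm, std::max(vx, vy));
    int s = (vm == b) ? 0 : (vx == b ? 1 : 2);
    int eq = (vm == b) + (vx == b) + (vy == b);
    if (eq > 1 && b != NEG_INF) ties = true;
    return s;
  };

  // Traceback; ops recorded end-to-start then reversed:
  // 0 = match column, 1 = gap in Q row (consume P), 2 = gap in P row.
  std::vector<int> ops;
  ops.reserve(m + n);
  for (int j = n; j > ej; --j) ops.push_back(2);   // trailing free gaps
  for (int i = m; i > ei; --i) ops.push_back(1);

  int i = ei, j = ej;
  int state = pick_state(M[at(i, j)], IX[at(i, j)], IY[at(i, j)]);

  while (i > 0 || j > 0) {
    if (state == 0) {
      // M[i][j] came from the best of the three at (i-1, j-1)
      ops.push_back(0);
      --i; --j;
      if (i == 0 && j == 0) break;
      state = pick_state(M[at(i, j)], IX[at(i, j)], IY[at(i, j)]);
    } else if (state == 1) {
      ops.push_back(1);
      --i;
      if (i == 0 && j == 0) break;
      if (j == 0) {
        // first column: initialization region, stay in IX
        state = (i == 0) ? 0 : 1;
        if (i == 0) break;
        continue;
      }
      const int ij = at(i, j);
      double ext = IX[ij] + ge;
      double opn = M[ij] + go + ge;
      double swc = IY[ij] + go + ge;
      // prefer extension over opening at equal score
      double b = std::max(ext, std::max(opn, swc));
      int eq = (ext == b) + (opn == b) + (swc == b);
      if (eq > 1 && b != NEG_INF) ties = true;
      state = (ext == b) ? 1 : (opn == b ? 0 : 2);
    } else {
      ops.push_back(2);
      --j;
      if (i == 0 && j == 0) break;
      if (i == 0) {
        state = (j == 0) ? 0 : 2;
        if (j == 0) break;
        continue;
      }
      const int ij = at(i, j);
      double ext = IY[ij] + ge;
      double opn = M[ij] + go + ge;
      double swc = IX[ij] + go + ge;
      double b = std::max(ext, std::max(opn, swc));
      int eq = (ext == b) + (opn == b) + (swc == b);
      if (eq > 1 && b != NEG_INF) ties = true;
      state = (ext == b) ? 2 : (opn == b ? 0 : 1);
    }
  }

  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()),
                      _["ties"] = ties);
}
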