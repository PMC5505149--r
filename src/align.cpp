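#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Affine-gap pairwise DP (Gotoh) in two modes:
//
//   semiglobal: end-gap-free global ("overlap") alignment. The dynamic program
//     starts for free on an edge of one sequence (row 0 / column 0 initialised
//     to zero) and ends for free on an edge (maximum over the last row and last
//     column); interior gaps cost gap_open + L * gap_extend. A trailing charged
//     gap run in one sequence followed by a free overhang of the other is a
//     legal ending, so gap states are included in the final maximum.
//
//   local: Smith-Waterman with the same affine costs; optimum always ends on a
//     substitution column, no-hit when the best score is <= 0.
//
// Sequences arrive as 0-based integer codes into the substitution matrix.
// Determinism: during traceback prefer the diagonal move, then the gap that
// consumes the query; among co-optimal end cells prefer a substitution-column
// ending, then the smallest subject end coordinate, then the smallest query
// end coordinate.
//
// Reported statistics cover the aligned region only (first to last aligned
// residue pair, interior gap columns included); terminal charged gap columns
// affect the score but not aligned_cols or the spans.

static const int NEG_INF = INT_MIN / 4;

enum TB : unsigned char { TB_START = 0, TB_M = 1, TB_X = 2, TB_Y = 3 };

struct AlnOut {
  int score, aligned_cols, n_identical, n_similar;
  int q_start, q_end, s_start, s_end; // 0-based half-open on unaligned sequences
};

struct EndCell {
  int score; unsigned char state; int i, j; bool have;
  EndCell() : score(0), state(TB_M), i(0), j(0), have(false) {}
  // preference: higher score, then M endings, then smaller subject coord, then query
  void offer(int sc, unsigned char st, int ii, int jj) {
    if (sc <= 0) return;
    const int rank = (st == TB_M) ? 0 : 1;
    const int brank = (state == TB_M) ? 0 : 1;
    if (!have || sc > score ||
        (sc == score && (rank < brank ||
                         (rank == brank && (jj < j || (jj == j && ii < i)))))) {
      score = sc; state = st; i = ii; j = jj; have = true;
    }
  }
};

static AlnOut align_core(const int* a, int m, const int* b, int n,
                         const int* sub, int K, const int* ambig,
                         int go, int ge, bool local) {
  std::vector<int> Mp(n + 1), Xp(n + 1), Yp(n + 1);
  std::vector<int> Mc(n + 1), Xc(n + 1), Yc(n + 1);
  // traceback packed 2+2+2 bits per cell: M | X<<2 | Y<<4
  std::vector<unsigned char> tb((size_t)m * n);

  for (int j = 0; j <= n; ++j) { Mp[j] = 0; Xp[j] = NEG_INF; Yp[j] = NEG_INF; }

  EndCell end;

  for (int i = 1; i <= m; ++i) {
    Mc[0] = 0; Xc[0] = NEG_INF; Yc[0] = NEG_INF;
    const int* srow = sub + (size_t)a[i - 1] * K;
    unsigned char* trow = tb.data() + (size_t)(i - 1) * n;
    const int* Mpp = Mp.data(); const int* Xpp = Xp.data(); const int* Ypp = Yp.data();
    int* Mcp = Mc.data(); int* Xcp = Xc.data(); int* Ycp = Yc.data();
    const bool lastrow = (i == m);
    for (int j = 1; j <= n; ++j) {
      const int s = srow[b[j - 1]];

      // M: align a[i-1] with b[j-1]
      int vb = Mpp[j - 1];
      unsigned char tm = (i == 1 || j == 1) ? TB_START : TB_M;
      if (Xpp[j - 1] > vb) { vb = Xpp[j - 1]; tm = TB_X; }
      if (Ypp[j - 1] > vb) { vb = Ypp[j - 1]; tm = TB_Y; }
      if (local && 0 > vb) { vb = 0; tm = TB_START; }
      const int mm = s + vb;
      Mcp[j] = mm;

      // X: gap in subject, consumes query; may open from the free boundary
      const int vxm = Mpp[j] - go - ge;
      const int vxx = Xpp[j] - ge;
      unsigned char tx;
      if (vxm >= vxx) { Xcp[j] = vxm; tx = (i == 1) ? TB_START : TB_M; }
      else            { Xcp[j] = vxx; tx = TB_X; }

      // Y: gap in query, consumes subject
      const int vym = Mcp[j - 1] - go - ge;
      const int vyy = Ycp[j - 1] - ge;
      unsigned char ty;
      if (vym >= vyy) { Ycp[j] = vym; ty = (j == 1) ? TB_START : TB_M; }
      else            { Ycp[j] = vyy; ty = TB_Y; }

      trow[j - 1] = (unsigned char)(tm | (tx << 2) | (ty << 4));

      if (local) {
        if (mm >= end.score) end.offer(mm, TB_M, i, j);
      } else {
        if (lastrow || j == n) { if (mm >= end.score) end.offer(mm, TB_M, i, j); }
        if (j == n && i < m && Ycp[j] >= end.score) end.offer(Ycp[j], TB_Y, i, j);
        if (lastrow && j < n && Xcp[j] >= end.score) end.offer(Xcp[j], TB_X, i, j);
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  AlnOut out { 0, 0, 0, 0, 0, 0, 0, 0 };
  if (!end.have) return out;  // empty alignment (all-overhang) is optimal
  out.score = end.score;

  // walk the optimal path back to its start, recording every column,
  // then keep statistics for the aligned region only (first to last
  // aligned pair; charged terminal gap runs contribute score, not columns)
  std::vector<unsigned char> col_state;
  std::vector<int> col_i, col_j;
  int i = end.i, j = end.j; unsigned char state = end.state;
  while (true) {
    const size_t t = (size_t)(i - 1) * n + (j - 1);
    col_state.push_back(state); col_i.push_back(i); col_j.push_back(j);
    unsigned char nxt;
    if (state == TB_M)      { nxt = tb[t] & 3;        --i; --j; }
    else if (state == TB_X) { nxt = (tb[t] >> 2) & 3; --i; }
    else                    { nxt = (tb[t] >> 4) & 3; --j; }
    if (nxt == TB_START) break;
    state = nxt;
  }
  // columns are in reverse order; locate the extreme M columns
  int first_m = -1, last_m = -1;  // indices into the reversed vectors
  for (int k = 0; k < (int)col_state.size(); ++k) {
    if (col_state[k] == TB_M) { if (last_m < 0) last_m = k; first_m = k; }
  }
  // end.have guarantees at least one M column
  out.q_end = col_i[last_m]; out.s_end = col_j[last_m];
  out.q_start = col_i[first_m] - 1; out.s_start = col_j[first_m] - 1;
  for (int k = last_m; k <= first_m; ++k) {
    ++out.aligned_cols;
    if (col_state[k] == TB_M) {
      const int ci = col_i[k], cj = col_j[k];
      const int sc = sub[a[ci - 1] * K + b[cj - 1]];
      if (a[ci - 1] == b[cj - 1] && !ambig[a[ci - 1]]) ++out.n_identical;
      if (sc > 0) ++out.n_similar;
    }
  }
  return out;
}

// Score-only fill (rolling rows, no traceback).
static int score_core(const int* a, int m, const int* b, int n,
                      const int* sub, int K, int go, int ge, bool local) {
  std::vector<int> Mprev(n + 1, 0), Xprev(n + 1, NEG_INF), Yprev(n + 1, NEG_INF);
  std::vector<int> Mcur(n + 1), Xcur(n + 1), Ycur(n + 1);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    Mcur[0] = 0; Xcur[0] = NEG_INF; Ycur[0] = NEG_INF;
    const int* srow = sub + a[i - 1] * K;
    for (int j = 1; j <= n; ++j) {
      int vb = Mprev[j - 1];
      if (Xprev[j - 1] > vb) vb = Xprev[j - 1];
      if (Yprev[j - 1] > vb) vb = Yprev[j - 1];
      if (local && vb < 0) vb = 0;
      const int mm = srow[b[j - 1]] + vb;
      Mcur[j] = mm;
      int vx = Xprev[j] - ge;
      { const int o = Mprev[j] - go - ge; if (o > vx) vx = o; }
      Xcur[j] = vx;
      int vy = Ycur[j - 1] - ge;
      { const int o = Mcur[j - 1] - go - ge; if (o > vy) vy = o; }
      Ycur[j] = vy;
      if (local) {
        if (mm > best) best = mm;
      } else {
        if ((i == m || j == n) && mm > best) best = mm;
        if (j == n && i < m && Ycur[j] > best) best = Ycur[j];
        if (i == m && j < n && Xcur[j] > best) best = Xcur[j];
      }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }
  return best;
}

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                    IntegerVector ambig, int gap_open, int gap_extend, bool local) {
  const int K = sub.nrow();
  AlnOut o = align_core(INTEGER(a), a.size(), INTEGER(b), b.size(),
                        INTEGER(sub), K, INTEGER(ambig), gap_open, gap_extend, local);
  return List::create(_["score"] = o.score,
                      _["aligned_cols"] = o.aligned_cols,
                      _["n_identical"] = o.n_identical,
                      _["n_similar"] = o.n_similar,
                      _["q_start"] = o.q_start, _["q_end"] = o.q_end,
                      _["s_start"] = o.s_start, _["s_end"] = o.s_end);
}

// [[Rcpp::export(name = ".align_score_cpp")]]
int align_score_cpp(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                    int gap_open, int gap_extend, bool local) {
  return score_core(INTEGER(a), a.size(), INTEGER(b), b.size(),
                    INTEGER(sub), sub.nrow(), gap_open, gap_extend, local);
}

// All-pairs score matrix between two lists of encoded sequences.
// [[Rcpp::export(name = ".score_matrix_cpp")]]
IntegerMatrix score_matrix_cpp(List a_list, List b_list, IntegerMatrix sub,
                               int gap_open, int gap_extend, bool local) {
  const int K = sub.nrow();
  const int na = a_list.size(), nb = b_list.size();
  IntegerMatrix out(na, nb);
  std::vector<IntegerVector> bs(nb);
  for (int j = 0; j < nb; ++j) bs[j] = as<IntegerVector>(b_list[j]);
  for (int i = 0; i < na; ++i) {
    IntegerVector ai = as<IntegerVector>(a_list[i]);
    for (int j = 0; j < nb; ++j) {
      out(i, j) = score_core(INTEGER(ai), ai.size(), INTEGER(bs[j]), bs[j].size(),
                             INTEGER(sub), K, gap_open, gap_extend, local);
    }
  }
  return out;
}

// Symmetric all-pairs scores within one list (score(a,b) == score(b,a) for a
// fixed scheme); only the upper triangle is computed. Diagonal left 0.
// [[Rcpp::export(name = ".score_pairs_upper_cpp")]]
IntegerMatrix score_pairs_upper_cpp(List seqs, IntegerMatrix sub,
                                    int gap_open, int gap_extend, bool local) {
  const int K = sub.nrow();
  const int n = seqs.size();
  IntegerMatrix out(n, n);
  std::vector<IntegerVector> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = as<IntegerVector>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const int sc = score_core(INTEGER(xs[i]), xs[i].size(),
                                INTEGER(xs[j]), xs[j].size(),
                                INTEGER(sub), K, gap_open, gap_extend, local);
      out(i, j) = sc; out(j, i) = sc;
    }
  }
  return out;
}
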