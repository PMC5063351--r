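#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman (Gotoh) with a fully deterministic traceback.
//
// Three-state recurrence: M ends in an aligned pair, X ends in a gap in the
// subject (consumes query), Y ends in a gap in the query (consumes subject).
// A gap of length L costs gap_open + L * gap_extend (the opening column pays
// both). 'N' never matches anything, including another 'N'.
//
// Tie-breaking, everywhere, prefers M over X over Y ("diagonal, then up"),
// and the traceback starts from the first (smallest query index, then
// smallest subject index) cell attaining the maximal score.

static inline int subst(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  const long NEG = -1000000000L;

  std::vector<long> M((n + 1) * (m + 1), NEG);
  std::vector<long> X((n + 1) * (m + 1), NEG);
  std::vector<long> Y((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  long best = 0;
  int bi = 0, bj = 0;
  char bstate = '0';

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      long prev = 0;  // local: may start fresh
      long pm = M[at(i - 1, j - 1)], px = X[at(i - 1, j - 1)],
           py = Y[at(i - 1, j - 1)];
      if (pm > prev) prev = pm;
      if (px > prev) prev = px;
      if (py > prev) prev = py;
      M[at(i, j)] = prev + subst(a[i - 1], b[j - 1], match, mismatch);

      long xo = (M[at(i - 1, j)] > NEG) ? M[at(i - 1, j)] + gap_open + gap_extend : NEG;
      long xe = (X[at(i - 1, j)] > NEG) ? X[at(i - 1, j)] + gap_extend : NEG;
      long xy = (Y[at(i - 1, j)] > NEG) ? Y[at(i - 1, j)] + gap_open + gap_extend : NEG;
      X[at(i, j)] = std::max(xo, std::max(xe, xy));

      long yo = (M[at(i, j - 1)] > NEG) ? M[at(i, j - 1)] + gap_open + gap_extend : NEG;
      long ye = (Y[at(i, j - 1)] > NEG) ? Y[at(i, j - 1)] + gap_extend : NEG;
      long yx = (X[at(i, j - 1)] > NEG) ? X[at(i, j - 1)] + gap_open + gap_extend : NEG;
      Y[at(i, j)] = std::max(yo, std::max(ye, yx));

      // record maximum; strict '>' keeps the first cell under (i, j) order
      if (M[at(i, j)] > best) { best = M[at(i, j)]; bi = i; bj = j; bstate = 'M'; }
      if (X[at(i, j)] > best) { best = X[at(i, j)]; bi = i; bj = j; bstate = 'X'; }
      if (Y[at(i, j)] > best) { best = Y[at(i, j)]; bi = i; bj = j; bstate = 'Y'; }
    }
  }

  if (best <= 0) {
    return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0,
                        _["n_match"] = 0, _["n_col"] = 0);
  }

  // traceback
  int i = bi, j = bj;
  char state = bstate;
  int n_match = 0, n_col = 0;
  int q_end = bi, s_end = bj;
  while (true) {
    if (state == 'M') {
      ++n_col;
      if (a[i - 1] != 'N' && a[i - 1] == b[j - 1]) ++n_match;
      long pm = M[at(i - 1, j - 1)], px = X[at(i - 1, j - 1)],
           py = Y[at(i - 1, j - 1)];
      long prev = std::max((long)0, std::max(pm, std::max(px, py)));
      --i; --j;
      if (prev <= 0) break;  // alignment starts here
      if (pm == prev) state = 'M';
      else if (px == prev) state = 'X';
      else state = 'Y';
    } else if (state == 'X') {
      ++n_col;
      long cur = X[at(i, j)];
      long pm = (M[at(i - 1, j)] > NEG) ? M[at(i - 1, j)] + gap_open + gap_extend : NEG;
      long px = (X[at(i - 1, j)] > NEG) ? X[at(i - 1, j)] + gap_extend : NEG;
      --i;
      if (pm == cur) state = 'M';
      else if (px == cur) state = 'X';
      else state = 'Y';
    } else {
      ++n_col;
      long cur = Y[at(i, j)];
      long pm = (M[at(i, j - 1)] > NEG) ? M[at(i, j - 1)] + gap_open + gap_extend : NEG;
      long px = (X[at(i, j - 1)] > NEG) ? X[at(i, j - 1)] + gap_open + gap_extend : NEG;
      --j;
      if (pm == cur) state = 'M';
      else if (px == cur) state = 'X';
      else state = 'Y';
    }
  }

  return List::create(_["score"] = (double)best,
                      _["q_start"] = i, _["q_end"] = q_end,
                      _["s_start"] = j, _["s_end"] = s_end,
                      _["n_match"] = n_match, _["n_col"] = n_col);
}
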