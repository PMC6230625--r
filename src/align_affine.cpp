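#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps (Gotoh) and a
// bisulfite-aware asymmetric substitution rule: a reference C accepts either
// C or T in the read as a match (conversion-expected at non-CpG Cs,
// state-informative at CpG Cs), every other reference base requires an exact
// match; N never matches. A gap of length L costs gap_open + (L-1)*gap_ext.
//
// Returns the optimal score and one optimal pair of gapped strings
// (ties broken deterministically: substitution > gap-in-read > gap-in-ref).

static inline bool is_match(char r, char q) {
  if (r == 'N' || q == 'N') return false;
  if (r == 'C') return q == 'C' || q == 'T';
  return r == q;
}

// [[Rcpp::export(name = ".cpp_align_affine")]]
List cpp_align_affine(std::string ref, std::string read,
                      double match, double mismatch,
                      double gap_open, double gap_ext) {
  const int n = ref.size(), m = read.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  // M: ref[i] aligned to read[j]; X: gap in read (ref consumed);
  // Y: gap in ref (read consumed)
  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  // traceback: which of M/X/Y the cell came from (0=M,1=X,2=Y)
  std::vector<unsigned char> tM((n + 1) * (m + 1)), tX((n + 1) * (m + 1)),
      tY((n + 1) * (m + 1));
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = gap_open + (i - 1) * gap_ext;
    tX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = gap_open + (j - 1) * gap_ext;
    tY[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = is_match(ref[i - 1], read[j - 1]) ? match : mismatch;
      // M
      double bm = M[at(i - 1, j - 1)];
      unsigned char tb = 0;
      if (X[at(i - 1, j - 1)] > bm) { bm = X[at(i - 1, j - 1)]; tb = 1; }
      if (Y[at(i - 1, j - 1)] > bm) { bm = Y[at(i - 1, j - 1)]; tb = 2; }
      M[at(i, j)] = bm + s;
      tM[at(i, j)] = tb;
      // X: gap in read, consume ref[i-1]
      double open = M[at(i - 1, j)] + gap_open;
      double ext = X[at(i - 1, j)] + gap_ext;
      double openY = Y[at(i - 1, j)] + gap_open;
      if (open >= ext && open >= openY) { X[at(i, j)] = open; tX[at(i, j)] = 0; }
      else if (ext >= openY)            { X[at(i, j)] = ext;  tX[at(i, j)] = 1; }
      else                              { X[at(i, j)] = openY; tX[at(i, j)] = 2; }
      // Y: gap in ref, consume read[j-1]
      double openM = M[at(i, j - 1)] + gap_open;
      double extY = Y[at(i, j - 1)] + gap_ext;
      double openX = X[at(i, j - 1)] + gap_open;
      if (openM >= extY && openM >= openX) { Y[at(i, j)] = openM; tY[at(i, j)] = 0; }
      else if (extY >= openX)              { Y[at(i, j)] = extY;  tY[at(i, j)] = 2; }
      else                                 { Y[at(i, j)] = openX; tY[at(i, j)] = 1; }
    }
  }

  double best = M[at(n, m)];
  int state = 0;
  if (X[at(n, m)] > best) { best = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > best) { best = Y[at(n, m)]; state = 2; }

  std::string ra, qa;
  ra.reserve(n + m);
  qa.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char prev = tM[at(i, j)];
      ra.push_back(ref[i - 1]);
      qa.push_back(read[j - 1]);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      unsigned char prev = tX[at(i, j)];
      ra.push_back(ref[i - 1]);
      qa.push_back('-');
      --i;
      state = prev;
    } else {
      unsigned char prev = tY[at(i, j)];
      ra.push_back('-');
      qa.push_back(read[j - 1]);
      --j;
      state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(qa.begin(), qa.end());

  return List::create(_["score"] = best, _["ref_aln"] = ra,
                      _["read_aln"] = qa);
}
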