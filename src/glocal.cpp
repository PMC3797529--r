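#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Glocal affine-gap alignment of one DNA sequence against a position-specific
// scoring profile: global over the profile (every match position is either
// emitted against a residue or deleted), local over the sequence (unaligned
// leading/trailing residues are free; internal insertions pay affine costs).
//
// emis : L x 5 score matrix (columns A,C,G,T,N), bits.
// seq  : residues encoded 0..4 (A,C,G,T,N).
// Tie-break among predecessor states is fixed: match > delete > insert.
//
// Returns score, the residue (or -1 for a deletion) placed at each of the L
// profile positions, and the 0-based half-open interval of the sequence that
// the alignment consumes.
// [[Rcpp::export]]
List glocal_align(NumericMatrix emis, IntegerVector seq,
                  double gap_open, double gap_extend) {
  const int L = emis.nrow();
  const int m = seq.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  // state layers, row-major (L+1) x (m+1)
  std::vector<double> M((L + 1) * (m + 1), NEG), D = M, I = M;
  // traceback: predecessor state per cell (0=M,1=D,2=I,3=start)
  std::vector<signed char> pM(M.size(), -1), pD(M.size(), -1), pI(M.size(), -1);
  const int W = m + 1;
#define IX(i, j) ((i) * W + (j))
  for (int j = 0; j <= m; ++j) { M[IX(0, j)] = 0.0; pM[IX(0, j)] = 3; }
  for (int i = 1; i <= L; ++i) {
    const double eA = emis(i - 1, 0), eC = emis(i - 1, 1), eG = emis(i - 1, 2),
                 eT = emis(i - 1, 3), eN = emis(i - 1, 4);
    for (int j = 0; j <= m; ++j) {
      // delete: profile position i skipped, no residue consumed
      double dM = M[IX(i - 1, j)] + gap_open;
      double dD = D[IX(i - 1, j)] + gap_extend;
      if (dM >= dD) { D[IX(i, j)] = dM; pD[IX(i, j)] = 0; }
      else          { D[IX(i, j)] = dD; pD[IX(i, j)] = 1; }
      if (j >= 1) {
        // match: residue j emitted at profile position i
        double e;
        switch (seq[j - 1]) {
          case 0: e = eA; break; case 1: e = eC; break;
          case 2: e = eG; break; case 3: e = eT; break;
          default: e = eN;
        }
        double b = M[IX(i - 1, j - 1)]; signed char p = 0;
        if (D[IX(i - 1, j - 1)] > b) { b = D[IX(i - 1, j - 1)]; p = 1; }
        if (I[IX(i - 1, j - 1)] > b) { b = I[IX(i - 1, j - 1)]; p = 2; }
        M[IX(i, j)] = b + e; pM[IX(i, j)] = p;
        // insert: residue j consumed between profile positions
        double iM = M[IX(i, j - 1)] + gap_open;
        double iI = I[IX(i, j - 1)] + gap_extend;
        if (iM >= iI) { I[IX(i, j)] = iM; pI[IX(i, j)] = 0; }
        else          { I[IX(i, j)] = iI; pI[IX(i, j)] = 2; }
      }
    }
  }
  // free trailing sequence: best over end column j, prefer match, smallest j
  double best = NEG; int bj = 0; int bs = 0;
  for (int j = 0; j <= m; ++j) {
    if (M[IX(L, j)] > best) { best = M[IX(L, j)]; bj = j; bs = 0; }
    if (D[IX(L, j)] > best) { best = D[IX(L, j)]; bj = j; bs = 1; }
  }
  IntegerVector aligned(L, -1);
  int i = L, j = bj, s = bs;
  int minj = bj, maxj = bj;
  while (i > 0) {
    if (s == 0) { // match at (i, j)
      aligned[i - 1] = seq[j - 1];
      if (j < minj) minj = j;
      s = pM[IX(i, j)]; --i; --j;
    } else if (s == 1) { // delete
      s = pD[IX(i, j)]; --i;
    } else { // insert
      s = pI[IX(i, j)]; --j;
    }
  }
  int seq_start = minj > 0 ? minj - 1 : j;
  int seq_end = maxj;
  if (seq_end < seq_start) { seq_start = 0; seq_end = 0; }
  return List::create(_["score"] = best, _["aligned"] = aligned,
                      _["seq_start"] = seq_start, _["seq_end"] = seq_end);
#undef IX
}
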