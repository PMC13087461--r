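#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdlib>
using namespace Rcpp;

// Banded global alignment with affine gaps (Gotoh), read = query vs
// reference. A gap of length k scores gap_open + k * gap_extend.
// CIGAR convention: M consumes both, I consumes the read (gap in the
// reference), D consumes the reference (gap in the read).
// Deterministic tie-breaking: diagonal (match/mismatch) over a gap, then
// gap-in-read (D) over gap-in-reference (I); within a gap state, extension
// over opening.
//
// Cells (i, j) with |j - i| <= band are kept; storage is one row of
// 2*band+1 diagonals per read position.

static const double NEG = -1e18;

// [[Rcpp::export]]
List banded_align_cpp(std::string read, std::string ref, int band,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  int m = (int)read.size(), n = (int)ref.size();
  if (band < 0) stop("band-width error: band_width must be >= 0");
  if (std::abs(n - m) > band)
    stop("band-width error: |len(read) - len(ref)| exceeds band_width");

  int W = 2 * band + 1;
  size_t sz = (size_t)(m + 1) * W;
  std::vector<double> H(sz, NEG), E(sz, NEG), F(sz, NEG);
  // tbH: 0 diag, 1 from E (D-gap ends), 2 from F (I-gap ends), 3 origin
  // tbE/tbF: 1 extended, 0 opened from H
  std::vector<unsigned char> tbH(sz, 3), tbE(sz, 0), tbF(sz, 0);

  auto idx = [&](int i, int k) { return (size_t)i * W + k; };
  // j = i + (k - band)

  H[idx(0, band)] = 0.0;
  for (int j = 1; j <= n && j <= band; ++j) {       // leading gap in read (D)
    int k = j + band;                                // i = 0
    E[idx(0, k)] = gap_open + j * gap_extend;
    tbE[idx(0, k)] = (j > 1);
    H[idx(0, k)] = E[idx(0, k)];
    tbH[idx(0, k)] = 1;
  }
  for (int i = 1; i <= m && i <= band; ++i) {       // leading gap in ref (I)
    int k = band - i;                                // j = 0
    F[idx(i, k)] = gap_open + i * gap_extend;
    tbF[idx(i, k)] = (i > 1);
    H[idx(i, k)] = F[idx(i, k)];
    tbH[idx(i, k)] = 2;
  }

  for (int i = 1; i <= m; ++i) {
    for (int k = 0; k < W; ++k) {
      int j = i + k - band;
      if (j < 1 || j > n) continue;
      size_t c = idx(i, k);

      // E: gap in read (D), moves j; previous cell (i, j-1) = diagonal k-1
      if (k - 1 >= 0) {
        size_t p = idx(i, k - 1);
        double e_ext = (E[p] <= NEG / 2) ? NEG : E[p] + gap_extend;
        double e_opn = (H[p] <= NEG / 2) ? NEG : H[p] + gap_open + gap_extend;
        if (e_ext >= e_opn && e_ext > NEG / 2) { E[c] = e_ext; tbE[c] = 1; }
        else if (e_opn > NEG / 2)             { E[c] = e_opn; tbE[c] = 0; }
      }
      // F: gap in reference (I), moves i; previous cell (i-1, j) = k+1
      if (k + 1 < W) {
        size_t p = idx(i - 1, k + 1);
        double f_ext = (F[p] <= NEG / 2) ? NEG : F[p] + gap_extend;
        double f_opn = (H[p] <= NEG / 2) ? NEG : H[p] + gap_open + gap_extend;
        if (f_ext >= f_opn && f_ext > NEG / 2) { F[c] = f_ext; tbF[c] = 1; }
        else if (f_opn > NEG / 2)             { F[c] = f_opn; tbF[c] = 0; }
      }
      // H: diagonal from (i-1, j-1) = same k
      double diag = NEG;
      size_t pd = idx(i - 1, k);
      if (H[pd] > NEG / 2)
        diag = H[pd] + (read[i - 1] == ref[j - 1] ? match : mismatch);

      double best = diag; unsigned char tb = 0;
      if (E[c] > best) { best = E[c]; tb = 1; }
      if (F[c] > best) { best = F[c]; tb = 2; }
      if (best > NEG / 2) { H[c] = best; tbH[c] = tb; }
    }
  }

  int kend = n - m + band;
  double score = H[idx(m, kend)];
  if (score <= NEG / 2)
    stop("band-width error: no path through the band");

  // traceback
  std::string ops; ops.reserve(m + n);
  int i = m, k = kend, state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 || i + k - band > 0) {
    size_t c = idx(i, k);
    if (state == 0) {
      unsigned char tb = tbH[c];
      if (tb == 0)      { ops.push_back('M'); --i; }      // k unchanged
      else if (tb == 1) { state = 1; }
      else if (tb == 2) { state = 2; }
      else break;
    } else if (state == 1) {
      ops.push_back('D');
      unsigned char tb = tbE[c];
      --k;                                                // j decreases
      if (!tb) state = 0;
    } else {
      ops.push_back('I');
      unsigned char tb = tbF[c];
      --i; ++k;                                           // i decreases
      if (!tb) state = 0;
    }
  }

  // run-length encode reversed op string
  std::string cigar;
  int run = 0; char cur = 0;
  for (int p = (int)ops.size() - 1; p >= -1; --p) {
    char op = (p >= 0) ? ops[p] : 0;
    if (op == cur) { ++run; continue; }
    if (run > 0) { cigar += std::to_string(run); cigar.push_back(cur); }
    cur = op; run = 1;
  }
  if (cigar.empty()) cigar = "";

  return List::create(_["score"] = score, _["cigar"] = cigar);
}
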