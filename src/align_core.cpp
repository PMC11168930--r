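// Core alignment kernels: exact k-mer seed finding, banded global DP for
// nucleotide pairs, and affine-gap local (Smith-Waterman) alignment for
// proteins.  Sequences arrive as plain character strings; lowercase bases are
// soft-masked and never seed, but align like their uppercase counterparts.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <climits>
#include <cctype>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;  // N, lowercase (masked), anything else
  }
}

// Exact k-mer matches between s1 and s2 (2 <= k <= 31).  Lowercase and
// ambiguous bases break seeds.  k-mers occurring more than max_occ times in s2
// are skipped (repeat damping).  With self_mode only pairs i < j are emitted.
// stride subsamples s1 start positions.  Returns a 2-column 0-based matrix.
// [[Rcpp::export]]
IntegerMatrix kmer_hits_cpp(std::string s1, std::string s2, int k,
                            int max_occ = 64, bool self_mode = false,
                            int stride = 1) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  if (stride < 1) stop("stride must be >= 1");
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  std::unordered_map<uint64_t, std::vector<int> > index;
  const int n2 = (int) s2.size();
  {
    uint64_t h = 0;
    int run = 0;  // valid bases accumulated
    for (int p = 0; p < n2; ++p) {
      int b = base2bits(s2[(size_t) p]);
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t) b) & mask;
      if (++run >= k) index[h].push_back(p - k + 1);
    }
  }
  std::vector<int> out1, out2;
  const int n1 = (int) s1.size();
  uint64_t h = 0;
  int run = 0;
  for (int p = 0; p < n1; ++p) {
    int b = base2bits(s1[(size_t) p]);
    if (b < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t) b) & mask;
    if (++run >= k) {
      int i = p - k + 1;
      if (i % stride != 0) continue;
      std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
        index.find(h);
      if (it == index.end()) continue;
      const std::vector<int>& pos = it->second;
      if ((int) pos.size() > max_occ) continue;
      for (size_t q = 0; q < pos.size(); ++q) {
        int j = pos[q];
        if (self_mode && i >= j) continue;
        out1.push_back(i);
        out2.push_back(j);
      }
    }
  }
  IntegerMatrix out((int) out1.size(), 2);
  for (int r = 0; r < (int) out1.size(); ++r) {
    out(r, 0) = out1[(size_t) r];
    out(r, 1) = out2[(size_t) r];
  }
  return out;
}

// Banded global alignment with linear gap cost.  Case-insensitive; 'N' never
// matches anything (including another N).  The band covers diagonals
// [min(0, n2-n1) - band, max(0, n2-n1) + band] so the (n1, n2) corner is
// always reachable.  Returns match/mismatch/gap column counts.
// [[Rcpp::export]]
List banded_global_cpp(std::string s1, std::string s2, int match = 1,
                       int mismatch = -2, int gap = -3, int band = 200) {
  const int n1 = (int) s1.size(), n2 = (int) s2.size();
  if (n1 == 0 || n2 == 0) stop("empty sequence in banded_global");
  if (band < 1) stop("band must be positive");
  const int dlo = std::min(0, n2 - n1) - band;
  const int dhi = std::max(0, n2 - n1) + band;
  const int W = dhi - dlo + 1;
  const int NEG = INT_MIN / 4;
  std::vector<int> prev((size_t) W, NEG), cur((size_t) W, NEG);
  std::vector<uint8_t> tb((size_t) (n1 + 1) * (size_t) W, 0);
  // row i = 0: leading gap in s1
  for (int w = 0; w < W; ++w) {
    int j = 0 + dlo + w;
    if (j >= 0 && j <= n2) {
      prev[(size_t) w] = gap * j;
      if (j > 0) tb[(size_t) w] = 3;  // left
    }
  }
  for (int i = 1; i <= n1; ++i) {
    char a = (char) std::toupper((unsigned char) s1[(size_t) (i - 1)]);
    for (int w = 0; w < W; ++w) cur[(size_t) w] = NEG;
    for (int w = 0; w < W; ++w) {
      int j = i + dlo + w;
      if (j < 0 || j > n2) continue;
      int best = NEG; uint8_t dir = 0;
      if (j > 0) {  // diagonal
        int sc = prev[(size_t) w];
        if (sc > NEG) {
          char b = (char) std::toupper((unsigned char) s2[(size_t) (j - 1)]);
          bool ok = (a == b) && a != 'N';
          sc += ok ? match : mismatch;
          if (sc > best) { best = sc; dir = 1; }
        }
      }
      if (w + 1 < W) {  // up: consume s1 base (gap in s2)
        int sc = prev[(size_t) (w + 1)];
        if (sc > NEG && sc + gap > best) { best = sc + gap; dir = 2; }
      }
      if (w > 0 && j > 0) {  // left: consume s2 base (gap in s1)
        int sc = cur[(size_t) (w - 1)];
        if (sc > NEG && sc + gap > best) { best = sc + gap; dir = 3; }
      }
      if (dir != 0) {
        cur[(size_t) w] = best;
        tb[(size_t) i * (size_t) W + (size_t) w] = dir;
      }
    }
    std::swap(prev, cur);
  }
  const int wEnd = n2 - n1 - dlo;
  if (wEnd < 0 || wEnd >= W) stop("band does not reach alignment end");
  int score = prev[(size_t) wEnd];
  if (score <= NEG) stop("no alignment within band; increase band_width");
  // traceback
  int i = n1, w = wEnd;
  long matches = 0, mismatches = 0, gapcols = 0;
  while (true) {
    int j = i + dlo + w;
    if (i == 0 && j == 0) break;
    uint8_t dir = tb[(size_t) i * (size_t) W + (size_t) w];
    if (dir == 1) {
      char a = (char) std::toupper((unsigned char) s1[(size_t) (i - 1)]);
      char b = (char) std::toupper((unsigned char) s2[(size_t) (j - 1)]);
      if (a == b && a != 'N') ++matches; else ++mismatches;
      i -= 1;  // w unchanged: diagonal constant
    } else if (dir == 2) {
      ++gapcols; i -= 1; w += 1;
    } else if (dir == 3) {
      ++gapcols; w -= 1;
    } else {
      stop("traceback failure in banded_global");
    }
  }
  long cols = matches + mismatches + gapcols;
  return List::create(
    _["score"] = score, _["matches"] = (double) matches,
    _["mismatches"] = (double) mismatches, _["gap_cols"] = (double) gapcols,
    _["columns"] = (double) cols,
    _["identity_pct"] = cols ? 100.0 * (double) matches / (double) cols : 0.0,
    _["gap_pct"] = cols ? 100.0 * (double) gapcols / (double) cols : 0.0);
}

// Affine-gap Smith-Waterman with a substitution matrix.  A gap of length L
// costs gap_open + L * gap_ext (both positive penalties), matching the
// Biostrings pairwiseAlignment convention.  Returns the best local alignment's
// score, column counts and 0-based half-open coordinates in both sequences.
// [[Rcpp::export]]
List smith_waterman_cpp(std::string s1, std::string s2, IntegerMatrix sub,
                        std::string alphabet, double gap_open = 10,
                        double gap_ext = 1) {
  const int n1 = (int) s1.size(), n2 = (int) s2.size();
  if (n1 == 0 || n2 == 0) stop("empty sequence in smith_waterman");
  if ((double) n1 * (double) n2 > 4e7) stop("sequences too long for local DP");
  int lut[256];
  for (int c = 0; c < 256; ++c) lut[c] = -1;
  for (size_t a = 0; a < alphabet.size(); ++a)
    lut[(unsigned char) alphabet[a]] = (int) a;
  std::vector<int> e1((size_t) n1), e2((size_t) n2);
  for (int i = 0; i < n1; ++i) {
    int v = lut[(unsigned char) std::toupper((unsigned char) s1[(size_t) i])];
    if (v < 0) stop("residue '%s' not in alphabet",
                    std::string(1, s1[(size_t) i]).c_str());
    e1[(size_t) i] = v;
  }
  for (int j = 0; j < n2; ++j) {
    int v = lut[(unsigned char) std::toupper((unsigned char) s2[(size_t) j])];
    if (v < 0) stop("residue '%s' not in alphabet",
                    std::string(1, s2[(size_t) j]).c_str());
    e2[(size_t) j] = v;
  }
  const double NEG = -1e18;
  const size_t cols = (size_t) n2 + 1;
  std::vector<double> Hprev(cols, 0.0), Hcur(cols, 0.0);
  std::vector<double> Eprev(cols, NEG), Ecur(cols, NEG);  // gap in s2 (up)
  std::vector<double> Frow(cols, NEG);                    // gap in s1 (left)
  // H traceback: 0 stop, 1 diag, 2 close-from-E, 3 close-from-F
  // E/F tracebacks: 1 if extension (stay in gap), 0 if opened from H
  std::vector<uint8_t> tbH((size_t) (n1 + 1) * cols, 0);
  std::vector<uint8_t> tbE((size_t) (n1 + 1) * cols, 0);
  std::vector<uint8_t> tbF((size_t) (n1 + 1) * cols, 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n1; ++i) {
    Frow.assign(cols, NEG);
    Hcur[0] = 0.0; Ecur[0] = NEG;
    for (int j = 1; j <= n2; ++j) {
      const size_t at = (size_t) i * cols + (size_t) j;
      double eOpen = Hprev[(size_t) j] - gap_open - gap_ext;
      double eExt  = Eprev[(size_t) j] - gap_ext;
      if (eExt > eOpen) { Ecur[(size_t) j] = eExt; tbE[at] = 1; }
      else             { Ecur[(size_t) j] = eOpen; tbE[at] = 0; }
      double fOpen = Hcur[(size_t) (j - 1)] - gap_open - gap_ext;
      double fExt  = Frow[(size_t) (j - 1)] - gap_ext;
      if (fExt > fOpen) { Frow[(size_t) j] = fExt; tbF[at] = 1; }
      else              { Frow[(size_t) j] = fOpen; tbF[at] = 0; }
      double diag = Hprev[(size_t) (j - 1)] +
        (double) sub(e1[(size_t) (i - 1)], e2[(size_t) (j - 1)]);
      double h = 0.0; uint8_t dir = 0;
      if (diag > h) { h = diag; dir = 1; }
      if (Ecur[(size_t) j] > h) { h = Ecur[(size_t) j]; dir = 2; }
      if (Frow[(size_t) j] > h) { h = Frow[(size_t) j]; dir = 3; }
      Hcur[(size_t) j] = h;
      tbH[at] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  // traceback from (bi, bj); state 0 = H, 1 = E (gap in s2), 2 = F (gap in s1)
  long matches = 0, mm = 0, gapcols = 0;
  int i = bi, j = bj, state = 0;
  while (i > 0 || j > 0) {
    const size_t at = (size_t) i * cols + (size_t) j;
    if (state == 0) {
      uint8_t dir = tbH[at];
      if (dir == 0) break;
      if (dir == 1) {
        if (e1[(size_t) (i - 1)] == e2[(size_t) (j - 1)]) ++matches; else ++mm;
        --i; --j;
      } else if (dir == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {  // E: consume an s1 base
      uint8_t ext = tbE[at];
      ++gapcols; --i;
      state = ext ? 1 : 0;
    } else {                  // F: consume an s2 base
      uint8_t ext = tbF[at];
      ++gapcols; --j;
      state = ext ? 2 : 0;
    }
  }
  int start1 = i, start2 = j;
  long colsn = matches + mm + gapcols;
  return List::create(
    _["score"] = best, _["matches"] = (double) matches,
    _["mismatches"] = (double) mm, _["gap_cols"] = (double) gapcols,
    _["columns"] = (double) colsn,
    _["identity_pct"] = colsn ? 100.0 * (double) matches / (double) colsn : 0.0,
    _["start1"] = start1, _["end1"] = bi,
    _["start2"] = start2, _["end2"] = bj);
}
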