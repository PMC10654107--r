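// Alignment kernels: local PSSM-vs-sequence search (affine gaps) and global
// profile-vs-profile Needleman-Wunsch used by the progressive aligner.

#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Best local alignment score of a position-specific scoring model against a
// residue-index sequence (1-based indices into the score columns; 0 scores
// zero). Rolling rows, no traceback.
// [[Rcpp::export(name = ".pssm_score")]]
double pssm_score(const NumericMatrix& S, const IntegerVector& seq,
                  double gap_open, double gap_ext) {
  const int nc = S.nrow();      // profile columns
  const int ns = seq.size();    // sequence length
  const int q = S.ncol();
  const double NEG = -1e30;
  // row-major copy of S for contiguous access per profile column
  std::vector<double> Sm((size_t)nc * q);
  for (int i = 0; i < nc; ++i)
    for (int a = 0; a < q; ++a) Sm[(size_t)i * q + a] = S(i, a);
  std::vector<int> sq(ns);
  for (int j = 0; j < ns; ++j) sq[j] = seq[j];
  std::vector<double> Mp(ns + 1, 0.0), Mc(ns + 1, 0.0);
  std::vector<double> Iqp(ns + 1, NEG), Iqc(ns + 1, NEG);
  std::vector<double> Isp(ns + 1, NEG), Isc(ns + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= nc; ++i) {
    const double* srow = &Sm[(size_t)(i - 1) * q];
    Mc[0] = 0.0; Iqc[0] = NEG; Isc[0] = NEG;
    for (int j = 1; j <= ns; ++j) {
      const int a = sq[j - 1];
      const double sub = (a >= 1 && a <= q) ? srow[a - 1] : 0.0;
      double diag = Mp[j - 1];
      if (Iqp[j - 1] > diag) diag = Iqp[j - 1];
      if (Isp[j - 1] > diag) diag = Isp[j - 1];
      double m = diag + sub;
      if (m < 0.0) m = 0.0;
      Mc[j] = m;
      double iq = Mp[j] - gap_open;
      if (Iqp[j] - gap_ext > iq) iq = Iqp[j] - gap_ext;
      Iqc[j] = iq;
      double is = Mc[j - 1] - gap_open;
      if (Isc[j - 1] - gap_ext > is) is = Isc[j - 1] - gap_ext;
      Isc[j] = is;
      if (m > best) best = m;
    }
    std::swap(Mp, Mc); std::swap(Iqp, Iqc); std::swap(Isp, Isc);
  }
  return best;
}

// Full local alignment with traceback (byte matrices, rolling score rows).
// Returns the best score, the aligned profile-column and sequence ranges
// (1-based, inclusive) and, for guided insertion into the profile's
// alignment, the sequence position aligned to each profile column
// (0 = deletion / outside the local alignment).
// [[Rcpp::export(name = ".pssm_align")]]
List pssm_align(const NumericMatrix& S, const IntegerVector& seq,
                double gap_open, double gap_ext) {
  const int nc = S.nrow(), ns = seq.size(), q = S.ncol();
  const double NEG = -1e30;
  std::vector<double> Sm((size_t)nc * q);
  for (int i = 0; i < nc; ++i)
    for (int a = 0; a < q; ++a) Sm[(size_t)i * q + a] = S(i, a);
  const size_t W = ns + 1;
  std::vector<unsigned char> tbM((size_t)(nc + 1) * W, 0),
      tbIq((size_t)(nc + 1) * W, 0), tbIs((size_t)(nc + 1) * W, 0);
  std::vector<double> Mp(W, 0.0), Mc(W, 0.0);
  std::vector<double> Iqp(W, NEG), Iqc(W, NEG);
  std::vector<double> Isp(W, NEG), Isc(W, NEG);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= nc; ++i) {
    const double* srow = &Sm[(size_t)(i - 1) * q];
    unsigned char* rM = &tbM[(size_t)i * W];
    unsigned char* rIq = &tbIq[(size_t)i * W];
    unsigned char* rIs = &tbIs[(size_t)i * W];
    Mc[0] = 0.0; Iqc[0] = NEG; Isc[0] = NEG;
    for (int j = 1; j <= ns; ++j) {
      const int a = seq[j - 1];
      const double sub = (a >= 1 && a <= q) ? srow[a - 1] : 0.0;
      double diag = Mp[j - 1]; unsigned char src = 1;
      if (Iqp[j - 1] > diag) { diag = Iqp[j - 1]; src = 2; }
      if (Isp[j - 1] > diag) { diag = Isp[j - 1]; src = 3; }
      double m = diag + sub;
      if (m < 0.0) { m = 0.0; src = 0; }
      Mc[j] = m; rM[j] = src;
      if (Mp[j] - gap_open >= Iqp[j] - gap_ext) {
        Iqc[j] = Mp[j] - gap_open; rIq[j] = 1;
      } else {
        Iqc[j] = Iqp[j] - gap_ext; rIq[j] = 2;
      }
      if (Mc[j - 1] - gap_open >= Isc[j - 1] - gap_ext) {
        Isc[j] = Mc[j - 1] - gap_open; rIs[j] = 1;
      } else {
        Isc[j] = Isc[j - 1] - gap_ext; rIs[j] = 3;
      }
      if (m > best) { best = m; bi = i; bj = j; }
    }
    std::swap(Mp, Mc); std::swap(Iqp, Iqc); std::swap(Isp, Isc);
  }
  IntegerVector colmap(nc, 0);
  int i = bi, j = bj, state = 1;
  int pend = bi, send = bj, pstart = bi, sstart = bj;
  while (i > 0 && j > 0) {
    if (state == 1) {
      unsigned char src = tbM[(size_t)i * W + j];
      colmap[i - 1] = j;
      pstart = i; sstart = j;
      --i; --j;
      if (src == 0) break;
      state = src;
    } else if (state == 2) {   // gap in sequence: profile column deleted
      state = tbIq[(size_t)i * W + j];
      --i;
    } else {                   // insertion in sequence: discarded
      state = tbIs[(size_t)i * W + j];
      --j;
    }
  }
  return List::create(_["score"] = best, _["pstart"] = pstart,
                      _["pend"] = pend, _["sstart"] = sstart,
                      _["send"] = send, _["colmap"] = colmap);
}

// Global affine Needleman-Wunsch over a precomputed column-pair score
// matrix S (la x lb; S[i,j] = match score of profile columns i and j,
// typically A %*% M %*% t(B) computed with BLAS upstream). End gaps are
// penalized. Returns the aligned column paths (0 = gap) and the score.
// [[Rcpp::export(name = ".nw_profile")]]
List nw_profile(const NumericMatrix& S, double gap_open, double gap_ext) {
  const int la = S.nrow(), lb = S.ncol();
  const double NEG = -1e30;
  const size_t W = lb + 1;
  std::vector<unsigned char> tbM((size_t)(la + 1) * W, 0),
      tbX((size_t)(la + 1) * W, 0), tbY((size_t)(la + 1) * W, 0);
  std::vector<double> Mp(W, NEG), Mc(W, NEG);
  std::vector<double> Xp(W, NEG), Xc(W, NEG);
  std::vector<double> Yp(W, NEG), Yc(W, NEG);
  Mp[0] = 0.0;
  for (int j = 1; j <= lb; ++j) {
    Yp[j] = -gap_open - gap_ext * (j - 1);
    tbY[j] = (j == 1) ? 1 : 3;
  }
  // column-major access into S is fine row-by-row with a flat copy
  std::vector<double> Sf((size_t)la * lb);
  for (int i = 0; i < la; ++i)
    for (int j = 0; j < lb; ++j) Sf[(size_t)i * lb + j] = S(i, j);
  for (int i = 1; i <= la; ++i) {
    const double* srow = &Sf[(size_t)(i - 1) * lb];
    unsigned char* rM = &tbM[(size_t)i * W];
    unsigned char* rX = &tbX[(size_t)i * W];
    unsigned char* rY = &tbY[(size_t)i * W];
    Mc[0] = NEG; Yc[0] = NEG;
    Xc[0] = -gap_open - gap_ext * (i - 1);
    rX[0] = (i == 1) ? 1 : 2;
    for (int j = 1; j <= lb; ++j) {
      double d = Mp[j - 1]; unsigned char src = 1;
      if (Xp[j - 1] > d) { d = Xp[j - 1]; src = 2; }
      if (Yp[j - 1] > d) { d = Yp[j - 1]; src = 3; }
      Mc[j] = d + srow[j - 1]; rM[j] = src;
      if (Mp[j] - gap_open >= Xp[j] - gap_ext) {
        Xc[j] = Mp[j] - gap_open; rX[j] = 1;
      } else {
        Xc[j] = Xp[j] - gap_ext; rX[j] = 2;
      }
      if (Mc[j - 1] - gap_open >= Yc[j - 1] - gap_ext) {
        Yc[j] = Mc[j - 1] - gap_open; rY[j] = 1;
      } else {
        Yc[j] = Yc[j - 1] - gap_ext; rY[j] = 3;
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  double bestv = Mp[lb]; int state = 1;
  if (Xp[lb] > bestv) { bestv = Xp[lb]; state = 2; }
  if (Yp[lb] > bestv) { bestv = Yp[lb]; state = 3; }
  std::vector<int> pa, pb;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    if (state == 1) {
      unsigned char src = tbM[(size_t)i * W + j];
      pa.push_back(i); pb.push_back(j);
      --i; --j; state = src;
    } else if (state == 2) {
      unsigned char src = tbX[(size_t)i * W + j];
      pa.push_back(i); pb.push_back(0);
      --i; state = src;
    } else {
      unsigned char src = tbY[(size_t)i * W + j];
      pa.push_back(0); pb.push_back(j);
      --j; state = src;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = bestv,
                      _["path_a"] = IntegerVector(pa.begin(), pa.end()),
                      _["path_b"] = IntegerVector(pb.begin(), pb.end()));
}
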