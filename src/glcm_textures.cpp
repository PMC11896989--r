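#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Sliding-window GLCM texture images.
//
// For every pixel, gray-level pairs are accumulated over the four distance-1
// offsets (0, 45, 90, 135 degrees) restricted to the window x window
// neighborhood; with symmetric accumulation the transposed pair is added too.
// Pairs touching off-image or NA (masked) pixels are skipped. The eight
// Haralick statistics are evaluated from the normalized per-window
// distribution; a pixel with zero accumulable pairs is NaN in every feature.
// ENT uses log base 2; COR is defined as 1 when a marginal variance is zero.
// [[Rcpp::export]]
List glcm_texture_images_cpp(IntegerMatrix gray, int G, int window,
                             bool symmetric) {
  const int nr = gray.nrow(), nc = gray.ncol();
  const int h = window / 2;
  const int dr[4] = {0, -1, -1, -1};
  const int dc[4] = {1, 1, 0, -1};
  const double nan = R_NaN;

  NumericMatrix MEA(nr, nc), VAR(nr, nc), HOM(nr, nc), CON(nr, nc),
      DIS(nr, nc), ENT(nr, nc), SEC(nr, nc), COR(nr, nc);
  std::vector<double> P((size_t)G * G, 0.0);
  std::vector<int> touched;
  touched.reserve(128);
  const double log2inv = 1.0 / std::log(2.0);

  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (gray(r0, c0) == NA_INTEGER) {
        MEA(r0, c0) = VAR(r0, c0) = HOM(r0, c0) = CON(r0, c0) = nan;
        DIS(r0, c0) = ENT(r0, c0) = SEC(r0, c0) = COR(r0, c0) = nan;
        continue;
      }
      touched.clear();
      double total = 0.0;
      const int rlo = r0 - h, rhi = r0 + h, clo = c0 - h, chi = c0 + h;
      for (int o = 0; o < 4; ++o) {
        for (int c = std::max(clo, 0); c <= std::min(chi, nc - 1); ++c) {
          for (int r = std::max(rlo, 0); r <= std::min(rhi, nr - 1); ++r) {
            const int r2 = r + dr[o], c2 = c + dc[o];
            if (r2 < rlo || r2 > rhi || c2 < clo || c2 > chi) continue;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            const int a = gray(r, c), b = gray(r2, c2);
            if (a == NA_INTEGER || b == NA_INTEGER) continue;
            int cell = a * G + b;
            if (P[cell] == 0.0) touched.push_back(cell);
            P[cell] += 1.0;
            total += 1.0;
            if (symmetric) {
              cell = b * G + a;
              if (P[cell] == 0.0) touched.push_back(cell);
              P[cell] += 1.0;
              total += 1.0;
            }
          }
        }
      }
      if (total == 0.0) {
        MEA(r0, c0) = VAR(r0, c0) = HOM(r0, c0) = CON(r0, c0) = nan;
        DIS(r0, c0) = ENT(r0, c0) = SEC(r0, c0) = COR(r0, c0) = nan;
        continue;
      }
      double mea = 0, e_i2 = 0, uj = 0, e_j2 = 0, e_ij = 0;
      double hom = 0, con = 0, dis = 0, ent = 0, sec = 0;
      for (size_t t = 0; t < touched.size(); ++t) {
        const int cell = touched[t];
        const double p = P[cell] / total;
        const int i = cell / G, j = cell % G;
        const double d = i - j;
        mea += i * p;
        e_i2 += (double)i * i * p;
        uj += j * p;
        e_j2 += (double)j * j * p;
        e_ij += (double)i * j * p;
        hom += p / (1.0 + d * d);
        con += d * d * p;
        dis += std::fabs(d) * p;
        ent -= p * std::log(p) * log2inv;
        sec += p * p;
        P[cell] = 0.0;
      }
      const double vi = e_i2 - mea * mea, vj = e_j2 - uj * uj;
      const double cov = e_ij - mea * uj;
      MEA(r0, c0) = mea;
      VAR(r0, c0) = vi;
      HOM(r0, c0) = hom;
      CON(r0, c0) = con;
      DIS(r0, c0) = dis;
      ENT(r0, c0) = ent;
      SEC(r0, c0) = sec;
      COR(r0, c0) = (vi <= 0.0 || vj <= 0.0) ? 1.0 : cov / std::sqrt(vi * vj);
    }
  }
  return List::create(MEA, VAR, HOM, CON, DIS, ENT, SEC, COR);
}
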