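// Nearest-neighbour Euclidean distances between positive pixels of a binary
// mask (self excluded), via an expanding Chebyshev-ring search on the pixel
// grid. Exact: the search stops only once no farther ring can beat the best
// candidate.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector nn_distances_cpp(LogicalMatrix mask) {
  const int ny = mask.nrow(), nx = mask.ncol();
  std::vector<int> pr, pc;
  for (int c = 0; c < nx; ++c)
    for (int r = 0; r < ny; ++r)
      if (mask(r, c)) { pr.push_back(r); pc.push_back(c); }
  const int n = (int)pr.size();
  if (n < 2) stop("need at least 2 positive pixels");

  const int Rmax = std::max(ny, nx);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const int r0 = pr[i], c0 = pc[i];
    long best_sq = -1;
    for (int R = 1; R <= Rmax; ++R) {
      int rlo = r0 - R, rhi = r0 + R, clo = c0 - R, chi = c0 + R;
      // top and bottom rows of the ring
      for (int rr = rlo; rr <= rhi; rr += (rhi - rlo > 0 ? rhi - rlo : 1)) {
        if (rr < 0 || rr >= ny) { if (rhi == rlo) break; continue; }
        int ca = std::max(clo, 0), cb = std::min(chi, nx - 1);
        for (int cc = ca; cc <= cb; ++cc)
          if (mask(rr, cc)) {
            long dsq = (long)(rr - r0) * (rr - r0) + (long)(cc - c0) * (cc - c0);
            if (best_sq < 0 || dsq < best_sq) best_sq = dsq;
          }
        if (rhi == rlo) break;
      }
      // left and right columns (excluding corners already scanned)
      for (int cc = clo; cc <= chi; cc += (chi - clo > 0 ? chi - clo : 1)) {
        if (cc < 0 || cc >= nx) { if (chi == clo) break; continue; }
        int ra = std::max(rlo + 1, 0), rb = std::min(rhi - 1, ny - 1);
        for (int rr = ra; rr <= rb; ++rr)
          if (mask(rr, cc)) {
            long dsq = (long)(rr - r0) * (rr - r0) + (long)(cc - c0) * (cc - c0);
            if (best_sq < 0 || dsq < best_sq) best_sq = dsq;
          }
        if (chi == clo) break;
      }
      if (best_sq >= 0 && best_sq <= (long)R * R) break;
    }
    out[i] = std::sqrt((double)best_sq);
  }
  return out;
}
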