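#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Edge-preserving RNL ranked filter.
//
// For every pixel, neighbours within `radius` (circular window, centre
// included) are ranked by their combined perceptual distance
// sqrt(dS^2 + dL^2) to the centre pixel, computed in log-catch space with
// the supplied chromatic Weber fractions (first three channels) and the
// luminance Weber fraction (fourth channel). The centre is replaced by the
// weighted mean of the neighbours' catches with weight (1 - rank/N)^falloff
// (rank 0 = closest, i.e. the centre itself on ties). The pass is applied
// `repetition` times. Ties are broken by window order, so the result is
// deterministic.
//
// catch_: H x W x 4 array (R dim order), wc: length-3 chromatic Weber
// fractions, wl: luminance Weber fraction.
// [[Rcpp::export(name = ".ranked_filter_cpp")]]
NumericVector ranked_filter_cpp(NumericVector catch_, NumericVector wc,
                                double wl, int falloff, int radius,
                                int repetition) {
  IntegerVector dims = catch_.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2];
  if (C != 4) stop("ranked filter expects 4 channels (sw, mw, lw, dbl)");

  const double den = wc[0] * wc[0] * wc[1] * wc[1] +
                     wc[0] * wc[0] * wc[2] * wc[2] +
                     wc[1] * wc[1] * wc[2] * wc[2];

  // window offsets within circular radius
  std::vector<int> offr, offc;
  for (int dr = -radius; dr <= radius; ++dr)
    for (int dc = -radius; dc <= radius; ++dc)
      if (dr * dr + dc * dc <= radius * radius) {
        offr.push_back(dr);
        offc.push_back(dc);
      }
  const int K = (int)offr.size();

  std::vector<double> cur(catch_.begin(), catch_.end());
  std::vector<double> nxt(cur.size());
  std::vector<double> logc(cur.size());

  std::vector<double> dist(K), wsum_q(4);
  std::vector<int> ord(K);

  for (int rep = 0; rep < repetition; ++rep) {
    for (size_t i = 0; i < cur.size(); ++i) logc[i] = std::log(cur[i]);
    const size_t plane = (size_t)H * W;
    for (int r = 0; r < H; ++r) {
      for (int c = 0; c < W; ++c) {
        const size_t p0 = (size_t)c * H + r;
        const double f0 = logc[p0], f1 = logc[p0 + plane],
                     f2 = logc[p0 + 2 * plane], f3 = logc[p0 + 3 * plane];
        int n = 0;
        static thread_local std::vector<size_t> pix;
        pix.resize(K);
        for (int k = 0; k < K; ++k) {
          int rr = r + offr[k], cc = c + offc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          const size_t p = (size_t)cc * H + rr;
          const double d0 = logc[p] - f0, d1 = logc[p + plane] - f1,
                       d2 = logc[p + 2 * plane] - f2,
                       d3 = logc[p + 3 * plane] - f3;
          const double num = wc[0] * wc[0] * (d1 - d2) * (d1 - d2) +
                             wc[1] * wc[1] * (d0 - d2) * (d0 - d2) +
                             wc[2] * wc[2] * (d0 - d1) * (d0 - d1);
          const double dS2 = num / den;
          const double dL = d3 / wl;
          dist[n] = dS2 + dL * dL;
          pix[n] = p;
          ++n;
        }
        for (int k = 0; k < n; ++k) ord[k] = k;
        std::stable_sort(ord.begin(), ord.begin() + n,
                         [&](int a, int b) { return dist[a] < dist[b]; });
        double wsum = 0.0;
        wsum_q[0] = wsum_q[1] = wsum_q[2] = wsum_q[3] = 0.0;
        for (int k = 0; k < n; ++k) {
          const double wgt = std::pow(1.0 - (double)k / n, falloff);
          const size_t p = pix[ord[k]];
          wsum += wgt;
          for (int ch = 0; ch < 4; ++ch) wsum_q[ch] += wgt * cur[p + ch * plane];
        }
        for (int ch = 0; ch < 4; ++ch)
          nxt[p0 + ch * plane] = wsum_q[ch] / wsum;
      }
    }
    std::swap(cur, nxt);
  }

  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dims;
  return out;
}
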