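#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Supersampled scanline rasterizer: fraction of each pixel of an
// nrow x ncol patch covered by a closed polygon. Polygon vertices are given
// in continuous patch coordinates where pixel (i, j) (0-based row, col)
// spans [j, j+1) x [i, i+1). Even-odd fill; exact interval overlap along x,
// `ss` subsamples along y (4 is ample for the measurement chain downstream).
// [[Rcpp::export]]
NumericMatrix cpp_polygon_coverage(NumericVector px, NumericVector py,
                                   int nrow, int ncol, int ss = 4) {
    int n = px.size();
    NumericMatrix cov(nrow, ncol);
    if (n < 3) return cov;
    double wsub = 1.0 / ss;
    std::vector<double> xs;
    xs.reserve(8);
    for (int i = 0; i < nrow; ++i) {
        for (int si = 0; si < ss; ++si) {
            double y = i + (si + 0.5) * wsub;
            xs.clear();
            for (int k = 0; k < n; ++k) {
                int k2 = (k + 1 == n) ? 0 : k + 1;
                double y1 = py[k], y2 = py[k2];
                if ((y1 <= y) != (y2 <= y)) {
                    double t = (y - y1) / (y2 - y1);
                    xs.push_back(px[k] + t * (px[k2] - px[k]));
                }
            }
            if (xs.empty()) continue;
            std::sort(xs.begin(), xs.end());
            for (size_t m = 0; m + 1 < xs.size(); m += 2) {
                double xa = std::max(0.0, xs[m]);
                double xb = std::min((double)ncol, xs[m + 1]);
                if (xb <= xa) continue;
                int ja = (int)xa;
                int jb = std::min(ncol - 1, (int)xb);
                for (int j = ja; j <= jb; ++j) {
                    double lo = std::max(xa, (double)j);
                    double hi = std::min(xb, (double)(j + 1));
                    if (hi > lo) cov(i, j) += (hi - lo) * wsub;
                }
            }
        }
    }
    return cov;
}
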