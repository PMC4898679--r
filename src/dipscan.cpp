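// Flank deviation scans for the dip statistic: greatest-convex-minorant /
// least-concave-majorant hull sweeps over prefixes/suffixes of the distinct
// sorted sample values, returning the largest step-function deviation.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".gcmMaxDevCpp")]]
double gcmMaxDevCpp(NumericVector u, NumericVector cc, NumericVector pre,
                    int k, bool endPre) {
  std::vector<int> h;
  h.reserve(k);
  for (int i = 0; i < k; ++i) {
    while (h.size() >= 2) {
      int a = h[h.size() - 2], b = h[h.size() - 1];
      if ((pre[b] - pre[a]) * (u[i] - u[a]) -
          (pre[i] - pre[a]) * (u[b] - u[a]) >= 0)
        h.pop_back();
      else
        break;
    }
    h.push_back(i);
  }
  // deviation of post-jump counts above the hull line
  double maxdev = 0.0;
  size_t seg = 0;
  for (int j = 0; j < k; ++j) {
    while (seg + 2 < h.size() && u[h[seg + 1]] <= u[j]) ++seg;
    double x0 = u[h[seg]], x1 = u[h[seg + 1 < h.size() ? seg + 1 : seg]];
    double y0 = pre[h[seg]],
           y1 = pre[h[seg + 1 < h.size() ? seg + 1 : seg]];
    double line;
    if (x1 > x0) {
      double t = (u[j] - x0) / (x1 - x0);
      if (t < 0) t = 0;
      if (t > 1) t = 1;
      line = y0 + t * (y1 - y0);
    } else {
      line = y0;
    }
    double y = (endPre && j == k - 1) ? pre[j] : cc[j];
    if (y - line > maxdev) maxdev = y - line;
  }
  return maxdev;
}

// [[Rcpp::export(name = ".lcmMaxDevCpp")]]
double lcmMaxDevCpp(NumericVector u, NumericVector cc, NumericVector pre,
                    int k, bool endPost) {
  int K = u.size();
  std::vector<int> h;
  h.reserve(K - k + 1);
  for (int i = k - 1; i < K; ++i) {
    while (h.size() >= 2) {
      int a = h[h.size() - 2], b = h[h.size() - 1];
      if ((cc[b] - cc[a]) * (u[i] - u[a]) -
          (cc[i] - cc[a]) * (u[b] - u[a]) <= 0)
        h.pop_back();
      else
        break;
    }
    h.push_back(i);
  }
  double maxdev = 0.0;
  size_t seg = 0;
  for (int j = k - 1; j < K; ++j) {
    while (seg + 2 < h.size() && u[h[seg + 1]] <= u[j]) ++seg;
    double x0 = u[h[seg]], x1 = u[h[seg + 1 < h.size() ? seg + 1 : seg]];
    double y0 = cc[h[seg]], y1 = cc[h[seg + 1 < h.size() ? seg + 1 : seg]];
    double line;
    if (x1 > x0) {
      double t = (u[j] - x0) / (x1 - x0);
      if (t < 0) t = 0;
      if (t > 1) t = 1;
      line = y0 + t * (y1 - y0);
    } else {
      line = y0;
    }
    double y = (endPost && j == k - 1) ? cc[j] : pre[j];
    if (line - y > maxdev) maxdev = line - y;
  }
  return maxdev;
}
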