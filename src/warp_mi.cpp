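#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pixel coordinates are 0-based with x = column (right) and y = row (down).
// A rigid transform maps p' = R(theta) (p - center) + center + (tx, ty).
// Warping uses inverse mapping: out(q) = img(T^{-1}(q)) with bilinear
// sampling; source points falling outside [0, W-1] x [0, H-1] are invalid.

static inline int bin_of(double v, int bins) {
  int b = (int)std::floor(v * bins);
  if (b < 0) b = 0;
  if (b >= bins) b = bins - 1; // value 1.0 lands in the last bin
  return b;
}

// [[Rcpp::export]]
List cpp_warp_rigid(NumericMatrix img, double theta, double tx, double ty,
                    double cx, double cy, int out_h, int out_w) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(out_h, out_w);
  LogicalMatrix valid(out_h, out_w);
  double ct = std::cos(theta), st = std::sin(theta);
  for (int col = 0; col < out_w; ++col) {
    double qx = (double)col;
    for (int row = 0; row < out_h; ++row) {
      double qy = (double)row;
      // inverse map: p = R(-theta) (q - center - t) + center
      double dx = qx - cx - tx, dy = qy - cy - ty;
      double xs =  ct * dx + st * dy + cx;
      double ys = -st * dx + ct * dy + cy;
      if (xs >= 0.0 && xs <= (double)(W - 1) &&
          ys >= 0.0 && ys <= (double)(H - 1)) {
        int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
        if (x0 > W - 2) x0 = W - 2;
        if (y0 > H - 2) y0 = H - 2;
        if (W == 1) x0 = 0;
        if (H == 1) y0 = 0;
        double fx = xs - x0, fy = ys - y0;
        int x1 = (W == 1) ? x0 : x0 + 1;
        int y1 = (H == 1) ? y0 : y0 + 1;
        double v00 = img(y0, x0), v01 = img(y0, x1);
        double v10 = img(y1, x0), v11 = img(y1, x1);
        out(row, col) = (1 - fy) * ((1 - fx) * v00 + fx * v01) +
                        fy       * ((1 - fx) * v10 + fx * v11);
        valid(row, col) = true;
      } else {
        out(row, col) = 0.0;
        valid(row, col) = false;
      }
    }
  }
  return List::create(_["pixels"] = out, _["valid"] = valid);
}

// [[Rcpp::export]]
NumericMatrix cpp_joint_hist(NumericMatrix ref, NumericMatrix mov,
                             LogicalMatrix valid, int bins,
                             Nullable<NumericMatrix> weights) {
  int H = ref.nrow(), W = ref.ncol();
  NumericMatrix joint(bins, bins);
  bool has_w = weights.isNotNull();
  NumericMatrix wmat;
  if (has_w) wmat = weights.get();
  for (int col = 0; col < W; ++col) {
    for (int row = 0; row < H; ++row) {
      if (!valid(row, col)) continue;
      double w = has_w ? wmat(row, col) : 1.0;
      joint(bin_of(ref(row, col), bins), bin_of(mov(row, col), bins)) += w;
    }
  }
  return joint;
}

// Warp + weighted joint histogram + mutual information in one pass.
// Returns MI in bits, or NA if no valid pixel remains.
// [[Rcpp::export]]
double cpp_eval_mi(NumericMatrix ref, NumericMatrix mov,
                   double theta, double tx, double ty,
                   double cx, double cy, int bins,
                   Nullable<NumericMatrix> weights) {
  int H = ref.nrow(), W = ref.ncol();
  int Hm = mov.nrow(), Wm = mov.ncol();
  bool has_w = weights.isNotNull();
  NumericMatrix wmat;
  if (has_w) wmat = weights.get();
  std::vector<double> joint((size_t)bins * bins, 0.0);
  double total = 0.0;
  double ct = std::cos(theta), st = std::sin(theta);
  const double *pref = REAL(ref), *pmov = REAL(mov);
  const double *pw = has_w ? REAL(wmat) : (double*)0;
  const double xmax = (double)(Wm - 1), ymax = (double)(Hm - 1);
  const double dbins = (double)bins;
  for (int col = 0; col < W; ++col) {
    double dx = (double)col - cx - tx;
    double dy0 = -cy - ty;
    // source coords are affine in the row index: step (st, ct) per row
    double xs =  ct * dx + st * dy0 + cx;
    double ys = -st * dx + ct * dy0 + cy;
    const double *ref_col = pref + (size_t)H * col;
    const double *w_col = has_w ? pw + (size_t)H * col : (double*)0;
    for (int row = 0; row < H; ++row, xs += st, ys += ct) {
      if (!(xs >= 0.0 && xs <= xmax && ys >= 0.0 && ys <= ymax)) continue;
      int x0 = (int)xs, y0 = (int)ys;
      if (x0 > Wm - 2) x0 = Wm - 2;
      if (y0 > Hm - 2) y0 = Hm - 2;
      if (Wm == 1) x0 = 0;
      if (Hm == 1) y0 = 0;
      double fx = xs - x0, fy = ys - y0;
      const double *m0 = pmov + (size_t)Hm * x0 + y0;
      const double *m1 = (Wm == 1) ? m0 : m0 + Hm;
      int dr = (Hm == 1) ? 0 : 1;
      double v = (1 - fy) * ((1 - fx) * m0[0] + fx * m1[0]) +
                 fy       * ((1 - fx) * m0[dr] + fx * m1[dr]);
      double w = has_w ? w_col[row] : 1.0;
      int bi = (int)(ref_col[row] * dbins); if (bi >= bins) bi = bins - 1;
      int bj = (int)(v * dbins);            if (bj >= bins) bj = bins - 1;
      joint[(size_t)bi + (size_t)bins * bj] += w;
      total += w;
    }
  }
  if (total <= 0.0) return NA_REAL;
  std::vector<double> pi(bins, 0.0), pj(bins, 0.0);
  for (int j = 0; j < bins; ++j)
    for (int i = 0; i < bins; ++i) {
      double p = joint[(size_t)i + (size_t)bins * j] / total;
      pi[i] += p;
      pj[j] += p;
    }
  double mi = 0.0;
  const double l2 = std::log(2.0);
  for (int j = 0; j < bins; ++j)
    for (int i = 0; i < bins; ++i) {
      double p = joint[(size_t)i + (size_t)bins * j] / total;
      if (p > 0.0) mi += p * std::log(p / (pi[i] * pj[j])) / l2;
    }
  return mi;
}
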