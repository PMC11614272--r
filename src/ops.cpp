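// Hot array primitives for the attention and resampling layers: max+mean
// reduction along one axis of a [C,D,H,W] array (with argmax for the
// backward pass), its adjoint, broadcast expansion/summation along an
// axis, 2x max pooling, and linear 2x upsampling along one axis.
// Axis codes follow R: 2 = D, 3 = H, 4 = W.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

// Strides for iterating [C,D,H,W] with one axis singled out: the array is
// viewed as outer x n_axis x inner after an index transform.
struct AxisView {
  long n;        // length of the reduced/expanded axis
  long stride;   // element stride along that axis
  long n_groups; // number of (c, other, other) positions
  // group -> base offset
  std::vector<long> base;

  AxisView(const IntegerVector& dim4, int axis) {
    const long C = dim4[0], D = dim4[1], H = dim4[2], W = dim4[3];
    long s[4] = {1, C, C * D, C * D * H};
    long len[4] = {C, D, H, W};
    n = len[axis - 1];
    stride = s[axis - 1];
    n_groups = C * D * H * W / n;
    base.resize(n_groups);
    long g = 0;
    // iterate the three kept axes in their memory order
    int kept[3]; int kk = 0;
    for (int a = 0; a < 4; ++a) if (a != axis - 1) kept[kk++] = a;
    for (long i2 = 0; i2 < len[kept[2]]; ++i2)
      for (long i1 = 0; i1 < len[kept[1]]; ++i1)
        for (long i0 = 0; i0 < len[kept[0]]; ++i0)
          base[g++] = i0 * s[kept[0]] + i1 * s[kept[1]] + i2 * s[kept[2]];
  }
};

}  // namespace

// [[Rcpp::export(name = ".axis_maxmean_fwd_cpp")]]
List axis_maxmean_fwd_cpp(NumericVector x, IntegerVector dim4, int axis) {
  AxisView v(dim4, axis);
  NumericVector K(v.n_groups);
  IntegerVector arg(v.n_groups);
  const double* px = x.begin();
  for (long g = 0; g < v.n_groups; ++g) {
    const double* p = px + v.base[g];
    double mx = p[0], sm = p[0];
    long am = 0;
    for (long j = 1; j < v.n; ++j) {
      const double val = p[j * v.stride];
      sm += val;
      if (val > mx) { mx = val; am = j; }
    }
    K[g] = mx + sm / v.n;
    arg[g] = (int)(am + 1);  // 1-based for R
  }
  return List::create(_["K"] = K, _["arg"] = arg);
}

// [[Rcpp::export(name = ".axis_maxmean_bwd_cpp")]]
NumericVector axis_maxmean_bwd_cpp(NumericVector dK, IntegerVector arg,
                                   IntegerVector dim4, int axis) {
  AxisView v(dim4, axis);
  NumericVector dx((long)dim4[0] * dim4[1] * dim4[2] * dim4[3]);
  dx.attr("dim") = dim4;
  double* pdx = dx.begin();
  for (long g = 0; g < v.n_groups; ++g) {
    double* p = pdx + v.base[g];
    const double mean_part = dK[g] / v.n;
    for (long j = 0; j < v.n; ++j) p[j * v.stride] += mean_part;
    p[(long)(arg[g] - 1) * v.stride] += dK[g];
  }
  return dx;
}

// [[Rcpp::export(name = ".axis_expand_cpp")]]
NumericVector axis_expand_cpp(NumericVector A, IntegerVector dim4, int axis) {
  AxisView v(dim4, axis);
  NumericVector out((long)dim4[0] * dim4[1] * dim4[2] * dim4[3]);
  out.attr("dim") = dim4;
  double* po = out.begin();
  for (long g = 0; g < v.n_groups; ++g) {
    double* p = po + v.base[g];
    const double val = A[g];
    for (long j = 0; j < v.n; ++j) p[j * v.stride] = val;
  }
  return out;
}

// [[Rcpp::export(name = ".axis_collapse_cpp")]]
NumericVector axis_collapse_cpp(NumericVector x, IntegerVector dim4,
                                int axis) {
  AxisView v(dim4, axis);
  NumericVector out(v.n_groups);
  const double* px = x.begin();
  for (long g = 0; g < v.n_groups; ++g) {
    const double* p = px + v.base[g];
    double sm = 0;
    for (long j = 0; j < v.n; ++j) sm += p[j * v.stride];
    out[g] = sm;
  }
  return out;
}

// [[Rcpp::export(name = ".maxpool2_fwd_cpp")]]
List maxpool2_fwd_cpp(NumericVector x, IntegerVector dim4) {
  const long C = dim4[0], D = dim4[1], H = dim4[2], W = dim4[3];
  const long Do = D / 2, Ho = H / 2, Wo = W / 2;
  NumericVector y(C * Do * Ho * Wo);
  IntegerVector arg(C * Do * Ho * Wo);
  y.attr("dim") = IntegerVector::create(C, Do, Ho, Wo);
  const double* px = x.begin();
  const long sD = C, sH = C * D, sW = C * D * H;
  long o = 0;
  for (long ow = 0; ow < Wo; ++ow)
    for (long oh = 0; oh < Ho; ++oh)
      for (long od = 0; od < Do; ++od) {
        const double* b = px + 2 * od * sD + 2 * oh * sH + 2 * ow * sW;
        for (long c = 0; c < C; ++c, ++o) {
          double mx = b[c];
          int am = 0, idx = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh)
              for (int dd = 0; dd < 2; ++dd, ++idx) {
                const double val = b[c + dd * sD + dh * sH + dw * sW];
                if (val > mx) { mx = val; am = idx; }
              }
          y[o] = mx;
          arg[o] = am;
        }
      }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".maxpool2_bwd_cpp")]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector arg,
                               IntegerVector dim4) {
  const long C = dim4[0], D = dim4[1], H = dim4[2], W = dim4[3];
  const long Do = D / 2, Ho = H / 2, Wo = W / 2;
  NumericVector dx(C * D * H * W);
  dx.attr("dim") = dim4;
  double* pdx = dx.begin();
  const long sD = C, sH = C * D, sW = C * D * H;
  long o = 0;
  for (long ow = 0; ow < Wo; ++ow)
    for (long oh = 0; oh < Ho; ++oh)
      for (long od = 0; od < Do; ++od) {
        double* b = pdx + 2 * od * sD + 2 * oh * sH + 2 * ow * sW;
        for (long c = 0; c < C; ++c, ++o) {
          const int idx = arg[o];
          const int dd = idx % 2, dh = (idx / 2) % 2, dw = idx / 4;
          b[c + dd * sD + dh * sH + dw * sW] += dy[o];
        }
      }
  return dx;
}

// Linear x2 upsampling along one axis: even outputs 0.75*x[i] + 0.25*x[i-1],
// odd outputs 0.75*x[i] + 0.25*x[i+1], indices clamped at the ends.
// [[Rcpp::export(name = ".up2_axis_fwd_cpp")]]
NumericVector up2_axis_fwd_cpp(NumericVector x, IntegerVector dim4,
                               int axis) {
  AxisView v(dim4, axis);
  IntegerVector odim = clone(dim4);
  odim[axis - 1] = 2 * dim4[axis - 1];
  AxisView vo(odim, axis);
  NumericVector out((long)odim[0] * odim[1] * odim[2] * odim[3]);
  out.attr("dim") = odim;
  const double* px = x.begin();
  double* po = out.begin();
  for (long g = 0; g < v.n_groups; ++g) {
    const double* p = px + v.base[g];
    double* q = po + vo.base[g];
    for (long i = 0; i < v.n; ++i) {
      const double xm = p[std::max(0L, i - 1) * v.stride];
      const double xc = p[i * v.stride];
      const double xp = p[std::min(v.n - 1, i + 1) * v.stride];
      q[(2 * i) * vo.stride] = 0.75 * xc + 0.25 * xm;
      q[(2 * i + 1) * vo.stride] = 0.75 * xc + 0.25 * xp;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".up2_axis_bwd_cpp")]]
NumericVector up2_axis_bwd_cpp(NumericVector dy, IntegerVector odim,
                               int axis) {
  IntegerVector dim4 = clone(odim);
  dim4[axis - 1] = odim[axis - 1] / 2;
  AxisView v(dim4, axis);
  AxisView vo(odim, axis);
  NumericVector dx((long)dim4[0] * dim4[1] * dim4[2] * dim4[3]);
  dx.attr("dim") = dim4;
  const double* pdy = dy.begin();
  double* pdx = dx.begin();
  for (long g = 0; g < v.n_groups; ++g) {
    const double* q = pdy + vo.base[g];
    double* p = pdx + v.base[g];
    for (long i = 0; i < v.n; ++i) {
      const double de = q[(2 * i) * vo.stride];
      const double dodd = q[(2 * i + 1) * vo.stride];
      p[i * v.stride] += 0.75 * (de + dodd);
      p[std::max(0L, i - 1) * v.stride] += 0.25 * de;
      p[std::min(v.n - 1, i + 1) * v.stride] += 0.25 * dodd;
    }
  }
  return dx;
}
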