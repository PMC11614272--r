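// Exact 3D cross-correlation via im2col + BLAS GEMM, with the matching
// backward pass (col2im). Arrays follow R's column-major [C, D, H, W]
// layout; kernels may differ per axis so 2D convolutions are the kd = 1
// special case. 1x1x1 kernels bypass im2col entirely (pure GEMM on the
// channel-by-voxel matrix). Work is chunked over (oh, ow) panels to bound
// the im2col buffer.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct ConvGeom {
  int C, D, H, W;
  int kd, kh, kw;
  int pd, ph, pw;
  int sd, sh, sw;
  int Do, Ho, Wo;
  int rows;     // C * kd * kh * kw
  long ncols;   // Do * Ho * Wo

  ConvGeom(const IntegerVector& xdim, const IntegerVector& k,
           const IntegerVector& pad, const IntegerVector& stride) {
    C = xdim[0]; D = xdim[1]; H = xdim[2]; W = xdim[3];
    kd = k[0]; kh = k[1]; kw = k[2];
    pd = pad[0]; ph = pad[1]; pw = pad[2];
    sd = stride[0]; sh = stride[1]; sw = stride[2];
    Do = (D + 2 * pd - kd) / sd + 1;
    Ho = (H + 2 * ph - kh) / sh + 1;
    Wo = (W + 2 * pw - kw) / sw + 1;
    if (Do < 1 || Ho < 1 || Wo < 1)
      stop("kernel larger than padded input");
    rows = C * kd * kh * kw;
    ncols = (long)Do * Ho * Wo;
  }

  bool is_1x1() const {
    return kd == 1 && kh == 1 && kw == 1 && pd == 0 && ph == 0 && pw == 0 &&
           sd == 1 && sh == 1 && sw == 1;
  }
};

// Fill the im2col block for output panels [p0, p1), where a panel is one
// (oh, ow) pair covering all Do depth positions. M: rows x (p1-p0)*Do.
void im2col_panels(const double* x, const ConvGeom& g, long p0, long p1,
                   arma::mat& M) {
  M.zeros();
  const long strideD = g.C;
  const long strideH = (long)g.C * g.D;
  const long strideW = (long)g.C * g.D * g.H;
  for (long p = p0; p < p1; ++p) {
    const int oh = (int)(p % g.Ho);
    const int ow = (int)(p / g.Ho);
    double* mpanel = M.colptr((p - p0) * g.Do);
    for (int iw = 0; iw < g.kw; ++iw) {
      const int w = ow * g.sw - g.pw + iw;
      if (w < 0 || w >= g.W) continue;
      for (int ih = 0; ih < g.kh; ++ih) {
        const int h = oh * g.sh - g.ph + ih;
        if (h < 0 || h >= g.H) continue;
        const double* xbase = x + h * strideH + w * strideW;
        for (int id = 0; id < g.kd; ++id) {
          const long r0 = (long)g.C * (id + g.kd * (ih + (long)g.kh * iw));
          // valid od: 0 <= od*sd - pd + id < D
          for (int od = 0; od < g.Do; ++od) {
            const int d = od * g.sd - g.pd + id;
            if (d < 0 || d >= g.D) continue;
            std::copy(xbase + d * strideD, xbase + d * strideD + g.C,
                      mpanel + (long)od * M.n_rows + r0);
          }
        }
      }
    }
  }
}

// Adjoint: scatter-add M's entries back into dx.
void col2im_panels(double* dx, const ConvGeom& g, long p0, long p1,
                   const arma::mat& M) {
  const long strideD = g.C;
  const long strideH = (long)g.C * g.D;
  const long strideW = (long)g.C * g.D * g.H;
  for (long p = p0; p < p1; ++p) {
    const int oh = (int)(p % g.Ho);
    const int ow = (int)(p / g.Ho);
    const double* mpanel = M.colptr((p - p0) * g.Do);
    for (int iw = 0; iw < g.kw; ++iw) {
      const int w = ow * g.sw - g.pw + iw;
      if (w < 0 || w >= g.W) continue;
      for (int ih = 0; ih < g.kh; ++ih) {
        const int h = oh * g.sh - g.ph + ih;
        if (h < 0 || h >= g.H) continue;
        double* dbase = dx + h * strideH + w * strideW;
        for (int id = 0; id < g.kd; ++id) {
          const long r0 = (long)g.C * (id + g.kd * (ih + (long)g.kh * iw));
          for (int od = 0; od < g.Do; ++od) {
            const int d = od * g.sd - g.pd + id;
            if (d < 0 || d >= g.D) continue;
            const double* src = mpanel + (long)od * M.n_rows + r0;
            double* dst = dbase + d * strideD;
            for (int c = 0; c < g.C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
}

long panels_per_chunk(const ConvGeom& g) {
  // keep the im2col buffer near 32 MB
  long target = (4L * 1024 * 1024) / std::max(1L, (long)g.rows * g.Do);
  long npanels = (long)g.Ho * g.Wo;
  return std::max(1L, std::min(npanels, target));
}

}  // namespace

// [[Rcpp::export(name = ".conv3d_fwd_cpp")]]
NumericVector conv3d_fwd_cpp(NumericVector x, IntegerVector xdim,
                             NumericMatrix Wm, NumericVector b,
                             IntegerVector k, IntegerVector pad,
                             IntegerVector stride) {
  ConvGeom g(xdim, k, pad, stride);
  const int Cout = Wm.nrow();
  if (Wm.ncol() != g.rows) stop("weight matrix does not match kernel geometry");
  arma::mat Wa(Wm.begin(), Cout, g.rows, false, true);
  arma::vec ba(b.begin(), Cout, false, true);

  NumericVector y((long)Cout * g.ncols);
  arma::mat Ya(y.begin(), Cout, g.ncols, false, true);

  if (g.is_1x1()) {
    arma::mat Xa(x.begin(), g.C, g.ncols, false, true);
    Ya = Wa * Xa;
  } else {
    const long pc = panels_per_chunk(g);
    const long npanels = (long)g.Ho * g.Wo;
    arma::mat M(g.rows, pc * g.Do);
    for (long p0 = 0; p0 < npanels; p0 += pc) {
      const long p1 = std::min(npanels, p0 + pc);
      arma::mat Mv(M.memptr(), g.rows, (p1 - p0) * g.Do, false, true);
      im2col_panels(x.begin(), g, p0, p1, Mv);
      Ya.cols(p0 * g.Do, p1 * g.Do - 1) = Wa * Mv;
    }
  }
  Ya.each_col() += ba;
  y.attr("dim") = IntegerVector::create(Cout, g.Do, g.Ho, g.Wo);
  return y;
}

// [[Rcpp::export(name = ".conv3d_bwd_cpp")]]
List conv3d_bwd_cpp(NumericVector x, IntegerVector xdim, NumericMatrix Wm,
                    NumericVector dy, IntegerVector k, IntegerVector pad,
                    IntegerVector stride) {
  ConvGeom g(xdim, k, pad, stride);
  const int Cout = Wm.nrow();
  if (Wm.ncol() != g.rows) stop("weight matrix does not match kernel geometry");
  if ((long)dy.size() != (long)Cout * g.ncols) stop("dy size mismatch");
  arma::mat Wa(Wm.begin(), Cout, g.rows, false, true);
  arma::mat dYa(dy.begin(), Cout, g.ncols, false, true);

  NumericMatrix dW(Cout, g.rows);
  arma::mat dWa(dW.begin(), Cout, g.rows, false, true);
  NumericVector dx((long)g.C * g.D * g.H * g.W);
  dx.attr("dim") = xdim;

  if (g.is_1x1()) {
    arma::mat Xa(x.begin(), g.C, g.ncols, false, true);
    arma::mat dXa(dx.begin(), g.C, g.ncols, false, true);
    dWa = dYa * Xa.t();
    dXa = Wa.t() * dYa;
  } else {
    const long pc = panels_per_chunk(g);
    const long npanels = (long)g.Ho * g.Wo;
    arma::mat M(g.rows, pc * g.Do);
    for (long p0 = 0; p0 < npanels; p0 += pc) {
      const long p1 = std::min(npanels, p0 + pc);
      arma::mat Mv(M.memptr(), g.rows, (p1 - p0) * g.Do, false, true);
      im2col_panels(x.begin(), g, p0, p1, Mv);
      dWa += dYa.cols(p0 * g.Do, p1 * g.Do - 1) * Mv.t();
      Mv = Wa.t() * dYa.cols(p0 * g.Do, p1 * g.Do - 1);  // reuse as dM
      col2im_panels(dx.begin(), g, p0, p1, Mv);
    }
  }
  arma::vec dba = arma::sum(dYa, 1);
  NumericVector db(dba.begin(), dba.end());
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
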