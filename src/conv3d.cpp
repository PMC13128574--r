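// 3D convolution kernels for (B, C, D, H, W) arrays in R's column-major
// layout (batch index fastest).  The channel-first layout makes direct
// spatial access heavily strided, so both paths first stage the input into
// contiguous per-(channel, depth) planes, then run im2col + BLAS (generic
// path) or a plain stencil (depthwise path) on contiguous memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline long idx5(long b, long c, long d, long h, long w,
                        long B, long C, long D, long H) {
  return b + B * (c + C * (d + D * (h + H * w)));
}

// copy plane (c, d) of x into a contiguous (H*W) buffer
static void load_plane(const double* x, double* buf,
                       long b, long c, long d,
                       long B, long C, long D, long H, long W) {
  for (long w = 0; w < W; ++w) {
    const double* src = x + idx5(b, c, d, 0, w, B, C, D, H);
    double* dst = buf + H * w;
    for (long h = 0; h < H; ++h) dst[h] = src[B * C * D * h];
  }
}

static void store_plane_add(double* x, const double* buf,
                            long b, long c, long d,
                            long B, long C, long D, long H, long W) {
  for (long w = 0; w < W; ++w) {
    double* dst = x + idx5(b, c, d, 0, w, B, C, D, H);
    const double* src = buf + H * w;
    for (long h = 0; h < H; ++h) dst[B * C * D * h] += src[h];
  }
}

// weight layout: (Cout, Cin_g, kd, kh, kw) column-major (Cout fastest);
// returns (Coutg x K) with K ordered as (ci fastest, then kd, kh, kw)
static arma::mat weight_mat(const double* wp, long g,
                            long Cout, long Coutg, long Cg,
                            long kd, long kh, long kw) {
  long K = Cg * kd * kh * kw;
  arma::mat Wm(Coutg, K);
  for (long kwi = 0; kwi < kw; ++kwi)
    for (long khi = 0; khi < kh; ++khi)
      for (long kdi = 0; kdi < kd; ++kdi)
        for (long ci = 0; ci < Cg; ++ci) {
          long k = ci + Cg * (kdi + kd * (khi + kh * kwi));
          for (long co = 0; co < Coutg; ++co)
            Wm(co, k) = wp[(g * Coutg + co) +
                           Cout * (ci + Cg * (kdi + kd * (khi + kh * kwi)))];
        }
  return Wm;
}

// col matrix (npos x K), filled tap-by-tap from the contiguous plane stage
static void fill_col(const double* planes, arma::mat& col, long od,
                     long D, long H, long W,
                     long Cg, long kd, long kh, long kw,
                     long sd, long sh, long sw,
                     long pd, long ph, long pw,
                     long Ho, long Wo) {
  long HW = H * W;
  col.zeros();
  long k = 0;
  for (long kwi = 0; kwi < kw; ++kwi)
    for (long khi = 0; khi < kh; ++khi)
      for (long kdi = 0; kdi < kd; ++kdi) {
        long id = od * sd + kdi - pd;
        for (long ci = 0; ci < Cg; ++ci) {
          if (id >= 0 && id < D) {
            const double* pl = planes + HW * (id + D * ci);
            double* ck = col.colptr(k + ci);
            for (long ow = 0; ow < Wo; ++ow) {
              long iw = ow * sw + kwi - pw;
              if (iw < 0 || iw >= W) continue;
              const double* src = pl + H * iw;
              double* dst = ck + Ho * ow;
              if (sh == 1) {
                long oh0 = std::max(0L, ph - khi);
                long oh1 = std::min(Ho, H + ph - khi);
                for (long oh = oh0; oh < oh1; ++oh) dst[oh] = src[oh + khi - ph];
              } else {
                for (long oh = 0; oh < Ho; ++oh) {
                  long ih = oh * sh + khi - ph;
                  if (ih >= 0 && ih < H) dst[oh] = src[ih];
                }
              }
            }
          }
        }
        k += Cg;
      }
}

// [[Rcpp::export]]
NumericVector conv3d_fw_cpp(NumericVector x, NumericVector w, NumericVector bias,
                            IntegerVector stride, IntegerVector pad, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  long B = xd[0], C = xd[1], D = xd[2], H = xd[3], Wi = xd[4];
  long Cout = wd[0], Cg = wd[1], kd = wd[2], kh = wd[3], kw = wd[4];
  long sd = stride[0], sh = stride[1], sw = stride[2];
  long pd = pad[0], ph = pad[1], pw = pad[2];
  long G = groups, Coutg = Cout / G;
  if (Cg * G != C) stop("conv3d: channel/group mismatch");
  long Do = (D + 2 * pd - kd) / sd + 1;
  long Ho = (H + 2 * ph - kh) / sh + 1;
  long Wo = (Wi + 2 * pw - kw) / sw + 1;
  NumericVector y(B * Cout * Do * Ho * Wo);
  y.attr("dim") = IntegerVector::create(B, Cout, Do, Ho, Wo);
  long HW = H * Wi, npos = Ho * Wo;
  std::vector<double> planes((size_t)(HW * D * Cg));
  const double* xp = x.begin();
  double* yp = y.begin();
  if (Cg == 1 && Coutg == 1) {
    // depthwise stencil on contiguous planes
    std::vector<double> outp((size_t)npos);
    for (long b = 0; b < B; ++b)
      for (long c = 0; c < C; ++c) {
        for (long d = 0; d < D; ++d)
          load_plane(xp, planes.data() + HW * d, b, c, d, B, C, D, H, Wi);
        for (long od = 0; od < Do; ++od) {
          std::fill(outp.begin(), outp.end(), bias[c]);
          for (long kwi = 0; kwi < kw; ++kwi)
            for (long khi = 0; khi < kh; ++khi)
              for (long kdi = 0; kdi < kd; ++kdi) {
                long id = od * sd + kdi - pd;
                if (id < 0 || id >= D) continue;
                double wv = w[c + C * (kdi + kd * (khi + kh * kwi))];
                const double* pl = planes.data() + HW * id;
                for (long ow = 0; ow < Wo; ++ow) {
                  long iw = ow * sw + kwi - pw;
                  if (iw < 0 || iw >= Wi) continue;
                  const double* src = pl + H * iw;
                  double* dst = outp.data() + Ho * ow;
                  for (long oh = 0; oh < Ho; ++oh) {
                    long ih = oh * sh + khi - ph;
                    if (ih >= 0 && ih < H) dst[oh] += wv * src[ih];
                  }
                }
              }
          for (long ow = 0; ow < Wo; ++ow) {
            double* dst = yp + idx5(b, c, od, 0, ow, B, Cout, Do, Ho);
            const double* src = outp.data() + Ho * ow;
            for (long oh = 0; oh < Ho; ++oh) dst[B * Cout * Do * oh] = src[oh];
          }
        }
      }
    return y;
  }
  long K = Cg * kd * kh * kw;
  arma::mat col(npos, K);
  for (long g = 0; g < G; ++g) {
    arma::mat WmT = weight_mat(w.begin(), g, Cout, Coutg, Cg, kd, kh, kw).t();
    for (long b = 0; b < B; ++b) {
      for (long ci = 0; ci < Cg; ++ci)
        for (long d = 0; d < D; ++d)
          load_plane(xp, planes.data() + HW * (d + D * ci),
                     b, g * Cg + ci, d, B, C, D, H, Wi);
      for (long od = 0; od < Do; ++od) {
        fill_col(planes.data(), col, od, D, H, Wi,
                 Cg, kd, kh, kw, sd, sh, sw, pd, ph, pw, Ho, Wo);
        arma::mat out = col * WmT;  // (npos x Coutg)
        for (long co = 0; co < Coutg; ++co) {
          long cidx = g * Coutg + co;
          const double* oc = out.colptr(co);
          double bv = bias[cidx];
          for (long ow = 0; ow < Wo; ++ow) {
            double* dst = yp + idx5(b, cidx, od, 0, ow, B, Cout, Do, Ho);
            const double* src = oc + Ho * ow;
            for (long oh = 0; oh < Ho; ++oh) dst[B * Cout * Do * oh] = src[oh] + bv;
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_bw_cpp(NumericVector x, NumericVector w, NumericVector gy,
                   IntegerVector stride, IntegerVector pad, int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = gy.attr("dim");
  long B = xd[0], C = xd[1], D = xd[2], H = xd[3], Wi = xd[4];
  long Cout = wd[0], Cg = wd[1], kd = wd[2], kh = wd[3], kw = wd[4];
  long sd = stride[0], sh = stride[1], sw = stride[2];
  long pd = pad[0], ph = pad[1], pw = pad[2];
  long G = groups, Coutg = Cout / G;
  long Do = yd[2], Ho = yd[3], Wo = yd[4];
  NumericVector gx(x.size());  gx.attr("dim") = xd;
  NumericVector gw(w.size());  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  long HW = H * Wi, npos = Ho * Wo;
  const double* xp = x.begin();
  const double* gyp = gy.begin();
  double* gxp = gx.begin();
  if (Cg == 1 && Coutg == 1) {
    std::vector<double> xbuf((size_t)(HW * D)), gxbuf((size_t)(HW * D));
    std::vector<double> gybuf((size_t)npos);
    for (long b = 0; b < B; ++b)
      for (long c = 0; c < C; ++c) {
        for (long d = 0; d < D; ++d)
          load_plane(xp, xbuf.data() + HW * d, b, c, d, B, C, D, H, Wi);
        std::fill(gxbuf.begin(), gxbuf.end(), 0.0);
        for (long od = 0; od < Do; ++od) {
          double acc = 0.0;
          for (long ow = 0; ow < Wo; ++ow) {
            const double* src = gyp + idx5(b, c, od, 0, ow, B, Cout, Do, Ho);
            double* dst = gybuf.data() + Ho * ow;
            for (long oh = 0; oh < Ho; ++oh) {
              dst[oh] = src[B * Cout * Do * oh];
              acc += dst[oh];
            }
          }
          gb[c] += acc;
          for (long kwi = 0; kwi < kw; ++kwi)
            for (long khi = 0; khi < kh; ++khi)
              for (long kdi = 0; kdi < kd; ++kdi) {
                long id = od * sd + kdi - pd;
                if (id < 0 || id >= D) continue;
                long widx = c + C * (kdi + kd * (khi + kh * kwi));
                double wv = w[widx];
                double gwacc = 0.0;
                const double* xpl = xbuf.data() + HW * id;
                double* gpl = gxbuf.data() + HW * id;
                for (long ow = 0; ow < Wo; ++ow) {
                  long iw = ow * sw + kwi - pw;
                  if (iw < 0 || iw >= Wi) continue;
                  const double* gyc = gybuf.data() + Ho * ow;
                  const double* xc = xpl + H * iw;
                  double* gc = gpl + H * iw;
                  for (long oh = 0; oh < Ho; ++oh) {
                    long ih = oh * sh + khi - ph;
                    if (ih < 0 || ih >= H) continue;
                    gwacc += gyc[oh] * xc[ih];
                    gc[ih] += gyc[oh] * wv;
                  }
                }
                gw[widx] += gwacc;
              }
        }
        for (long d = 0; d < D; ++d)
          store_plane_add(gxp, gxbuf.data() + HW * d, b, c, d, B, C, D, H, Wi);
      }
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  long K = Cg * kd * kh * kw;
  arma::mat col(npos, K), gyM(npos, Coutg);
  std::vector<double> planes((size_t)(HW * D * Cg)), gplanes((size_t)(HW * D * Cg));
  for (long g = 0; g < G; ++g) {
    arma::mat Wm = weight_mat(w.begin(), g, Cout, Coutg, Cg, kd, kh, kw);
    arma::mat gWm(Coutg, K, arma::fill::zeros);
    for (long b = 0; b < B; ++b) {
      for (long ci = 0; ci < Cg; ++ci)
        for (long d = 0; d < D; ++d)
          load_plane(xp, planes.data() + HW * (d + D * ci),
                     b, g * Cg + ci, d, B, C, D, H, Wi);
      std::fill(gplanes.begin(), gplanes.end(), 0.0);
      for (long od = 0; od < Do; ++od) {
        fill_col(planes.data(), col, od, D, H, Wi,
                 Cg, kd, kh, kw, sd, sh, sw, pd, ph, pw, Ho, Wo);
        for (long co = 0; co < Coutg; ++co) {
          double* gc = gyM.colptr(co);
          double acc = 0.0;
          for (long ow = 0; ow < Wo; ++ow) {
            const double* src = gyp + idx5(b, g * Coutg + co, od, 0, ow,
                                           B, Cout, Do, Ho);
            double* dst = gc + Ho * ow;
            for (long oh = 0; oh < Ho; ++oh) {
              dst[oh] = src[B * Cout * Do * oh];
              acc += dst[oh];
            }
          }
          gb[g * Coutg + co] += acc;
        }
        gWm += (col.t() * gyM).t();     // (Coutg x K)
        arma::mat gcol = gyM * Wm;      // (npos x K)
        long k = 0;
        for (long kwi = 0; kwi < kw; ++kwi)
          for (long khi = 0; khi < kh; ++khi)
            for (long kdi = 0; kdi < kd; ++kdi) {
              long id = od * sd + kdi - pd;
              for (long ci = 0; ci < Cg; ++ci) {
                if (id >= 0 && id < D) {
                  const double* ck = gcol.colptr(k + ci);
                  double* gpl = gplanes.data() + HW * (id + D * ci);
                  for (long ow = 0; ow < Wo; ++ow) {
                    long iw = ow * sw + kwi - pw;
                    if (iw < 0 || iw >= Wi) continue;
                    const double* src = ck + Ho * ow;
                    double* dst = gpl + H * iw;
                    for (long oh = 0; oh < Ho; ++oh) {
                      long ih = oh * sh + khi - ph;
                      if (ih >= 0 && ih < H) dst[ih] += src[oh];
                    }
                  }
                }
              }
              k += Cg;
            }
      }
      for (long ci = 0; ci < Cg; ++ci)
        for (long d = 0; d < D; ++d)
          store_plane_add(gxp, gplanes.data() + HW * (d + D * ci),
                          b, g * Cg + ci, d, B, C, D, H, Wi);
    }
    double* gwp = gw.begin();
    for (long kwi = 0; kwi < kw; ++kwi)
      for (long khi = 0; khi < kh; ++khi)
        for (long kdi = 0; kdi < kd; ++kdi)
          for (long ci = 0; ci < Cg; ++ci) {
            long k = ci + Cg * (kdi + kd * (khi + kh * kwi));
            for (long co = 0; co < Coutg; ++co)
              gwp[(g * Coutg + co) +
                  Cout * (ci + Cg * (kdi + kd * (khi + kh * kwi)))] += gWm(co, k);
          }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
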