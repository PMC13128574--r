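// Channel layer normalization over (B, C, D, H, W) arrays (batch index
// fastest in memory).  Forward saves per-voxel mean and inverse s.d. so the
// backward pass can rebuild the normalized values without storing them.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List ln_fw_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
               double eps) {
  IntegerVector xd = x.attr("dim");
  long B = xd[0], C = xd[1];
  long nsp = (long)xd[2] * xd[3] * xd[4];
  NumericVector y(x.size()); y.attr("dim") = xd;
  NumericVector mu(B * nsp), isd(B * nsp);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (long p = 0; p < nsp; ++p)
    for (long b = 0; b < B; ++b) {
      const double* xv = xp + b + B * C * p;
      double m = 0, m2 = 0;
      for (long c = 0; c < C; ++c) { double v = xv[B * c]; m += v; m2 += v * v; }
      m /= C; m2 = m2 / C - m * m;
      double is = 1.0 / std::sqrt(m2 + eps);
      long j = b + B * p;
      mu[j] = m; isd[j] = is;
      double* yv = yp + b + B * C * p;
      for (long c = 0; c < C; ++c)
        yv[B * c] = (xv[B * c] - m) * is * gamma[c] + beta[c];
    }
  return List::create(_["y"] = y, _["mu"] = mu, _["isd"] = isd);
}

// [[Rcpp::export]]
List ln_bw_cpp(NumericVector x, NumericVector gamma,
               NumericVector mu, NumericVector isd, NumericVector gy) {
  IntegerVector xd = x.attr("dim");
  long B = xd[0], C = xd[1];
  long nsp = (long)xd[2] * xd[3] * xd[4];
  NumericVector gx(x.size()); gx.attr("dim") = xd;
  NumericVector gg(C), gb(C);
  const double *xp = x.begin(), *gp = gy.begin();
  double* gxp = gx.begin();
  std::vector<double> xh(C), dxh(C);
  for (long p = 0; p < nsp; ++p)
    for (long b = 0; b < B; ++b) {
      long j = b + B * p;
      double m = mu[j], is = isd[j];
      const double* xv = xp + b + B * C * p;
      const double* gv = gp + b + B * C * p;
      double m1 = 0, m2 = 0;
      for (long c = 0; c < C; ++c) {
        double h = (xv[B * c] - m) * is;
        double g = gv[B * c];
        xh[c] = h;
        gg[c] += g * h;
        gb[c] += g;
        double d = g * gamma[c];
        dxh[c] = d;
        m1 += d; m2 += d * h;
      }
      m1 /= C; m2 /= C;
      double* gxv = gxp + b + B * C * p;
      for (long c = 0; c < C; ++c)
        gxv[B * c] = (dxh[c] - m1 - xh[c] * m2) * is;
    }
  return List::create(_["gx"] = gx, _["gg"] = gg, _["gb"] = gb);
}

// gather / scatter for the scan permutations (1-based index vectors)
// [[Rcpp::export]]
NumericVector gather_cpp(NumericVector x, IntegerVector idx) {
  NumericVector y(idx.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  const int* ip = idx.begin();
  long n = idx.size();
  for (long i = 0; i < n; ++i) yp[i] = xp[ip[i] - 1];
  return y;
}

// [[Rcpp::export]]
NumericVector scatter_cpp(NumericVector g, IntegerVector idx) {
  NumericVector y(g.size());
  const double* gp = g.begin();
  double* yp = y.begin();
  const int* ip = idx.begin();
  long n = idx.size();
  for (long i = 0; i < n; ++i) yp[ip[i] - 1] = gp[i];
  return y;
}

// x * sigmoid(x), with the derivative factor for the backward pass
// [[Rcpp::export]]
NumericVector silu_fw_cpp(NumericVector x) {
  NumericVector y(x.size());
  long n = x.size();
  const double* xp = x.begin();
  double* yp = y.begin();
  for (long i = 0; i < n; ++i) {
    double s = 1.0 / (1.0 + std::exp(-xp[i]));
    yp[i] = xp[i] * s;
  }
  if (!Rf_isNull(x.attr("dim"))) y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector silu_bw_cpp(NumericVector x, NumericVector g) {
  NumericVector gx(x.size());
  long n = x.size();
  const double* xp = x.begin();
  const double* gp = g.begin();
  double* yp = gx.begin();
  for (long i = 0; i < n; ++i) {
    double s = 1.0 / (1.0 + std::exp(-xp[i]));
    yp[i] = gp[i] * s * (1.0 + xp[i] * (1.0 - s));
  }
  if (!Rf_isNull(x.attr("dim"))) gx.attr("dim") = x.attr("dim");
  return gx;
}

// scan-order index vectors, built in C++ to avoid large temporaries.
// dir codes: 1 row-forward, 2 row-backward, 3 col-forward, 4 col-backward,
//            5 dhw / z-forward, 6 z-backward, 7 whd
// [[Rcpp::export]]
IntegerVector scan_index_cpp(IntegerVector shape, int dir) {
  long B = shape[0], C = shape[1], D = shape[2], H = shape[3], W = shape[4];
  long n = B * C * D * H * W;
  IntegerVector idx(n);
  int* out = idx.begin();
  if (dir <= 4) {
    long L = H * W, S = B * D;
    std::vector<long> spat((size_t)L);
    for (long t = 0; t < L; ++t) {
      long tt = (dir == 2 || dir == 4) ? (L - 1 - t) : t;
      long h, w;
      if (dir <= 2) { h = tt / W; w = tt % W; }
      else          { h = tt % H; w = tt / H; }
      spat[t] = B * C * D * (h + H * w);
    }
    long k = 0;
    for (long s = 0; s < S; ++s) {
      long b = s % B, d = s / B;
      long sp = (b + 1) + B * C * d;
      for (long c = 0; c < C; ++c) {
        long cp = B * c + sp;
        for (long t = 0; t < L; ++t) out[k++] = (int)(spat[t] + cp);
      }
    }
  } else {
    long L = D * H * W, S = B;
    std::vector<long> spat((size_t)L);
    for (long t = 0; t < L; ++t) {
      long tt = (dir == 6) ? (L - 1 - t) : t;
      long d, h, w;
      if (dir == 7) { d = tt % D; h = (tt / D) % H; w = tt / (D * H); }
      else          { d = tt / (H * W); h = (tt / W) % H; w = tt % W; }
      spat[t] = B * C * (d + D * (h + H * w));
    }
    long k = 0;
    for (long s = 0; s < S; ++s)
      for (long c = 0; c < C; ++c) {
        long cp = (s + 1) + B * c;
        for (long t = 0; t < L; ++t) out[k++] = (int)(spat[t] + cp);
      }
  }
  return idx;
}

// [[Rcpp::export]]
IntegerVector invert_permutation_cpp(IntegerVector idx) {
  IntegerVector inv(idx.size());
  long n = idx.size();
  const int* ip = idx.begin();
  int* op = inv.begin();
  for (long i = 0; i < n; ++i) op[ip[i] - 1] = (int)(i + 1);
  return inv;
}

// Scan-order gather/scatter with plane staging.  The generic permutation
// walks the volume with strides up to C*D*H elements; staging each (c,d)
// plane into a contiguous buffer keeps the traversal cache-resident.
// dir codes as in scan_index_cpp; fwd=true gathers volume -> sequence.
static void scan_move(const double* vol, double* seq, const int* shape,
                      int dir, bool fwd) {
  long B = shape[0], C = shape[1], D = shape[2], H = shape[3], W = shape[4];
  long HW = H * W;
  std::vector<double> buf((size_t)HW);
  long k = 0;  // position in the sequence array (t fastest, then c, then s)
  if (dir <= 4) {
    for (long d = 0; d < D; ++d)
      for (long b = 0; b < B; ++b)   // s enumerates (b, d), b fastest
        for (long c = 0; c < C; ++c) {
          double* base = const_cast<double*>(vol) + b + B * (c + C * d);
          long strideH = B * C * D;
          if (fwd)
            for (long w = 0; w < W; ++w) {
              const double* src = base + strideH * H * w;
              double* dst = buf.data() + H * w;
              for (long h = 0; h < H; ++h) dst[h] = src[strideH * h];
            }
          else std::fill(buf.begin(), buf.end(), 0.0);
          // traverse buf in scan order against seq[k..]
          if (dir <= 2) {           // row scans: w fastest
            for (long i = 0; i < HW; ++i) {
              long t = (dir == 2) ? (HW - 1 - i) : i;
              long h = t / W, w = t % W;
              if (fwd) seq[k++] = buf[h + H * w];
              else buf[h + H * w] = seq[k++];
            }
          } else {                  // column scans: h fastest
            for (long i = 0; i < HW; ++i) {
              long t = (dir == 4) ? (HW - 1 - i) : i;
              if (fwd) seq[k++] = buf[t];
              else buf[t] = seq[k++];
            }
          }
          if (!fwd)
            for (long w = 0; w < W; ++w) {
              double* dst = base + strideH * H * w;
              const double* src = buf.data() + H * w;
              for (long h = 0; h < H; ++h) dst[strideH * h] = src[h];
            }
        }
  } else if (dir == 5 || dir == 6) {  // depth-outermost, w fastest
    for (long b = 0; b < B; ++b)
      for (long c = 0; c < C; ++c) {
        // sequence block for (b, c) covers t = 0..D*H*W-1
        long k0 = k;
        for (long d = 0; d < D; ++d) {
          double* base = const_cast<double*>(vol) + b + B * (c + C * d);
          long strideH = B * C * D;
          if (fwd) {
            for (long w = 0; w < W; ++w) {
              const double* src = base + strideH * H * w;
              double* dst = buf.data() + H * w;
              for (long h = 0; h < H; ++h) dst[h] = src[strideH * h];
            }
            for (long h = 0; h < H; ++h)
              for (long w = 0; w < W; ++w) {
                long t = d * HW + h * W + w;
                long tt = (dir == 6) ? (D * HW - 1 - t) : t;
                seq[k0 + tt] = buf[h + H * w];
              }
          } else {
            for (long h = 0; h < H; ++h)
              for (long w = 0; w < W; ++w) {
                long t = d * HW + h * W + w;
                long tt = (dir == 6) ? (D * HW - 1 - t) : t;
                buf[h + H * w] = seq[k0 + tt];
              }
            for (long w = 0; w < W; ++w) {
              double* dst = base + strideH * H * w;
              const double* src = buf.data() + H * w;
              for (long h = 0; h < H; ++h) dst[strideH * h] = src[h];
            }
          }
        }
        k += D * HW;
      }
  } else {                            // whd: d fastest (small stride, direct)
    for (long b = 0; b < B; ++b)
      for (long c = 0; c < C; ++c)
        for (long w = 0; w < W; ++w)
          for (long h = 0; h < H; ++h) {
            const long base = b + B * (c + C * (D * (h + H * w)));
            long strideD = B * C;
            if (fwd)
              for (long d = 0; d < D; ++d)
                seq[k++] = vol[base + strideD * d];
            else
              for (long d = 0; d < D; ++d)
                const_cast<double*>(vol)[base + strideD * d] = seq[k++];
          }
  }
}

// [[Rcpp::export]]
NumericVector scan_gather_cpp(NumericVector x, IntegerVector shape, int dir) {
  NumericVector y(x.size());
  scan_move(x.begin(), y.begin(), shape.begin(), dir, true);
  return y;
}

// [[Rcpp::export]]
NumericVector scan_scatter_cpp(NumericVector seq, IntegerVector shape, int dir) {
  NumericVector y(seq.size());
  scan_move(y.begin(), const_cast<double*>(seq.begin()), shape.begin(), dir, false);
  return y;
}
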