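// Convolution and pooling kernels for the patch-classification networks.
// Activations are stored as R arrays of dim (h, w, c, n), column-major.
// "same" padding follows the asymmetric convention pad_begin = total/2
// (floor), pad_end = total - pad_begin, so a 64-input stride-2 3x3 layer
// pads (0, 1) and yields 32.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, bool same, int &pad_beg) {
  if (same) {
    int out = (in + stride - 1) / stride;
    int total = std::max((out - 1) * stride + k - in, 0);
    pad_beg = total / 2;
    return out;
  }
  pad_beg = 0;
  return (in - k) / stride + 1;
}

// im2col for one sample: returns (ho*wo) x (k*k*cin) matrix, rows ordered
// with output row index fastest (column-major image convention).
static void im2col(const double *x, int h, int w, int cin, int k, int stride,
                   int pad_h, int pad_w, int ho, int wo, arma::mat &col) {
  for (int c = 0; c < cin; ++c) {
    const double *xc = x + (size_t)c * h * w;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int colidx = c * k * k + kj * k + ki;
        double *dst = col.colptr(colidx);
        for (int oj = 0; oj < wo; ++oj) {
          int ij = oj * stride + kj - pad_w;
          bool okj = ij >= 0 && ij < w;
          for (int oi = 0; oi < ho; ++oi) {
            int ii = oi * stride + ki - pad_h;
            double v = 0.0;
            if (okj && ii >= 0 && ii < h) v = xc[(size_t)ij * h + ii];
            dst[(size_t)oj * ho + oi] = v;
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat &col, int h, int w, int cin, int k,
                   int stride, int pad_h, int pad_w, int ho, int wo,
                   double *dx) {
  for (int c = 0; c < cin; ++c) {
    double *xc = dx + (size_t)c * h * w;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int colidx = c * k * k + kj * k + ki;
        const double *src = col.colptr(colidx);
        for (int oj = 0; oj < wo; ++oj) {
          int ij = oj * stride + kj - pad_w;
          if (ij < 0 || ij >= w) continue;
          for (int oi = 0; oi < ho; ++oi) {
            int ii = oi * stride + ki - pad_h;
            if (ii < 0 || ii >= h) continue;
            xc[(size_t)ij * h + ii] += src[(size_t)oj * ho + oi];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward(NumericVector x, NumericVector wt,
                             NumericVector bias, int stride, bool same) {
  IntegerVector xd = x.attr("dim");   // h, w, cin, n
  IntegerVector wd = wt.attr("dim");  // k, k, cin, cout
  int h = xd[0], w = xd[1], cin = xd[2], n = xd[3];
  int k = wd[0], cout = wd[3];
  int pad_h, pad_w;
  int ho = out_size(h, k, stride, same, pad_h);
  int wo = out_size(w, k, stride, same, pad_w);
  arma::mat W(const_cast<double *>(wt.begin()), (size_t)k * k * cin, cout,
              false, true);
  arma::rowvec b(const_cast<double *>(bias.begin()), cout, false, true);
  NumericVector y((size_t)ho * wo * cout * n);
  y.attr("dim") = IntegerVector::create(ho, wo, cout, n);
  arma::mat col((size_t)ho * wo, (size_t)k * k * cin);
  for (int s = 0; s < n; ++s) {
    im2col(x.begin() + (size_t)s * h * w * cin, h, w, cin, k, stride, pad_h,
           pad_w, ho, wo, col);
    arma::mat ys = col * W; // (ho*wo) x cout
    ys.each_row() += b;
    std::copy(ys.begin(), ys.end(), y.begin() + (size_t)s * ho * wo * cout);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_backward(NumericVector x, NumericVector wt, NumericVector dy,
                     int stride, bool same) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = wt.attr("dim");
  int h = xd[0], w = xd[1], cin = xd[2], n = xd[3];
  int k = wd[0], cout = wd[3];
  int pad_h, pad_w;
  int ho = out_size(h, k, stride, same, pad_h);
  int wo = out_size(w, k, stride, same, pad_w);
  arma::mat W(const_cast<double *>(wt.begin()), (size_t)k * k * cin, cout,
              false, true);
  NumericVector dx((size_t)h * w * cin * n);
  dx.attr("dim") = xd;
  arma::mat dW((size_t)k * k * cin, cout, arma::fill::zeros);
  arma::rowvec db(cout, arma::fill::zeros);
  arma::mat col((size_t)ho * wo, (size_t)k * k * cin);
  for (int s = 0; s < n; ++s) {
    arma::mat dys(const_cast<double *>(dy.begin()) + (size_t)s * ho * wo * cout,
                  (size_t)ho * wo, cout, false, true);
    im2col(x.begin() + (size_t)s * h * w * cin, h, w, cin, k, stride, pad_h,
           pad_w, ho, wo, col);
    dW += col.t() * dys;
    db += arma::sum(dys, 0);
    arma::mat dcol = dys * W.t(); // (ho*wo) x (k*k*cin)
    col2im(dcol, h, w, cin, k, stride, pad_h, pad_w, ho, wo,
           dx.begin() + (size_t)s * h * w * cin);
  }
  NumericVector dWout(dW.begin(), dW.end());
  dWout.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List maxpool_forward(NumericVector x, int size, int stride) {
  IntegerVector xd = x.attr("dim");
  int h = xd[0], w = xd[1], c = xd[2], n = xd[3];
  int ho = h / stride, wo = w / stride;
  NumericVector y((size_t)ho * wo * c * n);
  y.attr("dim") = IntegerVector::create(ho, wo, c, n);
  IntegerVector idx((size_t)ho * wo * c * n); // argmax as 0-based flat index
  size_t p = 0;
  for (int s = 0; s < n; ++s) {
    for (int ch = 0; ch < c; ++ch) {
      const double *xc = x.begin() + ((size_t)s * c + ch) * h * w;
      size_t base = ((size_t)s * c + ch) * h * w;
      for (int oj = 0; oj < wo; ++oj) {
        for (int oi = 0; oi < ho; ++oi) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int kj = 0; kj < size; ++kj) {
            int ij = oj * stride + kj;
            if (ij >= w) continue;
            for (int ki = 0; ki < size; ++ki) {
              int ii = oi * stride + ki;
              if (ii >= h) continue;
              double v = xc[(size_t)ij * h + ii];
              if (v > best) { best = v; bidx = (size_t)ij * h + ii; }
            }
          }
          // y is (ho, wo, c, n): index oi + ho*(oj + wo*(ch + c*s))
          size_t yi = (size_t)oi + (size_t)ho * (oj + (size_t)wo * (ch + (size_t)c * s));
          y[yi] = best;
          idx[yi] = (int)(base + bidx);
          ++p;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_backward(NumericVector dy, IntegerVector idx,
                               IntegerVector in_dim) {
  NumericVector dx((size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3]);
  dx.attr("dim") = in_dim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// ---- fused batch-norm / activation helpers (hot path) ----

// per-channel mean and biased variance of a (h,w,c,n) array
// [[Rcpp::export]]
List bn_channel_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int hw = xd[0] * xd[1], c = xd[2], n = xd[3];
  NumericVector mu(c), va(c);
  for (int s = 0; s < n; ++s)
    for (int ch = 0; ch < c; ++ch) {
      const double *p = x.begin() + ((size_t)s * c + ch) * hw;
      double acc = 0;
      for (int i = 0; i < hw; ++i) acc += p[i];
      mu[ch] += acc;
    }
  for (int ch = 0; ch < c; ++ch) mu[ch] /= (double)hw * n;
  for (int s = 0; s < n; ++s)
    for (int ch = 0; ch < c; ++ch) {
      const double *p = x.begin() + ((size_t)s * c + ch) * hw;
      double m = mu[ch], acc = 0;
      for (int i = 0; i < hw; ++i) { double d = p[i] - m; acc += d * d; }
      va[ch] += acc;
    }
  for (int ch = 0; ch < c; ++ch) va[ch] /= (double)hw * n;
  return List::create(_["mean"] = mu, _["var"] = va);
}

// y = x * a[channel] + b[channel] on a (h,w,c,n) array
// [[Rcpp::export]]
NumericVector bn_affine(NumericVector x, NumericVector a, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  int hw = xd[0] * xd[1], c = xd[2], n = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int s = 0; s < n; ++s)
    for (int ch = 0; ch < c; ++ch) {
      const double *p = x.begin() + ((size_t)s * c + ch) * hw;
      double *q = y.begin() + ((size_t)s * c + ch) * hw;
      double aa = a[ch], bb = b[ch];
      for (int i = 0; i < hw; ++i) q[i] = p[i] * aa + bb;
    }
  return y;
}

// per-channel sums of dy and dy*xhat, then fused dx
// [[Rcpp::export]]
List bn_backward_spatial(NumericVector dy, NumericVector xhat,
                         NumericVector gamma_inv) {
  IntegerVector xd = dy.attr("dim");
  int hw = xd[0] * xd[1], c = xd[2], n = xd[3];
  NumericVector dgamma(c), dbeta(c);
  for (int s = 0; s < n; ++s)
    for (int ch = 0; ch < c; ++ch) {
      const double *pd = dy.begin() + ((size_t)s * c + ch) * hw;
      const double *px = xhat.begin() + ((size_t)s * c + ch) * hw;
      double ag = 0, ab = 0;
      for (int i = 0; i < hw; ++i) { ag += pd[i] * px[i]; ab += pd[i]; }
      dgamma[ch] += ag; dbeta[ch] += ab;
    }
  double m = (double)hw * n;
  NumericVector dx(dy.size());
  dx.attr("dim") = xd;
  for (int s = 0; s < n; ++s)
    for (int ch = 0; ch < c; ++ch) {
      const double *pd = dy.begin() + ((size_t)s * c + ch) * hw;
      const double *px = xhat.begin() + ((size_t)s * c + ch) * hw;
      double *q = dx.begin() + ((size_t)s * c + ch) * hw;
      double gi = gamma_inv[ch];
      double cg = gi * dgamma[ch] / m, cb = gi * dbeta[ch] / m;
      for (int i = 0; i < hw; ++i) q[i] = gi * pd[i] - px[i] * cg - cb;
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// leaky ReLU forward / gradient-times-dy, elementwise
// [[Rcpp::export]]
NumericVector leaky_forward(NumericVector x, double alpha) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] > 0 ? x[i] : alpha * x[i];
  return y;
}

// [[Rcpp::export]]
NumericVector leaky_backward(NumericVector dy, NumericVector x,
                             double alpha) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dx[i] = x[i] > 0 ? dy[i] : alpha * dy[i];
  return dx;
}
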