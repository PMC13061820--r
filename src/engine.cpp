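// Low-level kernels for the CNN engine: 3D convolution (im2col + GEMM),
// 3D max pooling, and batch normalisation, with the backward passes needed
// for training.  Tensors are R arrays laid out as (H, W, T, C, N), column
// major, so H is the fastest index.  Convolutions are stride 1 with
// explicit symmetric padding; pooling uses kernel == stride with floor
// division of the output size.
//
// GEMMs run in single precision (the usual deep-learning choice); the
// interface stays double on the R side.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

namespace {

// Copy one sample (planar (H,W,T,Cin), double) into a zero-padded
// single-precision buffer of per-channel planes (Hp, Wp, Tp).  Padding
// makes the im2col fill branch-free.
void pad_sample(const double* xs, int H, int W, int T, int Cin,
                int pt, int ph, int pw, fvec& xpad) {
  const int Hp = H + 2 * ph, Wp = W + 2 * pw, Tp = T + 2 * pt;
  const size_t Sp = (size_t)Hp * Wp * Tp;
  xpad.zeros();
  for (int cin = 0; cin < Cin; ++cin) {
    const double* xc = xs + (size_t)cin * H * W * T;
    float* pc = xpad.memptr() + (size_t)cin * Sp;
    for (int t = 0; t < T; ++t)
      for (int w = 0; w < W; ++w) {
        const double* src = xc + (size_t)H * (w + (size_t)W * t);
        float* dst = pc + ph + (size_t)Hp * ((w + pw) + (size_t)Wp * (t + pt));
        for (int h = 0; h < H; ++h) dst[h] = (float)src[h];
      }
  }
}

// Fill `col` (K x cp) with the im2col patch matrix for positions
// [p0, p0 + cp) of one padded sample.  Columns are positions, filled one
// position at a time (sequential writes, contiguous kh-runs on the read
// side); the GEMM then runs channels-major (small m), the fast
// orientation for the narrow layers of this family.  Row order within a
// column: dh + kh*(dw + kw*(dt + kt*cin)).  Position order matches the
// output layout: p = h + H*(w + W*t).
void im2col_chunk(const float* xpad, int H, int W, int T, int Cin,
                  int kt, int kh, int kw, int pt, int ph, int pw,
                  int p0, int cp, fmat& col) {
  const int Hp = H + 2 * ph, Wp = W + 2 * pw, Tp = T + 2 * pt;
  const size_t Sp = (size_t)Hp * Wp * Tp;
  const int HW = H * W;
  int t = p0 / HW;
  int rem = p0 - t * HW;
  int w = rem / H;
  int h = rem - w * H;
  for (int q = 0; q < cp; ++q) {
    float* cq = col.colptr(q);
    int r = 0;
    for (int cin = 0; cin < Cin; ++cin) {
      const float* pc = xpad + (size_t)cin * Sp + h;
      for (int dt = 0; dt < kt; ++dt)
        for (int dw = 0; dw < kw; ++dw) {
          const float* src =
              pc + (size_t)Hp * ((w + dw) + (size_t)Wp * (t + dt));
          for (int dh = 0; dh < kh; ++dh) cq[r++] = src[dh];
        }
    }
    if (++h == H) { h = 0; if (++w == W) { w = 0; ++t; } }
  }
}

// Scatter-add a dcol chunk (K x cp, same layout) into the padded input
// gradient.
void col2im_chunk(const fmat& dcol, int H, int W, int T, int Cin,
                  int kt, int kh, int kw, int pt, int ph, int pw,
                  int p0, int cp, float* dxpad) {
  const int Hp = H + 2 * ph, Wp = W + 2 * pw, Tp = T + 2 * pt;
  const size_t Sp = (size_t)Hp * Wp * Tp;
  const int HW = H * W;
  int t = p0 / HW;
  int rem = p0 - t * HW;
  int w = rem / H;
  int h = rem - w * H;
  for (int q = 0; q < cp; ++q) {
    const float* cq = dcol.colptr(q);
    int r = 0;
    for (int cin = 0; cin < Cin; ++cin) {
      float* pc = dxpad + (size_t)cin * Sp + h;
      for (int dt = 0; dt < kt; ++dt)
        for (int dw = 0; dw < kw; ++dw) {
          float* dst = pc + (size_t)Hp * ((w + dw) + (size_t)Wp * (t + dt));
          for (int dh = 0; dh < kh; ++dh) dst[dh] += cq[r++];
        }
    }
    if (++h == H) { h = 0; if (++w == W) { w = 0; ++t; } }
  }
}

// strip the padding of an accumulated gradient back to planar double
void unpad_sample(const fvec& dxpad, int H, int W, int T, int Cin,
                  int pt, int ph, int pw, double* dxs) {
  const int Hp = H + 2 * ph, Wp = W + 2 * pw, Tp = T + 2 * pt;
  const size_t Sp = (size_t)Hp * Wp * Tp;
  for (int cin = 0; cin < Cin; ++cin) {
    const float* pc = dxpad.memptr() + (size_t)cin * Sp;
    double* dxc = dxs + (size_t)cin * H * W * T;
    for (int t = 0; t < T; ++t)
      for (int w = 0; w < W; ++w) {
        const float* src =
            pc + ph + (size_t)Hp * ((w + pw) + (size_t)Wp * (t + pt));
        double* dst = dxc + (size_t)H * (w + (size_t)W * t);
        for (int h = 0; h < H; ++h) dst[h] = (double)src[h];
      }
  }
}

int chunk_positions(int P, int K) {
  // cap the col buffer around 8M floats (32 MB)
  int cp = (int)std::max((size_t)256, (size_t)(8000000 / std::max(K, 1)));
  return std::min(P, cp);
}

}  // namespace

// [[Rcpp::export(name = ".conv3d_forward")]]
NumericVector conv3d_forward_cpp(NumericVector x, IntegerVector xdim,
                                 NumericMatrix w, IntegerVector kdim,
                                 IntegerVector pad) {
  const int H = xdim[0], W = xdim[1], T = xdim[2], Cin = xdim[3], N = xdim[4];
  const int kt = kdim[0], kh = kdim[1], kw = kdim[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int K = Cin * kt * kh * kw;
  const int Cout = w.ncol();
  if (w.nrow() != K) stop("weight rows (%d) != Cin*kt*kh*kw (%d)", w.nrow(), K);
  const int P = H * W * T;
  const size_t sample_in = (size_t)P * Cin;
  const size_t sample_out = (size_t)P * Cout;

  fmat Wf(K, Cout);
  for (int c = 0; c < Cout; ++c)
    for (int r = 0; r < K; ++r) Wf(r, c) = (float)w(r, c);

  NumericVector y((R_xlen_t)sample_out * N);
  const int CP = chunk_positions(P, K);
  const size_t Sp = (size_t)(H + 2 * ph) * (W + 2 * pw) * (T + 2 * pt);
  fvec xpad(Sp * Cin);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * sample_in;
    double* ys = y.begin() + (size_t)n * sample_out;
    pad_sample(xs, H, W, T, Cin, pt, ph, pw, xpad);
    for (int p0 = 0; p0 < P; p0 += CP) {
      const int cp = std::min(CP, P - p0);
      fmat col(K, cp);
      im2col_chunk(xpad.memptr(), H, W, T, Cin, kt, kh, kw, pt, ph, pw,
                   p0, cp, col);
      fmat Y = Wf.t() * col;  // Cout x cp (channels-major: fast gemm shape)
      for (int c = 0; c < Cout; ++c) {
        double* yc = ys + (size_t)c * P + p0;
        const float* src = Y.memptr() + c;
        for (int q = 0; q < cp; ++q) yc[q] = (double)src[(size_t)q * Cout];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, T, Cout, N);
  return y;
}

// [[Rcpp::export(name = ".conv3d_backward")]]
List conv3d_backward_cpp(NumericVector x, IntegerVector xdim,
                         NumericMatrix w, IntegerVector kdim,
                         IntegerVector pad, NumericVector dy,
                         bool need_dx = true) {
  const int H = xdim[0], W = xdim[1], T = xdim[2], Cin = xdim[3], N = xdim[4];
  const int kt = kdim[0], kh = kdim[1], kw = kdim[2];
  const int pt = pad[0], ph = pad[1], pw = pad[2];
  const int K = Cin * kt * kh * kw;
  const int Cout = w.ncol();
  const int P = H * W * T;
  const size_t sample_in = (size_t)P * Cin;
  const size_t sample_out = (size_t)P * Cout;

  fmat Wf(K, Cout);
  for (int c = 0; c < Cout; ++c)
    for (int r = 0; r < K; ++r) Wf(r, c) = (float)w(r, c);

  NumericVector dx(need_dx ? (R_xlen_t)sample_in * N : 0);
  fmat dWf(K, Cout, arma::fill::zeros);
  const int CP = chunk_positions(P, K);
  const size_t Sp = (size_t)(H + 2 * ph) * (W + 2 * pw) * (T + 2 * pt);
  fvec xpad(Sp * Cin), dxpad(need_dx ? Sp * Cin : 0);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * sample_in;
    const double* dys = dy.begin() + (size_t)n * sample_out;
    pad_sample(xs, H, W, T, Cin, pt, ph, pw, xpad);
    if (need_dx) dxpad.zeros();
    for (int p0 = 0; p0 < P; p0 += CP) {
      const int cp = std::min(CP, P - p0);
      fmat col(K, cp);
      im2col_chunk(xpad.memptr(), H, W, T, Cin, kt, kh, kw, pt, ph, pw,
                   p0, cp, col);
      fmat dYv(Cout, cp);
      for (int c = 0; c < Cout; ++c) {
        const double* src = dys + (size_t)c * P + p0;
        float* dst = dYv.memptr() + c;
        for (int q = 0; q < cp; ++q) dst[(size_t)q * Cout] = (float)src[q];
      }
      dWf += col * dYv.t();              // K x Cout
      if (need_dx) {
        fmat dcol = Wf * dYv;            // K x cp
        col2im_chunk(dcol, H, W, T, Cin, kt, kh, kw, pt, ph, pw, p0, cp,
                     dxpad.memptr());
      }
    }
    if (need_dx)
      unpad_sample(dxpad, H, W, T, Cin, pt, ph, pw,
                   dx.begin() + (size_t)n * sample_in);
  }
  if (need_dx) dx.attr("dim") = IntegerVector::create(H, W, T, Cin, N);
  NumericMatrix dw(K, Cout);
  for (int c = 0; c < Cout; ++c)
    for (int r = 0; r < K; ++r) dw(r, c) = (double)dWf(r, c);
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// [[Rcpp::export(name = ".relu_forward")]]
NumericVector relu_forward_cpp(NumericVector x) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export(name = ".relu_backward")]]
NumericVector relu_backward_cpp(NumericVector dy, NumericVector x) {
  NumericVector dx(dy.size());
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[i] = x[i] > 0 ? dy[i] : 0.0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// [[Rcpp::export(name = ".maxpool3d_forward")]]
List maxpool3d_forward_cpp(NumericVector x, IntegerVector xdim,
                           IntegerVector k) {
  const int H = xdim[0], W = xdim[1], T = xdim[2], C = xdim[3], N = xdim[4];
  const int pt = k[0], ph = k[1], pw = k[2];
  const int Ho = H / ph, Wo = W / pw, To = T / pt;
  if (Ho < 1 || Wo < 1 || To < 1)
    stop("pooling kernel (%d,%d,%d) collapses input (%d,%d,%d) to zero",
         pt, ph, pw, T, H, W);
  const size_t Po = (size_t)Ho * Wo * To;
  NumericVector y((R_xlen_t)(Po * C * N));
  IntegerVector idx((R_xlen_t)(Po * C * N));  // 0-based into x
  const size_t HW = (size_t)H * W;
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)c + (size_t)C * n) * HW * T;
      for (int to = 0; to < To; ++to) {
        for (int wo = 0; wo < Wo; ++wo) {
          for (int ho = 0; ho < Ho; ++ho) {
            double best = R_NegInf;
            size_t besti = 0;
            for (int dt = 0; dt < pt; ++dt) {
              const int t = to * pt + dt;
              for (int dw = 0; dw < pw; ++dw) {
                const int w = wo * pw + dw;
                for (int dh = 0; dh < ph; ++dh) {
                  const int h = ho * ph + dh;
                  const size_t i = base + h + (size_t)H * (w + (size_t)W * t);
                  if (x[i] > best) { best = x[i]; besti = i; }
                }
              }
            }
            y[o] = best;
            idx[o] = (int)besti;
            ++o;
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, To, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool3d_backward")]]
NumericVector maxpool3d_backward_cpp(NumericVector dy, IntegerVector idx,
                                     IntegerVector xdim) {
  const R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3] * xdim[4];
  NumericVector dx(n);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  dx.attr("dim") = xdim;
  return dx;
}

// [[Rcpp::export(name = ".bn_forward")]]
List bn_forward_cpp(NumericVector x, IntegerVector xdim,
                    NumericVector gamma, NumericVector beta,
                    NumericVector rmean, NumericVector rvar,
                    bool training, double momentum, double eps,
                    bool fuse_relu = false) {
  const int H = xdim[0], W = xdim[1], T = xdim[2], C = xdim[3], N = xdim[4];
  const size_t S = (size_t)H * W * T;  // per channel per sample
  NumericVector y(x.size());
  NumericVector mean(C), invstd(C);
  NumericVector rm = clone(rmean), rv = clone(rvar);
  for (int c = 0; c < C; ++c) {
    double m, v;
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + ((size_t)c + (size_t)C * n) * S;
        for (size_t i = 0; i < S; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      }
      const double cnt = (double)S * N;
      m = s / cnt;
      v = s2 / cnt - m * m;
      if (v < 0) v = 0;
      rm[c] = (1 - momentum) * rm[c] + momentum * m;
      rv[c] = (1 - momentum) * rv[c] + momentum * v;
    } else {
      m = rm[c];
      v = rv[c];
    }
    const double is = 1.0 / std::sqrt(v + eps);
    mean[c] = m;
    invstd[c] = is;
    const double g = gamma[c] * is, b = beta[c] - m * g;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)c + (size_t)C * n) * S;
      double* yc = y.begin() + ((size_t)c + (size_t)C * n) * S;
      if (fuse_relu) {
        for (size_t i = 0; i < S; ++i) {
          const double v = g * xc[i] + b;
          yc[i] = v > 0 ? v : 0.0;
        }
      } else {
        for (size_t i = 0; i < S; ++i) yc[i] = g * xc[i] + b;
      }
    }
  }
  y.attr("dim") = xdim;
  return List::create(_["y"] = y, _["mean"] = mean, _["invstd"] = invstd,
                      _["running_mean"] = rm, _["running_var"] = rv);
}

// When `relu_y` is non-empty it is the output of a ReLU fused after this
// BN in the forward pass; the incoming gradient is masked by it on the
// fly (saving the separate ReLU backward pass and its allocation).
// [[Rcpp::export(name = ".bn_backward")]]
List bn_backward_cpp(NumericVector dy, NumericVector x, IntegerVector xdim,
                     NumericVector gamma, NumericVector mean,
                     NumericVector invstd,
                     NumericVector relu_y = NumericVector()) {
  const int H = xdim[0], W = xdim[1], T = xdim[2], C = xdim[3], N = xdim[4];
  const size_t S = (size_t)H * W * T;
  const double cnt = (double)S * N;
  const bool fuse = relu_y.size() > 0;
  if (fuse && relu_y.size() != dy.size())
    stop("relu mask size mismatch in bn backward");
  NumericVector dx(x.size());
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double m = mean[c], is = invstd[c];
    double sdy = 0, sdyx = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)c + (size_t)C * n) * S;
      const double* dyc = dy.begin() + off;
      const double* xc = x.begin() + off;
      const double* yc = fuse ? relu_y.begin() + off : nullptr;
      for (size_t i = 0; i < S; ++i) {
        const double g = (fuse && yc[i] <= 0) ? 0.0 : dyc[i];
        sdy += g;
        sdyx += g * (xc[i] - m) * is;
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    const double k = gamma[c] * is / cnt;
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)c + (size_t)C * n) * S;
      const double* dyc = dy.begin() + off;
      const double* xc = x.begin() + off;
      const double* yc = fuse ? relu_y.begin() + off : nullptr;
      double* dxc = dx.begin() + off;
      for (size_t i = 0; i < S; ++i) {
        const double g = (fuse && yc[i] <= 0) ? 0.0 : dyc[i];
        const double xhat = (xc[i] - m) * is;
        dxc[i] = k * (cnt * g - sdy - xhat * sdyx);
      }
    }
  }
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
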