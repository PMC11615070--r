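// N-dimensional (up to 3 spatial axes) convolution via chunked im2col + GEMM.
// Layout: column-major arrays with spatial axes first and channels last,
// i.e. x has dim (X, Y, Z, C_in); 2D inputs use Z = 1 with kz = 1.
// Weights have dim (kx, ky, kz, C_in, C_out) so the flat vector is already
// the K x C_out matrix with K = kx*ky*kz*C_in.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_len(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// Fill `cols` (K x nc) with the im2col block for output linear indices
// [n0, n0+nc). Out-of-bounds (padding) entries are zero.
static void im2col_chunk(const double* x, const int* xd, const int* kd,
                         const int* sd, const int* pd, const int* od,
                         int cin, long n0, int nc, arma::mat& cols) {
  const int X = xd[0], Y = xd[1], Z = xd[2];
  const int kx = kd[0], ky = kd[1], kz = kd[2];
  const int Xo = od[0], Yo = od[1];
  const long plane = (long)X * Y, vol = plane * Z;
  cols.zeros();
  for (int j = 0; j < nc; ++j) {
    long n = n0 + j;
    int xo = (int)(n % Xo);
    int yo = (int)((n / Xo) % Yo);
    int zo = (int)(n / ((long)Xo * Yo));
    int x0 = xo * sd[0] - pd[0];
    int y0 = yo * sd[1] - pd[1];
    int z0 = zo * sd[2] - pd[2];
    double* cj = cols.colptr(j);
    long k = 0;
    for (int c = 0; c < cin; ++c) {
      const double* xc = x + c * vol;
      for (int kzi = 0; kzi < kz; ++kzi) {
        int zi = z0 + kzi;
        bool zok = (zi >= 0 && zi < Z);
        for (int kyi = 0; kyi < ky; ++kyi) {
          int yi = y0 + kyi;
          bool yok = zok && (yi >= 0 && yi < Y);
          const double* base = xc + (long)zi * plane + (long)yi * X;
          for (int kxi = 0; kxi < kx; ++kxi, ++k) {
            int xi = x0 + kxi;
            if (yok && xi >= 0 && xi < X) cj[k] = base[xi];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nf_conv_fwd(NumericVector x, IntegerVector xdim,
                          NumericVector w, IntegerVector kdim,
                          int cin, int cout, NumericVector b,
                          IntegerVector stride, IntegerVector pad) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2];
  const int Xo = out_len(X, kdim[0], stride[0], pad[0]);
  const int Yo = out_len(Y, kdim[1], stride[1], pad[1]);
  const int Zo = out_len(Z, kdim[2], stride[2], pad[2]);
  if (Xo < 1 || Yo < 1 || Zo < 1) stop("convolution output would be empty");
  const long N = (long)Xo * Yo * Zo;
  const long K = (long)kdim[0] * kdim[1] * kdim[2] * cin;
  const int od[3] = {Xo, Yo, Zo};
  NumericVector y((R_xlen_t)(N * cout));
  arma::mat Wm(w.begin(), K, cout, false, true);
  const int chunk = (int)std::min<long>(N, std::max<long>(1L, (1L << 22) / K));
  arma::mat cols(K, chunk);
  for (long n0 = 0; n0 < N; n0 += chunk) {
    int nc = (int)std::min<long>(chunk, N - n0);
    im2col_chunk(x.begin(), xdim.begin(), kdim.begin(), stride.begin(),
                 pad.begin(), od, cin, n0, nc, cols);
    arma::mat Yc = Wm.t() * cols.cols(0, nc - 1); // cout x nc
    for (int c = 0; c < cout; ++c) {
      double* yp = y.begin() + (long)c * N + n0;
      const double bc = b[c];
      for (int j = 0; j < nc; ++j) yp[j] = Yc(c, j) + bc;
    }
  }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, cout);
  return y;
}

// [[Rcpp::export]]
List nf_conv_bwd(NumericVector x, IntegerVector xdim,
                 NumericVector w, IntegerVector kdim,
                 int cin, int cout, NumericVector gy,
                 IntegerVector stride, IntegerVector pad) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2];
  const int Xo = out_len(X, kdim[0], stride[0], pad[0]);
  const int Yo = out_len(Y, kdim[1], stride[1], pad[1]);
  const int Zo = out_len(Z, kdim[2], stride[2], pad[2]);
  const long N = (long)Xo * Yo * Zo;
  const long K = (long)kdim[0] * kdim[1] * kdim[2] * cin;
  const int od[3] = {Xo, Yo, Zo};
  const int kx = kdim[0], ky = kdim[1], kz = kdim[2];
  const long plane = (long)X * Y, vol = plane * Z;

  NumericVector gx(x.size());
  NumericVector gw(w.size());
  NumericVector gb(cout);
  arma::mat Wm(w.begin(), K, cout, false, true);
  arma::mat Gw(gw.begin(), K, cout, false, true);

  const int chunk = (int)std::min<long>(N, std::max<long>(1L, (1L << 22) / K));
  arma::mat cols(K, chunk), Gy(cout, chunk);
  for (long n0 = 0; n0 < N; n0 += chunk) {
    int nc = (int)std::min<long>(chunk, N - n0);
    im2col_chunk(x.begin(), xdim.begin(), kdim.begin(), stride.begin(),
                 pad.begin(), od, cin, n0, nc, cols);
    for (int c = 0; c < cout; ++c) {
      const double* gp = gy.begin() + (long)c * N + n0;
      for (int j = 0; j < nc; ++j) Gy(c, j) = gp[j];
    }
    arma::mat GyV = Gy.cols(0, nc - 1);
    Gw += cols.cols(0, nc - 1) * GyV.t();
    for (int c = 0; c < cout; ++c) gb[c] += arma::accu(GyV.row(c));
    arma::mat Gcols = Wm * GyV; // K x nc
    // col2im scatter-add
    for (int j = 0; j < nc; ++j) {
      long n = n0 + j;
      int xo = (int)(n % Xo);
      int yo = (int)((n / Xo) % Yo);
      int zo = (int)(n / ((long)Xo * Yo));
      int x0 = xo * stride[0] - pad[0];
      int y0 = yo * stride[1] - pad[1];
      int z0 = zo * stride[2] - pad[2];
      const double* cj = Gcols.colptr(j);
      long k = 0;
      for (int c = 0; c < cin; ++c) {
        double* xc = gx.begin() + (long)c * vol;
        for (int kzi = 0; kzi < kz; ++kzi) {
          int zi = z0 + kzi;
          bool zok = (zi >= 0 && zi < Z);
          for (int kyi = 0; kyi < ky; ++kyi) {
            int yi = y0 + kyi;
            bool yok = zok && (yi >= 0 && yi < Y);
            double* base = xc + (long)zi * plane + (long)yi * X;
            for (int kxi = 0; kxi < kx; ++kxi, ++k) {
              int xi = x0 + kxi;
              if (yok && xi >= 0 && xi < X) base[xi] += cj[k];
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = x.attr("dim");
  gw.attr("dim") = w.attr("dim");
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---- single-precision variants -------------------------------------------
// Same contracts as above with float arithmetic internally; inputs and
// outputs remain R doubles.  Used by the training loop, where float
// round-off is far below gradient noise.

static void im2col_chunk_f(const double* x, const int* xd, const int* kd,
                           const int* sd, const int* pd, const int* od,
                           int cin, long n0, int nc, arma::fmat& cols) {
  const int X = xd[0], Y = xd[1], Z = xd[2];
  const int kx = kd[0], ky = kd[1], kz = kd[2];
  const int Xo = od[0], Yo = od[1];
  const long plane = (long)X * Y, vol = plane * Z;
  cols.zeros();
  for (int j = 0; j < nc; ++j) {
    long n = n0 + j;
    int xo = (int)(n % Xo);
    int yo = (int)((n / Xo) % Yo);
    int zo = (int)(n / ((long)Xo * Yo));
    int x0 = xo * sd[0] - pd[0];
    int y0 = yo * sd[1] - pd[1];
    int z0 = zo * sd[2] - pd[2];
    float* cj = cols.colptr(j);
    long k = 0;
    for (int c = 0; c < cin; ++c) {
      const double* xc = x + c * vol;
      for (int kzi = 0; kzi < kz; ++kzi) {
        int zi = z0 + kzi;
        bool zok = (zi >= 0 && zi < Z);
        for (int kyi = 0; kyi < ky; ++kyi) {
          int yi = y0 + kyi;
          bool yok = zok && (yi >= 0 && yi < Y);
          const double* base = xc + (long)zi * plane + (long)yi * X;
          for (int kxi = 0; kxi < kx; ++kxi, ++k) {
            int xi = x0 + kxi;
            if (yok && xi >= 0 && xi < X) cj[k] = (float)base[xi];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nf_conv_fwd_f(NumericVector x, IntegerVector xdim,
                            NumericVector w, IntegerVector kdim,
                            int cin, int cout, NumericVector b,
                            IntegerVector stride, IntegerVector pad) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2];
  const int Xo = out_len(X, kdim[0], stride[0], pad[0]);
  const int Yo = out_len(Y, kdim[1], stride[1], pad[1]);
  const int Zo = out_len(Z, kdim[2], stride[2], pad[2]);
  if (Xo < 1 || Yo < 1 || Zo < 1) stop("convolution output would be empty");
  const long N = (long)Xo * Yo * Zo;
  const long K = (long)kdim[0] * kdim[1] * kdim[2] * cin;
  const int od[3] = {Xo, Yo, Zo};
  NumericVector y((R_xlen_t)(N * cout));
  arma::fmat Wm(K, cout);
  for (long i = 0; i < K * cout; ++i) Wm.memptr()[i] = (float)w[i];
  const int chunk = (int)std::min<long>(N, std::max<long>(1L, (1L << 22) / K));
  arma::fmat cols(K, chunk);
  for (long n0 = 0; n0 < N; n0 += chunk) {
    int nc = (int)std::min<long>(chunk, N - n0);
    im2col_chunk_f(x.begin(), xdim.begin(), kdim.begin(), stride.begin(),
                   pad.begin(), od, cin, n0, nc, cols);
    arma::fmat Yc = Wm.t() * cols.cols(0, nc - 1);
    for (int c = 0; c < cout; ++c) {
      double* yp = y.begin() + (long)c * N + n0;
      const double bc = b[c];
      for (int j = 0; j < nc; ++j) yp[j] = (double)Yc(c, j) + bc;
    }
  }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, cout);
  return y;
}

// [[Rcpp::export]]
List nf_conv_bwd_f(NumericVector x, IntegerVector xdim,
                   NumericVector w, IntegerVector kdim,
                   int cin, int cout, NumericVector gy,
                   IntegerVector stride, IntegerVector pad) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2];
  const int Xo = out_len(X, kdim[0], stride[0], pad[0]);
  const int Yo = out_len(Y, kdim[1], stride[1], pad[1]);
  const int Zo = out_len(Z, kdim[2], stride[2], pad[2]);
  const long N = (long)Xo * Yo * Zo;
  const long K = (long)kdim[0] * kdim[1] * kdim[2] * cin;
  const int od[3] = {Xo, Yo, Zo};
  const int kx = kdim[0], ky = kdim[1], kz = kdim[2];
  const long plane = (long)X * Y, vol = plane * Z;

  NumericVector gx(x.size());
  NumericVector gw(w.size());
  NumericVector gb(cout);
  arma::fmat Wm(K, cout), Gw(K, cout, arma::fill::zeros);
  for (long i = 0; i < K * cout; ++i) Wm.memptr()[i] = (float)w[i];

  const int chunk = (int)std::min<long>(N, std::max<long>(1L, (1L << 22) / K));
  arma::fmat cols(K, chunk), Gy(cout, chunk);
  for (long n0 = 0; n0 < N; n0 += chunk) {
    int nc = (int)std::min<long>(chunk, N - n0);
    im2col_chunk_f(x.begin(), xdim.begin(), kdim.begin(), stride.begin(),
                   pad.begin(), od, cin, n0, nc, cols);
    for (int c = 0; c < cout; ++c) {
      const double* gp = gy.begin() + (long)c * N + n0;
      for (int j = 0; j < nc; ++j) Gy(c, j) = (float)gp[j];
    }
    arma::fmat GyV = Gy.cols(0, nc - 1);
    Gw += cols.cols(0, nc - 1) * GyV.t();
    for (int c = 0; c < cout; ++c) gb[c] += (double)arma::accu(GyV.row(c));
    arma::fmat Gcols = Wm * GyV;
    for (int j = 0; j < nc; ++j) {
      long n = n0 + j;
      int xo = (int)(n % Xo);
      int yo = (int)((n / Xo) % Yo);
      int zo = (int)(n / ((long)Xo * Yo));
      int x0 = xo * stride[0] - pad[0];
      int y0 = yo * stride[1] - pad[1];
      int z0 = zo * stride[2] - pad[2];
      const float* cj = Gcols.colptr(j);
      long k = 0;
      for (int c = 0; c < cin; ++c) {
        double* xc = gx.begin() + (long)c * vol;
        for (int kzi = 0; kzi < kz; ++kzi) {
          int zi = z0 + kzi;
          bool zok = (zi >= 0 && zi < Z);
          for (int kyi = 0; kyi < ky; ++kyi) {
            int yi = y0 + kyi;
            bool yok = zok && (yi >= 0 && yi < Y);
            double* base = xc + (long)zi * plane + (long)yi * X;
            for (int kxi = 0; kxi < kx; ++kxi, ++k) {
              int xi = x0 + kxi;
              if (yok && xi >= 0 && xi < X) base[xi] += (double)cj[k];
            }
          }
        }
      }
    }
  }
  for (long i = 0; i < K * cout; ++i) gw[i] = (double)Gw.memptr()[i];
  gx.attr("dim") = x.attr("dim");
  gw.attr("dim") = w.attr("dim");
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
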