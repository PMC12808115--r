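// 3x3 same-padding convolution on (H, W, N, C) arrays, forward and backward.
// The nine kernel offsets each contribute one GEMM on a gathered
// (H*W*N) x Cin matrix; gathering is done here so the R side stays allocation
// light. Column-major layout with h fastest matches R arrays.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// copy the (di, dj)-shifted window of the zero-padded input into Xs
static void gather(const double* xp, double* xs,
                   int H, int W, int N, int C, int di, int dj) {
  const int Hp = H + 2, Wp = W + 2;
  const long planep = (long)Hp * Wp;
  const long plane = (long)H * W;
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const double* src0 = xp + ((long)c * N + n) * planep;
      double* dst0 = xs + ((long)c * N + n) * plane;
      for (int w = 0; w < W; ++w) {
        const double* src = src0 + (long)(w + dj) * Hp + di;
        std::memcpy(dst0 + (long)w * H, src, sizeof(double) * H);
      }
    }
  }
}

// scatter-add columns of dXs back into the padded gradient buffer
static void scatter(double* dxp, const double* dxs,
                    int H, int W, int N, int C, int di, int dj) {
  const int Hp = H + 2, Wp = W + 2;
  const long planep = (long)Hp * Wp;
  const long plane = (long)H * W;
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      double* dst0 = dxp + ((long)c * N + n) * planep;
      const double* src0 = dxs + ((long)c * N + n) * plane;
      for (int w = 0; w < W; ++w) {
        double* dst = dst0 + (long)(w + dj) * Hp + di;
        const double* src = src0 + (long)w * H;
        for (int h = 0; h < H; ++h) dst[h] += src[h];
      }
    }
  }
}

static arma::mat kernel_slice(const NumericVector& Wt, int di, int dj,
                              int Cin, int Cout) {
  arma::mat Wk(Cin, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      Wk(ci, co) = Wt[di + 3 * dj + 9 * (ci + (long)Cin * co)];
  return Wk;
}

static std::vector<double> pad_input(const NumericVector& x,
                                     int H, int W, int N, int C) {
  const int Hp = H + 2, Wp = W + 2;
  std::vector<double> xp((long)Hp * Wp * N * C, 0.0);
  const long planep = (long)Hp * Wp;
  const long plane = (long)H * W;
  const double* xd = x.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      const double* src0 = xd + ((long)c * N + n) * plane;
      double* dst0 = xp.data() + ((long)c * N + n) * planep;
      for (int w = 0; w < W; ++w)
        std::memcpy(dst0 + (long)(w + 1) * Hp + 1, src0 + (long)w * H,
                    sizeof(double) * H);
    }
  return xp;
}

// [[Rcpp::export(name = ".conv3_fwd_cpp")]]
NumericVector conv3_fwd_cpp(NumericVector x, NumericVector Wt, NumericVector b,
                            IntegerVector dims) {
  const int H = dims[0], W = dims[1], N = dims[2], Cin = dims[3];
  const int Cout = b.size();
  const long rows = (long)H * W * N;
  std::vector<double> xp = pad_input(x, H, W, N, Cin);
  arma::mat Xs(rows, Cin);
  arma::mat out(rows, Cout, arma::fill::zeros);
  for (int dj = 0; dj < 3; ++dj)
    for (int di = 0; di < 3; ++di) {
      gather(xp.data(), Xs.memptr(), H, W, N, Cin, di, dj);
      out += Xs * kernel_slice(Wt, di, dj, Cin, Cout);
    }
  for (int co = 0; co < Cout; ++co) out.col(co) += b[co];
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(H, W, N, Cout);
  return res;
}

// [[Rcpp::export(name = ".conv3_bwd_cpp")]]
List conv3_bwd_cpp(NumericVector x, NumericVector Wt, NumericVector g,
                   IntegerVector dims, int Cout, bool want_dx) {
  const int H = dims[0], W = dims[1], N = dims[2], Cin = dims[3];
  const long rows = (long)H * W * N;
  std::vector<double> xp = pad_input(x, H, W, N, Cin);
  arma::mat G(const_cast<double*>(g.begin()), rows, Cout, false, true);
  arma::mat Xs(rows, Cin);
  NumericVector dW(9L * Cin * Cout);
  std::vector<double> dxp;
  if (want_dx) dxp.assign((long)(H + 2) * (W + 2) * N * Cin, 0.0);
  arma::mat dXs(rows, Cin);
  for (int dj = 0; dj < 3; ++dj)
    for (int di = 0; di < 3; ++di) {
      gather(xp.data(), Xs.memptr(), H, W, N, Cin, di, dj);
      arma::mat dWk = Xs.t() * G;
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          dW[di + 3 * dj + 9 * (ci + (long)Cin * co)] = dWk(ci, co);
      if (want_dx) {
        dXs = G * kernel_slice(Wt, di, dj, Cin, Cout).t();
        scatter(dxp.data(), dXs.memptr(), H, W, N, Cin, di, dj);
      }
    }
  dW.attr("dim") = IntegerVector::create(3, 3, Cin, Cout);
  NumericVector db(Cout);
  for (int co = 0; co < Cout; ++co) db[co] = arma::accu(G.col(co));
  List res = List::create(Named("dW") = dW, Named("db") = db);
  if (want_dx) {
    NumericVector dx((long)H * W * N * Cin);
    const int Hp = H + 2;
    const long planep = (long)Hp * (W + 2);
    const long plane = (long)H * W;
    for (int c = 0; c < Cin; ++c)
      for (int n = 0; n < N; ++n) {
        const double* src0 = dxp.data() + ((long)c * N + n) * planep;
        double* dst0 = dx.begin() + ((long)c * N + n) * plane;
        for (int w = 0; w < W; ++w)
          std::memcpy(dst0 + (long)w * H, src0 + (long)(w + 1) * Hp + 1,
                      sizeof(double) * H);
      }
    dx.attr("dim") = IntegerVector::create(H, W, N, Cin);
    res["dx"] = dx;
  }
  return res;
}
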