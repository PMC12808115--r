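// Shape/pooling helpers on (H, W, N, C) arrays: 2x2 average pooling, nearest
// upsampling, channel concatenation, and per-(sample, channel) bias addition.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".pool2_cpp")]]
NumericVector pool2_cpp(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1];
  const long NC = (long)dims[2] * dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((long)Ho * Wo * NC);
  const double* xd = x.begin();
  double* od = out.begin();
  for (long p = 0; p < NC; ++p) {
    const double* xi = xd + p * H * W;
    double* oi = od + p * (long)Ho * Wo;
    for (int w = 0; w < Wo; ++w) {
      const double* c0 = xi + (long)(2 * w) * H;
      const double* c1 = xi + (long)(2 * w + 1) * H;
      double* oc = oi + (long)w * Ho;
      for (int h = 0; h < Ho; ++h)
        oc[h] = (c0[2 * h] + c0[2 * h + 1] + c1[2 * h] + c1[2 * h + 1]) * 0.25;
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, dims[2], dims[3]);
  return out;
}

// [[Rcpp::export(name = ".pool2_bwd_cpp")]]
NumericVector pool2_bwd_cpp(NumericVector g, IntegerVector dims_in) {
  const int H = dims_in[0], W = dims_in[1];
  const long NC = (long)dims_in[2] * dims_in[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((long)H * W * NC);
  const double* gd = g.begin();
  double* dd = dx.begin();
  for (long p = 0; p < NC; ++p) {
    const double* gi = gd + p * (long)Ho * Wo;
    double* di = dd + p * (long)H * W;
    for (int w = 0; w < Wo; ++w) {
      double* c0 = di + (long)(2 * w) * H;
      double* c1 = di + (long)(2 * w + 1) * H;
      const double* gc = gi + (long)w * Ho;
      for (int h = 0; h < Ho; ++h) {
        const double v = gc[h] * 0.25;
        c0[2 * h] = v; c0[2 * h + 1] = v; c1[2 * h] = v; c1[2 * h + 1] = v;
      }
    }
  }
  dx.attr("dim") = dims_in;
  return dx;
}

// [[Rcpp::export(name = ".up2_cpp")]]
NumericVector up2_cpp(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1];
  const long NC = (long)dims[2] * dims[3];
  const int Ho = H * 2, Wo = W * 2;
  NumericVector out((long)Ho * Wo * NC);
  const double* xd = x.begin();
  double* od = out.begin();
  for (long p = 0; p < NC; ++p) {
    const double* xi = xd + p * (long)H * W;
    double* oi = od + p * (long)Ho * Wo;
    for (int w = 0; w < W; ++w) {
      const double* xc = xi + (long)w * H;
      double* o0 = oi + (long)(2 * w) * Ho;
      double* o1 = oi + (long)(2 * w + 1) * Ho;
      for (int h = 0; h < H; ++h) {
        const double v = xc[h];
        o0[2 * h] = v; o0[2 * h + 1] = v; o1[2 * h] = v; o1[2 * h + 1] = v;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, dims[2], dims[3]);
  return out;
}

// [[Rcpp::export(name = ".up2_bwd_cpp")]]
NumericVector up2_bwd_cpp(NumericVector g, IntegerVector dims_out) {
  const int Ho = dims_out[0], Wo = dims_out[1];
  const long NC = (long)dims_out[2] * dims_out[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx((long)H * W * NC);
  const double* gd = g.begin();
  double* dd = dx.begin();
  for (long p = 0; p < NC; ++p) {
    const double* gi = gd + p * (long)Ho * Wo;
    double* di = dd + p * (long)H * W;
    for (int w = 0; w < W; ++w) {
      const double* g0 = gi + (long)(2 * w) * Ho;
      const double* g1 = gi + (long)(2 * w + 1) * Ho;
      double* dc = di + (long)w * H;
      for (int h = 0; h < H; ++h)
        dc[h] = g0[2 * h] + g0[2 * h + 1] + g1[2 * h] + g1[2 * h + 1];
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, dims_out[2], dims_out[3]);
  return dx;
}

// [[Rcpp::export(name = ".concat_ch_cpp")]]
NumericVector concat_ch_cpp(NumericVector a, NumericVector b,
                            IntegerVector da, IntegerVector db) {
  NumericVector out(a.size() + b.size());
  const long plane = (long)da[0] * da[1] * da[2];
  std::memcpy(out.begin(), a.begin(), sizeof(double) * a.size());
  std::memcpy(out.begin() + plane * da[3], b.begin(), sizeof(double) * b.size());
  out.attr("dim") = IntegerVector::create(da[0], da[1], da[2], da[3] + db[3]);
  return out;
}

// [[Rcpp::export(name = ".add_ncbias_cpp")]]
NumericVector add_ncbias_cpp(NumericVector x, NumericMatrix bias,
                             IntegerVector dims) {
  const int N = dims[2], C = dims[3];
  const long m = (long)dims[0] * dims[1];
  NumericVector out(x.size());
  const double* xd = x.begin();
  double* od = out.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      const double bv = bias(n, c);
      const double* xi = xd + ((long)c * N + n) * m;
      double* oi = od + ((long)c * N + n) * m;
      for (long i = 0; i < m; ++i) oi[i] = xi[i] + bv;
    }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export(name = ".sum_nc_cpp")]]
NumericMatrix sum_nc_cpp(NumericVector g, IntegerVector dims) {
  const int N = dims[2], C = dims[3];
  const long m = (long)dims[0] * dims[1];
  NumericMatrix out(N, C);
  const double* gd = g.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      const double* gi = gd + ((long)c * N + n) * m;
      double s = 0;
      for (long i = 0; i < m; ++i) s += gi[i];
      out(n, c) = s;
    }
  return out;
}

// [[Rcpp::export(name = ".silu_infer_cpp")]]
NumericVector silu_infer_cpp(NumericVector x) {
  NumericVector out(x.size());
  for (long i = 0; i < (long)x.size(); ++i)
    out[i] = x[i] / (1.0 + std::exp(-x[i]));
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export(name = ".instnorm_affine_infer_cpp")]]
NumericVector instnorm_affine_infer_cpp(NumericVector x, IntegerVector dims,
                                        NumericMatrix gamma, NumericMatrix beta,
                                        double eps) {
  const int N = dims[2], C = dims[3];
  const long m = (long)dims[0] * dims[1];
  NumericVector out(x.size());
  const double* xd = x.begin();
  double* od = out.begin();
  for (long gidx = 0; gidx < (long)N * C; ++gidx) {
    const double* xi = xd + gidx * m;
    double mu = 0;
    for (long i = 0; i < m; ++i) mu += xi[i];
    mu /= m;
    double v = 0;
    for (long i = 0; i < m; ++i) { double d = xi[i] - mu; v += d * d; }
    v /= m;
    const int n = gidx % N, c = gidx / N;
    const double a = gamma(n, c) / std::sqrt(v + eps);
    const double b = beta(n, c) - a * mu;
    double* oi = od + gidx * m;
    for (long i = 0; i < m; ++i) oi[i] = a * xi[i] + b;
  }
  out.attr("dim") = dims;
  return out;
}
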