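// Fused instance-normalization + affine, and SiLU, on (H, W, N, C) arrays.
// Normalization statistics are per (sample, channel) map over the H*W extent.
// gamma/beta are passed expanded to N x C; per-channel parameters are reduced
// on the R side.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".instnorm_affine_fwd_cpp")]]
List instnorm_affine_fwd_cpp(NumericVector x, IntegerVector dims,
                             NumericMatrix gamma, NumericMatrix beta,
                             double eps) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const long m = (long)H * W;
  const long groups = (long)N * C;
  NumericVector out(x.size()), xn(x.size());
  NumericVector svec(groups);
  const double* xd = x.begin();
  double* od = out.begin();
  double* xnd = xn.begin();
  for (long gidx = 0; gidx < groups; ++gidx) {
    const double* xi = xd + gidx * m;
    double mu = 0;
    for (long i = 0; i < m; ++i) mu += xi[i];
    mu /= m;
    double v = 0;
    for (long i = 0; i < m; ++i) { double d = xi[i] - mu; v += d * d; }
    v /= m;
    const double s = std::sqrt(v + eps);
    svec[gidx] = s;
    const int n = gidx % N, c = gidx / N;
    const double g = gamma(n, c), b = beta(n, c);
    double* oi = od + gidx * m;
    double* xni = xnd + gidx * m;
    for (long i = 0; i < m; ++i) {
      const double z = (xi[i] - mu) / s;
      xni[i] = z;
      oi[i] = g * z + b;
    }
  }
  out.attr("dim") = dims;
  return List::create(Named("out") = out, Named("xn") = xn, Named("s") = svec);
}

// [[Rcpp::export(name = ".instnorm_affine_bwd_cpp")]]
List instnorm_affine_bwd_cpp(NumericVector gout, NumericVector xn,
                             NumericVector svec, IntegerVector dims,
                             NumericMatrix gamma, bool want_dx) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const long m = (long)H * W;
  const long groups = (long)N * C;
  NumericMatrix dgamma(N, C), dbeta(N, C);
  NumericVector dx(want_dx ? gout.size() : 0);
  const double* gd = gout.begin();
  const double* xnd = xn.begin();
  for (long gidx = 0; gidx < groups; ++gidx) {
    const double* gi = gd + gidx * m;
    const double* xni = xnd + gidx * m;
    const int n = gidx % N, c = gidx / N;
    double sg = 0, sb = 0;
    for (long i = 0; i < m; ++i) { sg += gi[i] * xni[i]; sb += gi[i]; }
    dgamma(n, c) = sg;
    dbeta(n, c) = sb;
    if (want_dx) {
      const double gmul = gamma(n, c);
      const double mean_d = gmul * sb / m;
      const double mean_dxn = gmul * sg / m;
      const double s = svec[gidx];
      double* dxi = dx.begin() + gidx * m;
      for (long i = 0; i < m; ++i)
        dxi[i] = (gmul * gi[i] - mean_d - xni[i] * mean_dxn) / s;
    }
  }
  List res = List::create(Named("dgamma") = dgamma, Named("dbeta") = dbeta);
  if (want_dx) { dx.attr("dim") = dims; res["dx"] = dx; }
  return res;
}

// [[Rcpp::export(name = ".silu_fwd_cpp")]]
List silu_fwd_cpp(NumericVector x) {
  NumericVector out(x.size()), s(x.size());
  for (long i = 0; i < (long)x.size(); ++i) {
    const double sg = 1.0 / (1.0 + std::exp(-x[i]));
    s[i] = sg;
    out[i] = x[i] * sg;
  }
  out.attr("dim") = x.attr("dim");
  return List::create(Named("out") = out, Named("s") = s);
}

// [[Rcpp::export(name = ".silu_bwd_cpp")]]
NumericVector silu_bwd_cpp(NumericVector g, NumericVector x, NumericVector s) {
  NumericVector dx(g.size());
  for (long i = 0; i < (long)g.size(); ++i)
    dx[i] = g[i] * (s[i] * (1.0 + x[i] * (1.0 - s[i])));
  dx.attr("dim") = g.attr("dim");
  return dx;
}
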