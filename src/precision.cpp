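// 32-bit float kernels for the single-precision scan path. Inputs arrive as
// double matrices, are truncated to float, and all arithmetic (cross-product
// accumulation and the log10 LOD transform) stays in float before the result
// is widened back to double for R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::fmat to_fmat(const NumericMatrix& X) {
  arma::fmat F(X.nrow(), X.ncol());
  std::copy(X.begin(), X.end(), F.begin());  // narrows double -> float
  return F;
}

// [[Rcpp::export]]
NumericMatrix crossprod_float(const NumericMatrix& A, const NumericMatrix& B) {
  if (A.nrow() != B.nrow())
    stop("crossprod_float: row counts differ");
  arma::fmat Af = to_fmat(A);
  arma::fmat Bf = to_fmat(B);
  arma::fmat Cf = Af.t() * Bf;
  NumericMatrix out(A.ncol(), B.ncol());
  std::copy(Cf.begin(), Cf.end(), out.begin());
  return out;
}

// Ys, Gs: column-standardized (population variance 1) matrices sharing n
// rows. Returns the m x p LOD block -(n/2)*log10(1 - min(r^2, clamp)) with
// r = crossprod/n, computed in float throughout.
// [[Rcpp::export]]
NumericMatrix lod_block_float(const NumericMatrix& Ys, const NumericMatrix& Gs,
                              double r2_clamp) {
  if (Ys.nrow() != Gs.nrow())
    stop("lod_block_float: row counts differ");
  const float n = static_cast<float>(Ys.nrow());
  const float clamp = static_cast<float>(r2_clamp);
  // float cannot represent 1 - 1e-12; cap the clamp below 1 in float
  const float max_clamp = 1.0f - 1e-7f;
  const float cl = clamp < max_clamp ? clamp : max_clamp;
  arma::fmat Yf = to_fmat(Ys);
  arma::fmat Gf = to_fmat(Gs);
  arma::fmat R = (Yf.t() * Gf) / n;
  const float half_n = n / 2.0f;
  R.for_each([&](float& r) {
    float r2 = r * r;
    if (r2 > cl) r2 = cl;
    float lod = -half_n * std::log10(1.0f - r2);
    r = lod > 0.0f ? lod : 0.0f;
  });
  NumericMatrix out(Ys.ncol(), Gs.ncol());
  std::copy(R.begin(), R.end(), out.begin());
  return out;
}
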