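#include <Rcpp.h>
using namespace Rcpp;

// Gather sliding k x k windows of a padded image batch into columns.
// X: (Hp, Wp, C, B) column-major; result: (k*k*C) x (Ho*Wo*B).
// Column order: spatial positions (column-major over Ho x Wo) within image,
// images in batch order.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector X, int Hp, int Wp, int C, int B,
                         int k, int stride) {
  int Ho = (Hp - k) / stride + 1, Wo = (Wp - k) / stride + 1;
  int L = Ho * Wo, kkC = k * k * C;
  NumericMatrix out(kkC, L * B);
  const double* x = X.begin();
  double* o = out.begin();
  size_t img = (size_t)Hp * Wp * C;
  for (int b = 0; b < B; ++b) {
    for (int wc = 0; wc < Wo; ++wc) {
      for (int hc = 0; hc < Ho; ++hc) {
        double* col = o + (size_t)(b * L + wc * Ho + hc) * kkC;
        const double* base = x + (size_t)b * img + (size_t)(wc * stride) * Hp
                               + hc * stride;
        int r = 0;
        for (int c = 0; c < C; ++c)
          for (int j = 0; j < k; ++j) {
            const double* p = base + (size_t)c * Hp * Wp + (size_t)j * Hp;
            for (int i = 0; i < k; ++i) col[r++] = p[i];
          }
      }
    }
  }
  return out;
}

// Scatter-add column gradients back onto the padded image batch
// (adjoint of im2col_cpp).
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dcol, int Hp, int Wp, int C, int B,
                         int k, int stride) {
  int Ho = (Hp - k) / stride + 1, Wo = (Wp - k) / stride + 1;
  int L = Ho * Wo, kkC = k * k * C;
  NumericVector dX((size_t)Hp * Wp * C * B);
  double* x = dX.begin();
  const double* d = dcol.begin();
  size_t img = (size_t)Hp * Wp * C;
  for (int b = 0; b < B; ++b) {
    for (int wc = 0; wc < Wo; ++wc) {
      for (int hc = 0; hc < Ho; ++hc) {
        const double* col = d + (size_t)(b * L + wc * Ho + hc) * kkC;
        double* base = x + (size_t)b * img + (size_t)(wc * stride) * Hp
                         + hc * stride;
        int r = 0;
        for (int c = 0; c < C; ++c)
          for (int j = 0; j < k; ++j) {
            double* p = base + (size_t)c * Hp * Wp + (size_t)j * Hp;
            for (int i = 0; i < k; ++i) p[i] += col[r++];
          }
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(Hp, Wp, C, B);
  return dX;
}
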