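#include <Rcpp.h>
using namespace Rcpp;

// Minimum Euclidean distance from each focal point to the nearest stem of
// each species. Stems are passed as coordinate vectors plus a 1-based
// species index; `skip` gives, per focal, the 1-based index of a stem to
// ignore (the focal itself when conspecifics count as neighbors), or 0.
// Returns an n_focal x n_species matrix; R_PosInf where a species has no
// admissible stem.
// [[Rcpp::export]]
NumericMatrix min_dist_by_species(NumericVector fx, NumericVector fy,
                                  NumericVector sx, NumericVector sy,
                                  IntegerVector sp, int n_sp,
                                  IntegerVector skip) {
  const int nf = fx.size(), ns = sx.size();
  NumericMatrix out(nf, n_sp);
  std::fill(out.begin(), out.end(), R_PosInf);
  for (int i = 0; i < nf; ++i) {
    const double xi = fx[i], yi = fy[i];
    const int sk = skip[i] - 1;
    for (int j = 0; j < ns; ++j) {
      if (j == sk) continue;
      const double dx = sx[j] - xi, dy = sy[j] - yi;
      const double d2 = dx * dx + dy * dy;
      const int s = sp[j] - 1;
      if (d2 < out(i, s)) out(i, s) = d2;
    }
  }
  for (int i = 0; i < nf; ++i)
    for (int s = 0; s < n_sp; ++s)
      if (out(i, s) < R_PosInf) out(i, s) = std::sqrt(out(i, s));
  return out;
}
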