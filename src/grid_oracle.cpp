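#include <Rcpp.h>
using namespace Rcpp;

//' Grid-search distance from a point to the parental line
//'
//' Scans t over `[t_min, t_max]` in steps of `step` and returns the
//' minimum distance between `f` and `pm + t * (pf - pm)`. A numerical
//' oracle for the closed-form perpendicular projection used by
//' [mismatch()]; the squared distance is evaluated as a quadratic in t,
//' which keeps the scan cheap without changing what is minimised.
//'
//' @param f,pm,pf Equal-length numeric vectors: the phenotype and the two
//'   parental means.
//' @param t_min,t_max,step Grid range and resolution along the line.
//' @return Minimum distance over the grid.
//' @export
// [[Rcpp::export]]
double grid_line_distance(NumericVector f, NumericVector pm, NumericVector pf,
                          double t_min = -5.0, double t_max = 6.0,
                          double step = 1e-5) {
  int p = f.size();
  if (pm.size() != p || pf.size() != p)
    stop("grid_line_distance: vectors must have equal length");
  double a = 0.0, b = 0.0, c = 0.0;
  for (int j = 0; j < p; ++j) {
    double d = pf[j] - pm[j];
    double w = f[j] - pm[j];
    a += d * d;
    b += w * d;
    c += w * w;
  }
  long n = (long)std::floor((t_max - t_min) / step + 0.5);
  double best = R_PosInf;
  for (long i = 0; i <= n; ++i) {
    double t = t_min + step * (double)i;
    double d2 = c - 2.0 * t * b + t * t * a;
    if (d2 < best) best = d2;
  }
  if (best < 0.0) best = 0.0;
  return std::sqrt(best);
}
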