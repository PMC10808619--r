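#include <Rcpp.h>
using namespace Rcpp;

// Sigmoid bud growth rate with overflow guard: 1 / (1 + exp(fa * (T - fb))).
static inline double sigmoid_rate(double T, double fa, double fb) {
  double a = fa * (T - fb);
  if (a > 700.0) return 0.0;
  if (a < -700.0) return 1.0;
  return 1.0 / (1.0 + std::exp(a));
}

// Forward phenology prediction for all years of a precomputed forcing
// context. Columns of the matrices are phenology years; rows are days of
// the window (previous-year Dec 1 .. current-year Dec 31), padded to the
// longest window.
//
// family: 1 = tpforc_t, 2 = tpforc_p, 3 = uniforc, 4 = photothermal, 5 = m1
// par:    [thresh, f_a, f_b, F_star, T_base] (unused slots ignored)
// start_idx: 1-based row index per year where the trigger search (TPForc)
//            or the accumulation (comparison models, Jan 1) begins.
//
// Returns predicted day-of-year of the phenology year per year (Dec 31 of
// the previous year = 0), or NA when the trigger never fires or the
// forcing requirement is not met by Dec 31.
// [[Rcpp::export]]
NumericVector forc_predict_cpp(NumericMatrix temp, NumericMatrix dl,
                               IntegerMatrix doy, IntegerVector start_idx,
                               IntegerVector n_days, int family,
                               NumericVector par) {
  int ny = temp.ncol();
  double thresh = par[0], fa = par[1], fb = par[2];
  double fstar = par[3], tbase = par[4];
  NumericVector out(ny, NA_REAL);

  for (int y = 0; y < ny; ++y) {
    int nd = n_days[y];
    int s = start_idx[y] - 1;          // 0-based
    if (s < 0 || s >= nd) continue;

    // trigger search (TPForc families only)
    if (family == 1) {
      while (s < nd && !(temp(s, y) > thresh)) ++s;
      if (s >= nd) continue;
    } else if (family == 2) {
      while (s < nd && !(dl(s, y) > thresh)) ++s;
      if (s >= nd) continue;
    }

    double cum = 0.0;
    for (int d = s; d < nd; ++d) {
      double r;
      switch (family) {
      case 4:
        r = (dl(d, y) / 24.0) * sigmoid_rate(temp(d, y), fa, fb);
        break;
      case 5: {
        double ex = temp(d, y) - tbase;
        r = (dl(d, y) / 10.0) * (ex > 0.0 ? ex : 0.0);
        break;
      }
      default:
        r = sigmoid_rate(temp(d, y), fa, fb);
      }
      cum += r;
      if (cum >= fstar) {
        out[y] = (double)doy(d, y);
        break;
      }
    }
  }
  return out;
}
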