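#include <Rcpp.h>
using namespace Rcpp;

// Hourly recursion of the two-step chill-portion kinetics (precursor
// formation/destruction with deterministic banking when the precursor
// completes).  Temperatures in Kelvin; constants passed in from R so the
// parameterization lives in one versioned table on the R side.
//
// Per hour, given the post-banking precursor pool s:
//   E  = xs - (xs - s) * exp(-ak1)          (formation toward equilibrium xs)
//   if E >= 1: a portion fraction delt = xi * E is banked and the pool
//   resets to E - delt; otherwise the pool carries over unchanged.
// [[Rcpp::export]]
List dynamic_portions_cpp(NumericVector temp_k,
                          double e0, double e1, double a0, double a1,
                          double slp, double tetmlt,
                          double inter0, double portions0,
                          bool cumulative) {
  const int n = temp_k.size();
  double s = inter0;
  double portions = portions0;
  const double aa = a0 / a1;
  const double ee = e1 - e0;
  NumericVector cum(cumulative ? n : 0);

  for (int i = 0; i < n; ++i) {
    const double tk = temp_k[i];
    if (!R_finite(tk)) stop("non-finite temperature at position %d", i + 1);
    const double ftmprt = slp * tetmlt * (tk - tetmlt) / tk;
    const double sr = std::exp(ftmprt);
    const double xi = sr / (1.0 + sr);
    const double xs = aa * std::exp(ee / tk);
    const double ak1 = a1 * std::exp(-e1 / tk);
    double e = xs - (xs - s) * std::exp(-ak1);
    if (e >= 1.0) {
      const double delt = xi * e;
      portions += delt;
      s = e - delt;
    } else {
      s = e;
    }
    if (cumulative) cum[i] = portions;
  }

  return List::create(_["portions"] = portions,
                      _["intermediate"] = s,
                      _["cumulative"] = cum);
}
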