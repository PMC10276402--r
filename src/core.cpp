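#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation of the two-state gene with two transcript
// pools (pre-pulse RNA0, in-pulse RNA1).  Species order: RNA0, RNA1, Gon,
// Goff; rate order: beta0, beta1, delta0, delta1, kon, koff.  Propensities
// follow mass action on the reactant matrix (transcription requires Gon,
// decay acts per molecule, switching on the respective gene state).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector ssa_endpoint_cpp(NumericVector state0, NumericVector rates,
                               double t_end) {
  double rna0 = state0[0], rna1 = state0[1];
  int gon = (int)state0[2], goff = (int)state0[3];
  const double b0 = rates[0], b1 = rates[1], d0 = rates[2], d1 = rates[3],
               kon = rates[4], koff = rates[5];
  double t = 0.0;
  long iter = 0;
  while (true) {
    double a0 = b0 * gon;
    double a1 = b1 * gon;
    double a2 = d0 * rna0;
    double a3 = d1 * rna1;
    double a4 = kon * goff;
    double a5 = koff * gon;
    double atot = a0 + a1 + a2 + a3 + a4 + a5;
    if (atot <= 0.0) break;
    t += R::exp_rand() / atot;
    if (t > t_end) break;
    double u = unif_rand() * atot;
    if (u < a0) {
      rna0 += 1.0;
    } else if (u < a0 + a1) {
      rna1 += 1.0;
    } else if (u < a0 + a1 + a2) {
      rna0 -= 1.0;
    } else if (u < a0 + a1 + a2 + a3) {
      rna1 -= 1.0;
    } else if (u < a0 + a1 + a2 + a3 + a4) {
      gon = 1; goff = 0;
    } else {
      gon = 0; goff = 1;
    }
    if ((++iter & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return NumericVector::create(rna0, rna1, (double)gon, (double)goff);
}

// Approximate non-equilibrium pmf of the newly synthesised transcript
// count n = 0..nmax.  The Gauss hypergeometric factor 2F1(-n, -a, 1-a-n; z)
// with z = (1+b)/(e^tau + b) terminates after n+1 terms because -n is a
// non-positive integer; the terminating sum is evaluated directly with
// magnitude rescaling to dodge double overflow.  Values may legitimately
// come out negative or non-finite in unstable parameter regions; they are
// returned as-is so callers can flag instability.
// [[Rcpp::export]]
NumericVector new_pmf_cpp(int nmax, double a, double b, double tau) {
  NumericVector out(nmax + 1);
  const double et = exp(tau);                 // Inf for huge tau => z = 0
  const double z = R_FINITE(et) ? (1.0 + b) / (et + b) : 0.0;
  const double logodds = log(b / (1.0 + b));
  const double logdecay = a * log((1.0 + b * exp(-tau)) / (1.0 + b));
  const double lga = lgamma(a);
  for (int n = 0; n <= nmax; ++n) {
    double s = 1.0, term = 1.0, logscale = 0.0;
    for (int j = 0; j < n; ++j) {
      term *= ((-(double)n + j) * (-a + j)) /
              ((1.0 - a - (double)n + j) * (j + 1.0)) * z;
      s += term;
      double as = fabs(s), at = fabs(term);
      if (as > 1e250 || at > 1e250) {
        s *= 1e-250; term *= 1e-250;
        logscale += 250.0 * M_LN10;
      }
    }
    double logpre = lgamma(a + n) - lgamma((double)n + 1.0) - lga +
                    n * logodds + logdecay;
    if (s == 0.0) {
      out[n] = 0.0;
    } else {
      double v = exp(logpre + logscale + log(fabs(s)));
      out[n] = (s > 0.0) ? v : -v;
    }
  }
  return out;
}

// For m = 0..M computes the convolution sum_n pn[n]*ps[m-n] (den) and the
// first-moment sum sum_n n*pn[n]*ps[m-n] (num), used to normalise the
// new-given-total distribution and to form the expected new fraction per
// total count.  Direct O(M^2) sums: exact, no FFT roundoff sign flips.
// [[Rcpp::export]]
List conv_weights_cpp(NumericVector pn, NumericVector ps) {
  int M = pn.size() - 1;
  NumericVector num(M + 1), den(M + 1);
  for (int m = 0; m <= M; ++m) {
    double s0 = 0.0, s1 = 0.0;
    for (int n = 0; n <= m; ++n) {
      double w = pn[n] * ps[m - n];
      s0 += w;
      s1 += n * w;
    }
    den[m] = s0;
    num[m] = s1;
  }
  return List::create(_["num"] = num, _["den"] = den);
}
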