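#include <Rcpp.h>
using namespace Rcpp;

// Forward pass of the inheritance-vector HMM over one chromosome.
//
// The emission at a marker depends on the inheritance vector only through the
// descent partition of the typed allele positions, so emissions are stored per
// partition class and looked up per state. Markers with different missingness
// patterns (subsets of typed individuals with a call) use different
// state-to-class maps, hence the per-pattern class matrix.
//
// classprob: nclass_total x nmarker; classprob(c-1, j) is P(observed genotypes
//   at marker j | any state of class c). Class ids are global across patterns.
// cls_by_pattern: ns x npattern; 1-based global class of each state under each
//   missingness pattern.
// pattern: length nmarker, 1-based pattern index per marker.
// theta: length nmarker-1 recombination fractions between adjacent markers.
// nbits: number of modeled meioses; ns must equal 2^nbits.
//
// Transitions factorize per meiosis: each bit flips independently with
// probability theta. Returns the natural-log likelihood under a uniform prior
// over the 2^nbits states; running rescaling guards against underflow.
// [[Rcpp::export]]
double forward_loglik_cpp(NumericMatrix classprob, IntegerMatrix cls_by_pattern,
                          IntegerVector pattern, NumericVector theta, int nbits) {
  const int ns = cls_by_pattern.nrow();
  const int nm = pattern.size();
  if (nm == 0) return 0.0;
  if (ns != (1 << nbits)) stop("state count does not match 2^nbits");

  std::vector<double> v(ns);
  double logsum = 0.0;

  double s = 0.0;
  {
    const int p0 = pattern[0] - 1;
    for (int k = 0; k < ns; ++k) {
      v[k] = classprob(cls_by_pattern(k, p0) - 1, 0);
      s += v[k];
    }
  }
  if (s <= 0.0) return R_NegInf;
  for (int k = 0; k < ns; ++k) v[k] /= s;
  logsum += std::log(s);

  for (int j = 1; j < nm; ++j) {
    const double th = theta[j - 1];
    if (th > 0.0) {
      // per-bit conditional update: v <- (1-th) v + th v[bit flipped]
      for (int b = 0; b < nbits; ++b) {
        const int mask = 1 << b;
        for (int k = 0; k < ns; ++k) {
          if (k & mask) continue;
          const int k2 = k | mask;
          const double a = v[k], c = v[k2];
          v[k] = (1.0 - th) * a + th * c;
          v[k2] = (1.0 - th) * c + th * a;
        }
      }
    }
    const int pj = pattern[j] - 1;
    s = 0.0;
    for (int k = 0; k < ns; ++k) {
      v[k] *= classprob(cls_by_pattern(k, pj) - 1, j);
      s += v[k];
    }
    if (s <= 0.0) return R_NegInf;
    for (int k = 0; k < ns; ++k) v[k] /= s;
    logsum += std::log(s);
  }
  return logsum - std::log((double) ns);
}
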