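#include <Rcpp.h>
using namespace Rcpp;

// Two-state (HOM/HET) forward-backward over allele-depth observations.
//
// Emission at a marker with depth d and alt count a:
//   HOM: eps^a * (1-eps)^(d-a)     HET: 0.5^d
// (the binomial coefficient is common to both states and cancels in the
// posterior).  Zero-depth markers emit likelihood 1 in both states.
// Transition over inter-marker distance d bp:
//   P(switch) = 0.5 * (1 - exp(-2 * tau * d))
// i.e. a two-state Markov chain with switch intensity tau per bp; the
// stationary distribution (1/2, 1/2) is the prior at the first marker.
// Recursions are scaled to avoid underflow.

// [[Rcpp::export]]
List fb_posterior_cpp(IntegerVector alt, IntegerVector depth,
                      NumericVector pos, double eps, double tau) {
  int n = alt.size();
  if (n == 0) stop("no markers");
  NumericMatrix post(n, 2);
  NumericMatrix alpha(n, 2), beta(n, 2);
  NumericVector cvec(n);

  auto emis = [&](int i, int s) -> double {
    int d = depth[i], a = alt[i];
    if (d == 0) return 1.0;
    if (s == 0) { // HOM
      double e = 1.0;
      for (int k = 0; k < a; ++k) e *= eps;
      for (int k = 0; k < d - a; ++k) e *= (1.0 - eps);
      return e;
    }
    return std::pow(0.5, d); // HET
  };

  alpha(0, 0) = 0.5 * emis(0, 0);
  alpha(0, 1) = 0.5 * emis(0, 1);
  double c0 = alpha(0, 0) + alpha(0, 1);
  if (c0 <= 0) stop("zero likelihood at first marker");
  alpha(0, 0) /= c0; alpha(0, 1) /= c0; cvec[0] = c0;

  for (int i = 1; i < n; ++i) {
    double d = pos[i] - pos[i - 1];
    double sw = 0.5 * (1.0 - std::exp(-2.0 * tau * d));
    double st = 1.0 - sw;
    for (int s = 0; s < 2; ++s) {
      double pred = alpha(i - 1, s) * st + alpha(i - 1, 1 - s) * sw;
      alpha(i, s) = pred * emis(i, s);
    }
    double c = alpha(i, 0) + alpha(i, 1);
    if (c <= 0) stop("zero likelihood at marker %d", i + 1);
    alpha(i, 0) /= c; alpha(i, 1) /= c; cvec[i] = c;
  }

  beta(n - 1, 0) = 1.0; beta(n - 1, 1) = 1.0;
  for (int i = n - 2; i >= 0; --i) {
    double d = pos[i + 1] - pos[i];
    double sw = 0.5 * (1.0 - std::exp(-2.0 * tau * d));
    double st = 1.0 - sw;
    for (int s = 0; s < 2; ++s) {
      beta(i, s) = (st * emis(i + 1, s) * beta(i + 1, s) +
                    sw * emis(i + 1, 1 - s) * beta(i + 1, 1 - s)) / cvec[i + 1];
    }
  }

  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double u = alpha(i, 0) * beta(i, 0);
    double v = alpha(i, 1) * beta(i, 1);
    double z = u + v;
    post(i, 0) = u / z;
    post(i, 1) = v / z;
    ll += std::log(cvec[i]);
  }
  return List::create(_["posterior"] = post, _["loglik"] = ll);
}
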