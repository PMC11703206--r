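#include <Rcpp.h>
using namespace Rcpp;

// Shared inner loops for the two-mode enrichment model.
//
// codes: n x m integer matrix of residue indices (1..nrow(beta)); offset x of a
// window of width w = ncol(beta) reads columns x..x+w-1, so the number of
// offsets is noff = m - w + 1. gamma has length noff (all zero for the
// specific mode, which carries no positional bias).

// Log total mode affinity per sequence: log sum_x exp(e_{i,x} + gamma_x),
// accumulated as a log-sum-exp so large |beta| cannot overflow.
// [[Rcpp::export]]
NumericVector pb_mode_logaff(IntegerMatrix codes, NumericMatrix beta,
                             NumericVector gamma) {
  const int n = codes.nrow(), m = codes.ncol(), w = beta.ncol();
  const int noff = m - w + 1;
  if (noff < 1) stop("sequence shorter than window width");
  if (gamma.size() != noff) stop("positional bias length mismatch");
  NumericVector out(n);
  std::vector<double> e(noff);
  for (int i = 0; i < n; ++i) {
    double emax = R_NegInf;
    for (int x = 0; x < noff; ++x) {
      double s = gamma[x];
      for (int p = 0; p < w; ++p) s += beta(codes(i, x + p) - 1, p);
      e[x] = s;
      if (s > emax) emax = s;
    }
    double acc = 0.0;
    for (int x = 0; x < noff; ++x) acc += std::exp(e[x] - emax);
    out[i] = emax + std::log(acc);
  }
  return out;
}

// Direct total mode affinity per sequence: sum_x exp(e_{i,x} + gamma_x).
// Used for reported affinities, where exactness at benign magnitudes matters
// more than overflow protection (the likelihood path uses the log form).
// [[Rcpp::export]]
NumericVector pb_mode_aff(IntegerMatrix codes, NumericMatrix beta,
                          NumericVector gamma) {
  const int n = codes.nrow(), m = codes.ncol(), w = beta.ncol();
  const int noff = m - w + 1;
  if (noff < 1) stop("sequence shorter than window width");
  if (gamma.size() != noff) stop("positional bias length mismatch");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int x = 0; x < noff; ++x) {
      double s = gamma[x];
      for (int p = 0; p < w; ++p) s += beta(codes(i, x + p) - 1, p);
      acc += std::exp(s);
    }
    out[i] = acc;
  }
  return out;
}

// Weighted gradient accumulator. For per-sequence weights w_i and shifts s_i,
// adds w_i * exp(e_{i,x} + gamma_x - s_i) into the beta entries used by
// window (i, x) and into gamma_x. With s_i = log kappa_i - log alpha_mode this
// yields the data log-likelihood gradient for the mode's coefficients.
// [[Rcpp::export]]
List pb_mode_grad(IntegerMatrix codes, NumericMatrix beta, NumericVector gamma,
                  NumericVector wts, NumericVector shift) {
  const int n = codes.nrow(), m = codes.ncol(), w = beta.ncol();
  const int noff = m - w + 1;
  if (noff < 1) stop("sequence shorter than window width");
  if (gamma.size() != noff) stop("positional bias length mismatch");
  if (wts.size() != n || shift.size() != n) stop("weight length mismatch");
  NumericMatrix gbeta(beta.nrow(), w);
  NumericVector ggamma(noff);
  for (int i = 0; i < n; ++i) {
    for (int x = 0; x < noff; ++x) {
      double s = gamma[x] - shift[i];
      for (int p = 0; p < w; ++p) s += beta(codes(i, x + p) - 1, p);
      const double v = wts[i] * std::exp(s);
      ggamma[x] += v;
      for (int p = 0; p < w; ++p) gbeta(codes(i, x + p) - 1, p) += v;
    }
  }
  return List::create(_["beta"] = gbeta, _["gamma"] = ggamma);
}
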