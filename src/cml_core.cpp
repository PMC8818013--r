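#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Log-domain polynomial machinery for the conditional binomial likelihood.
//
// For one unit with linear indices eta_1..eta_T and K trials per period, the
// conditional density of (Y_1,...,Y_T) given S = sum_t Y_t has denominator
//   D(S) = sum_{q in Q} prod_t C(K, q_t) exp(q_t eta_t),
// the coefficient of z^S in prod_t (1 + z e^{eta_t})^K.  All coefficient
// arithmetic is in log space with log-sum-exp so that K*T of several hundred
// stays finite.

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  if (a > b) return a + log1p(std::exp(b - a));
  return b + log1p(std::exp(a - b));
}

// log-coefficients of one factor (1 + z e^{eta})^K: l[q] = lchoose(K,q) + q*eta
static std::vector<double> factor_logcoefs(double eta, int K) {
  std::vector<double> l(K + 1);
  for (int q = 0; q <= K; ++q)
    l[q] = R::lchoose((double)K, (double)q) + q * eta;
  return l;
}

// convolve log-polys a (deg la-1) and b, truncated at degree cap
static std::vector<double> logconv(const std::vector<double>& a,
                                   const std::vector<double>& b,
                                   int cap) {
  int la = a.size(), lb = b.size();
  int lo = std::min(la + lb - 1, cap + 1);
  std::vector<double> out(lo, R_NegInf);
  for (int i = 0; i < la; ++i) {
    if (a[i] == R_NegInf) continue;
    int jmax = std::min(lb - 1, lo - 1 - i);
    for (int j = 0; j <= jmax; ++j)
      out[i + j] = lse2(out[i + j], a[i] + b[j]);
  }
  return out;
}

// log D(S) for one unit
static double logdenom_group(const std::vector<double>& eta, int K, int S) {
  std::vector<double> poly(1, 0.0);
  for (size_t t = 0; t < eta.size(); ++t)
    poly = logconv(poly, factor_logcoefs(eta[t], K), S);
  return poly[S];
}

// [[Rcpp::export]]
double cpp_cond_logdenom(NumericVector eta, int K, int S) {
  std::vector<double> e(eta.begin(), eta.end());
  return logdenom_group(e, K, S);
}

// Conditional moments E(q_t | S) for one unit via prefix/suffix polynomials:
// P(q_t = q | S) proportional to C(K,q) e^{q eta_t} * [prefix_{<t} * suffix_{>t}]_{S-q}
// [[Rcpp::export]]
List cpp_cond_moments(NumericVector eta, int K, int S) {
  int T = eta.size();
  std::vector< std::vector<double> > pre(T + 1), suf(T + 1);
  pre[0] = std::vector<double>(1, 0.0);
  for (int t = 0; t < T; ++t)
    pre[t + 1] = logconv(pre[t], factor_logcoefs(eta[t], K), S);
  suf[T] = std::vector<double>(1, 0.0);
  for (int t = T - 1; t >= 0; --t)
    suf[t] = logconv(factor_logcoefs(eta[t], K), suf[t + 1], S);
  double ld = pre[T][S];
  NumericVector eq(T);
  for (int t = 0; t < T; ++t) {
    const std::vector<double>& a = pre[t];
    const std::vector<double>& b = suf[t + 1];
    double m = 0.0;
    int qmax = std::min(K, S);
    for (int q = 0; q <= qmax; ++q) {
      int d = S - q;  // degree the other periods must supply
      double c = R_NegInf;
      int jlo = std::max(0, d - (int)b.size() + 1);
      int jhi = std::min((int)a.size() - 1, d);
      for (int j = jlo; j <= jhi; ++j)
        c = lse2(c, a[j] + b[d - j]);
      if (c == R_NegInf) continue;
      double lp = R::lchoose((double)K, (double)q) + q * eta[t] + c - ld;
      m += q * std::exp(lp);
    }
    eq[t] = m;
  }
  return List::create(_["logdenom"] = ld, _["eq"] = eq);
}

// One pass over all informative groups: conditional log-likelihood, score,
// and per-group score contributions (for the clustered sandwich).
// starts: 0-based first row of each group; lens: rows per group.
// [[Rcpp::export]]
List cpp_cml_eval(NumericVector eta, NumericMatrix X, IntegerVector starts,
                  IntegerVector lens, IntegerVector Y, int K) {
  int G = starts.size(), p = X.ncol();
  double ll = 0.0;
  NumericVector score(p);
  NumericMatrix scores(G, p);
  for (int g = 0; g < G; ++g) {
    int s0 = starts[g], T = lens[g];
    std::vector<double> e(T);
    int S = 0;
    for (int t = 0; t < T; ++t) { e[t] = eta[s0 + t]; S += Y[s0 + t]; }
    if (S == 0 || S == K * T) continue;  // conditional probability 1
    List mom = cpp_cond_moments(wrap(e), K, S);
    double ld = mom["logdenom"];
    NumericVector eq = mom["eq"];
    for (int t = 0; t < T; ++t) {
      ll += Y[s0 + t] * e[t] +
            R::lchoose((double)K, (double)Y[s0 + t]);
      double r = Y[s0 + t] - eq[t];
      for (int j = 0; j < p; ++j) {
        double c = r * X(s0 + t, j);
        scores(g, j) += c;
        score[j] += c;
      }
    }
    ll -= ld;
  }
  return List::create(_["loglik"] = ll, _["score"] = score,
                      _["scores"] = scores);
}
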