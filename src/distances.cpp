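#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>
#include "sketch_common.h"
using namespace Rcpp;

// [[Rcpp::export]]
double dist_regmatch_cpp(NumericVector a, NumericVector b) {
  const int m = a.size();
  int eq = 0;
  for (int i = 0; i < m; ++i) eq += (a[i] == b[i]);
  return 1.0 - (double)eq / (double)m;
}

// SetSketch LSH estimator with the base-dependent correction.  For registers
// on the geometric grid with base b, the expected fraction D of equal
// registers satisfies (equal-cardinality split, r = 1/b)
//   E[D] = 1 + (2/ln b) * ln(J + (1 - J)(1 + r)/2),
// obtained by summing the joint register CDF over the grid and collapsing the
// geometric sum to its b->1 integral form.  Inverting for J:
//   J = (2 b^((D-1)/2) - 1 - r) / (1 - r).

// [[Rcpp::export]]
double setsketch_lsh_cpp(NumericVector a, NumericVector b, double base) {
  const int m = a.size();
  int eq = 0;
  for (int i = 0; i < m; ++i) eq += (a[i] == b[i]);
  if (eq == m) return 0.0;
  const double D = (double)eq / (double)m;
  const double r = 1.0 / base;
  double J = (2.0 * std::pow(base, (D - 1.0) / 2.0) - 1.0 - r) / (1.0 - r);
  if (J < 0) J = 0;
  if (J > 1) J = 1;
  return 1.0 - J;
}

// Cardinality estimator: from P(K_i <= k) = exp(-n a b^-k) the maximum of the
// per-register likelihood in n gives, to first order in (b - 1),
//   n_hat = m (1 - 1/b) / (ln b * a * sum_i b^-K_i)
// (the b -> 2 limit recovers the classic HyperLogLog raw estimator).

// [[Rcpp::export]]
double setsketch_card_cpp(NumericVector K, double base, double a) {
  const int m = K.size();
  double S = 0;
  for (int i = 0; i < m; ++i) S += std::pow(base, -K[i]);
  return (double)m * (1.0 - 1.0 / base) / (std::log(base) * a * S);
}

// Joint maximum-likelihood estimator over register pairs.  With the union
// decomposed into shared cardinality c and exclusive cardinalities
// alpha = nA - c, beta = nB - c, the joint CDF of a register pair is
//   C(j,k) = exp(-a (c b^-min(j,k) + alpha b^-j + beta b^-k))
// and P(KA=j, KB=k) follows by inclusion-exclusion over the grid cell.
// nA, nB are fixed at their single-sketch estimates and the log-likelihood is
// maximised over c by golden-section search; J = c / (nA + nB - c).

// [[Rcpp::export]]
double setsketch_jmle_cpp(NumericVector Ka, NumericVector Kb, double base, double a) {
  const int m = Ka.size();
  bool same = true;
  for (int i = 0; i < m && same; ++i) same = (Ka[i] == Kb[i]);
  if (same) return 0.0;

  const double na = setsketch_card_cpp(Ka, base, a);
  const double nb = setsketch_card_cpp(Kb, base, a);
  const double cmax = std::min(na, nb);

  std::vector<double> pa0(m), pa1(m), pb0(m), pb1(m);
  for (int i = 0; i < m; ++i) {
    pa0[i] = std::pow(base, -Ka[i]);
    pa1[i] = pa0[i] * base;  // b^-(Ka-1)
    pb0[i] = std::pow(base, -Kb[i]);
    pb1[i] = pb0[i] * base;
  }

  auto loglik = [&](double c) {
    const double alpha = na - c, beta = nb - c;
    double ll = 0;
    for (int i = 0; i < m; ++i) {
      const double j = Ka[i], k = Kb[i];
      // b^-min over the four corners of the grid cell
      double m00 = (j <= k) ? pa0[i] : pb0[i];          // (j,   k)
      double m10 = (j - 1 <= k) ? pa1[i] : pb0[i];      // (j-1, k)
      double m01 = (j <= k - 1) ? pa0[i] : pb1[i];      // (j,   k-1)
      double m11 = (j - 1 <= k - 1) ? pa1[i] : pb1[i];  // (j-1, k-1)
      double C00 = std::exp(-a * (c * m00 + alpha * pa0[i] + beta * pb0[i]));
      double C10 = std::exp(-a * (c * m10 + alpha * pa1[i] + beta * pb0[i]));
      double C01 = std::exp(-a * (c * m01 + alpha * pa0[i] + beta * pb1[i]));
      double C11 = std::exp(-a * (c * m11 + alpha * pa1[i] + beta * pb1[i]));
      double P = C00 - C10 - C01 + C11;
      ll += std::log(P > 1e-300 ? P : 1e-300);
    }
    return ll;
  };

  // golden-section maximisation of the (unimodal) profile likelihood in c
  const double gr = 0.6180339887498949;
  double lo = 0.0, hi = cmax;
  double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
  double f1 = loglik(x1), f2 = loglik(x2);
  for (int it = 0; it < 80; ++it) {
    if (f1 < f2) {
      lo = x1;
      x1 = x2;
      f1 = f2;
      x2 = lo + gr * (hi - lo);
      f2 = loglik(x2);
    } else {
      hi = x2;
      x2 = x1;
      f2 = f1;
      x1 = hi - gr * (hi - lo);
      f1 = loglik(x1);
    }
    if (hi - lo < 1e-9 * (1.0 + cmax)) break;
  }
  double c = (f1 > f2) ? x1 : x2;
  // compare interior optimum against the boundaries
  double l0 = loglik(0.0), lc = loglik(cmax), li = std::max(f1, f2);
  if (l0 >= li && l0 >= lc) c = 0.0;
  else if (lc >= li) c = cmax;
  double J = c / (na + nb - c);
  if (J < 0) J = 0;
  if (J > 1) J = 1;
  return 1.0 - J;
}

// ---------------------------------------------------------------------------
// Exact oracles over k-mer multisets (token arrays sorted ascending).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double j_exact_cpp(NumericVector ta, NumericVector tb) {
  const int na = ta.size(), nb = tb.size();
  int ia = 0, ib = 0, inter = 0, uni = 0;
  while (ia < na && ib < nb) {
    if (ta[ia] == tb[ib]) {
      ++inter;
      ++ia;
      ++ib;
    } else if (ta[ia] < tb[ib]) {
      ++ia;
    } else {
      ++ib;
    }
    ++uni;
  }
  uni += (na - ia) + (nb - ib);
  return uni > 0 ? (double)inter / (double)uni : 0.0;
}

// Probability Jaccard index
//   J_P = sum_{x in A^B} [ sum_y max(wA(y)/wA(x), wB(y)/wB(x)) ]^-1 .
// Rewriting the inner sum with t = wA(x)/wB(x) and sorting the union by
// r_y = wA(y)/wB(y) turns it into two prefix sums plus a binary search,
// O(U log U) instead of O(U^2).

// [[Rcpp::export]]
double jp_exact_cpp(NumericVector ta, IntegerVector ca,
                    NumericVector tb, IntegerVector cb) {
  const int na = ta.size(), nb = tb.size();
  double totA = 0, totB = 0;
  for (int i = 0; i < na; ++i) totA += ca[i];
  for (int i = 0; i < nb; ++i) totB += cb[i];

  struct Item { double wa, wb, r; };
  std::vector<Item> u;
  u.reserve(na + nb);
  std::vector<std::pair<double, double> > inter;  // (wa, wb) of shared tokens
  int ia = 0, ib = 0;
  while (ia < na || ib < nb) {
    double wa = 0, wb = 0;
    if (ia < na && (ib >= nb || ta[ia] <= tb[ib])) wa = ca[ia] / totA;
    if (ib < nb && (ia >= na || tb[ib] <= ta[ia])) wb = cb[ib] / totB;
    if (wa > 0) ++ia;
    if (wb > 0) ++ib;
    double r = (wb > 0) ? wa / wb : std::numeric_limits<double>::infinity();
    u.push_back({wa, wb, r});
    if (wa > 0 && wb > 0) inter.push_back(std::make_pair(wa, wb));
  }
  if (inter.empty()) return 0.0;

  std::sort(u.begin(), u.end(), [](const Item& x, const Item& y) { return x.r < y.r; });
  const int U = (int)u.size();
  // sbPref[i] = sum of wb over sorted[0..i-1]; saSuf[i] = sum of wa over sorted[i..U-1]
  std::vector<double> sbPref(U + 1, 0.0), saSuf(U + 1, 0.0), rs(U);
  for (int i = 0; i < U; ++i) {
    sbPref[i + 1] = sbPref[i] + u[i].wb;
    rs[i] = u[i].r;
  }
  for (int i = U - 1; i >= 0; --i) saSuf[i] = saSuf[i + 1] + u[i].wa;

  double jp = 0.0;
  for (size_t x = 0; x < inter.size(); ++x) {
    const double t = inter[x].first / inter[x].second;
    int idx = (int)(std::lower_bound(rs.begin(), rs.end(), t) - rs.begin());
    const double denom = saSuf[idx] + t * sbPref[idx];
    jp += inter[x].first / denom;
  }
  return jp;
}
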