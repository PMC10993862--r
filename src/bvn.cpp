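#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bivariate standard normal upper-tail probability P(X > dh, Y > dk),
// correlation r. Gauss-Legendre quadrature on the Drezner-Wesolowsky /
// Genz representation; absolute accuracy ~1e-15 away from |r| = 1.

static double phid(double x) { return 0.5 * erfc(-x * M_SQRT1_2); }

static double bvnu(double dh, double dk, double r) {
  static const double w1[] = {0.1713244923791705, 0.3607615730481384,
                              0.4679139345726904};
  static const double x1[] = {-0.9324695142031522, -0.6612093864662647,
                              -0.2386191860831970};
  static const double w2[] = {0.04717533638651177, 0.1069393259953183,
                              0.1600783285433464,  0.2031674267230659,
                              0.2334925365383547,  0.2491470458134029};
  static const double x2[] = {-0.9815606342467191, -0.9041172563704750,
                              -0.7699026741943050, -0.5873179542866171,
                              -0.3678314989981802, -0.1252334085114692};
  static const double w3[] = {0.01761400713915212, 0.04060142980038694,
                              0.06267204833410906, 0.08327674157670475,
                              0.1019301198172404,  0.1181945319615184,
                              0.1316886384491766,  0.1420961093183821,
                              0.1491729864726037,  0.1527533871307259};
  static const double x3[] = {-0.9931285991850949, -0.9639719272779138,
                              -0.9122344282513259, -0.8391169718222188,
                              -0.7463319064601508, -0.6360536807265150,
                              -0.5108670019508271, -0.3737060887154196,
                              -0.2277858511416451, -0.07652652113349733};
  const double *w, *x;
  int ng;
  double ar = std::fabs(r);
  if (ar < 0.3)      { ng = 3;  w = w1; x = x1; }
  else if (ar < 0.75){ ng = 6;  w = w2; x = x2; }
  else               { ng = 10; w = w3; x = x3; }

  double h = dh, k = dk, hk = h * k, bvn = 0.0;
  const double twopi = 2.0 * M_PI;

  if (ar < 0.925) {
    double hs = (h * h + k * k) / 2.0;
    double asr = std::asin(r);
    for (int i = 0; i < ng; i++) {
      for (int is = -1; is <= 1; is += 2) {
        double sn = std::sin(asr * (is * x[i] + 1.0) / 2.0);
        bvn += w[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
      }
    }
    bvn = bvn * asr / (2.0 * twopi) + phid(-h) * phid(-k);
  } else {
    if (r < 0.0) { k = -k; hk = -hk; }
    if (ar < 1.0) {
      double as = (1.0 - r) * (1.0 + r);
      double a = std::sqrt(as);
      double bs = (h - k) * (h - k);
      double c = (4.0 - hk) / 8.0;
      double d = (12.0 - hk) / 16.0;
      double asr = -(bs / as + hk) / 2.0;
      if (asr > -100.0)
        bvn = a * std::exp(asr) *
              (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
               c * d * as * as / 5.0);
      if (-hk < 100.0) {
        double b = std::sqrt(bs);
        bvn -= std::exp(-hk / 2.0) * std::sqrt(twopi) * phid(-b / a) * b *
               (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a /= 2.0;
      for (int i = 0; i < ng; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double xs = a * (is * x[i] + 1.0);
          xs = xs * xs;
          double rs = std::sqrt(1.0 - xs);
          double asr2 = -(bs / xs + hk) / 2.0;
          if (asr2 > -100.0)
            bvn += a * w[i] * std::exp(asr2) *
                   (std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs -
                    (1.0 + c * xs * (1.0 + d * xs)));
        }
      }
      bvn = -bvn / twopi;
    }
    if (r > 0.0) {
      bvn += phid(-std::max(h, k));
    } else {
      bvn = -bvn;
      if (k > h) bvn += phid(k) - phid(h);
    }
  }
  if (bvn < 0.0) bvn = 0.0;
  if (bvn > 1.0) bvn = 1.0;
  return bvn;
}

// P(X <= x, Y <= y), handles +/-Inf limits
static double bvn_cdf1(double x, double y, double r) {
  if (x == R_NegInf || y == R_NegInf) return 0.0;
  if (x == R_PosInf && y == R_PosInf) return 1.0;
  if (x == R_PosInf) return phid(y);
  if (y == R_PosInf) return phid(x);
  return bvnu(-x, -y, r);
}

// [[Rcpp::export]]
NumericVector cpp_bvn_cdf(NumericVector x, NumericVector y, double rho) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = bvn_cdf1(x[i], y[i], rho);
  return out;
}

// Cell probabilities of a two-way table under the bivariate normal model:
// item 1 with thresholds a (K1-1), item 2 with thresholds b (K2-1).
// Returns K1 x K2 matrix of rectangle probabilities.
// [[Rcpp::export]]
NumericMatrix cpp_poly_cell_probs(NumericVector a, NumericVector b,
                                  double rho) {
  int K1 = a.size() + 1, K2 = b.size() + 1;
  std::vector<double> aa(K1 + 1), bb(K2 + 1);
  aa[0] = R_NegInf; aa[K1] = R_PosInf;
  for (int i = 0; i < K1 - 1; i++) aa[i + 1] = a[i];
  bb[0] = R_NegInf; bb[K2] = R_PosInf;
  for (int j = 0; j < K2 - 1; j++) bb[j + 1] = b[j];
  // grid of CDF values
  std::vector<double> F((K1 + 1) * (K2 + 1));
  for (int i = 0; i <= K1; i++)
    for (int j = 0; j <= K2; j++)
      F[i * (K2 + 1) + j] = bvn_cdf1(aa[i], bb[j], rho);
  NumericMatrix P(K1, K2);
  for (int i = 0; i < K1; i++)
    for (int j = 0; j < K2; j++) {
      double p = F[(i + 1) * (K2 + 1) + (j + 1)] - F[i * (K2 + 1) + (j + 1)] -
                 F[(i + 1) * (K2 + 1) + j] + F[i * (K2 + 1) + j];
      P(i, j) = p > 1e-300 ? p : 1e-300;
    }
  return P;
}

// Bivariate normal density at finite grid corners; derivative of the cell
// probability with respect to rho equals the signed sum of densities at the
// four corners (Plackett's identity); infinite corners contribute zero.
static double bvn_pdf1(double x, double y, double r) {
  if (!R_finite(x) || !R_finite(y)) return 0.0;
  double omr2 = 1.0 - r * r;
  return std::exp(-(x * x - 2.0 * r * x * y + y * y) / (2.0 * omr2)) /
         (2.0 * M_PI * std::sqrt(omr2));
}

// [[Rcpp::export]]
NumericMatrix cpp_poly_cell_dprobs(NumericVector a, NumericVector b,
                                   double rho) {
  int K1 = a.size() + 1, K2 = b.size() + 1;
  std::vector<double> aa(K1 + 1), bb(K2 + 1);
  aa[0] = R_NegInf; aa[K1] = R_PosInf;
  for (int i = 0; i < K1 - 1; i++) aa[i + 1] = a[i];
  bb[0] = R_NegInf; bb[K2] = R_PosInf;
  for (int j = 0; j < K2 - 1; j++) bb[j + 1] = b[j];
  std::vector<double> D((K1 + 1) * (K2 + 1));
  for (int i = 0; i <= K1; i++)
    for (int j = 0; j <= K2; j++)
      D[i * (K2 + 1) + j] = bvn_pdf1(aa[i], bb[j], rho);
  NumericMatrix dP(K1, K2);
  for (int i = 0; i < K1; i++)
    for (int j = 0; j < K2; j++)
      dP(i, j) = D[(i + 1) * (K2 + 1) + (j + 1)] - D[i * (K2 + 1) + (j + 1)] -
                 D[(i + 1) * (K2 + 1) + j] + D[i * (K2 + 1) + j];
  return dP;
}

// Log-likelihood of an observed contingency table under the bivariate
// normal model with fixed thresholds.
// [[Rcpp::export]]
double cpp_poly_table_loglik(NumericMatrix counts, NumericVector a,
                             NumericVector b, double rho) {
  NumericMatrix P = cpp_poly_cell_probs(a, b, rho);
  double ll = 0.0;
  for (int i = 0; i < counts.nrow(); i++)
    for (int j = 0; j < counts.ncol(); j++)
      if (counts(i, j) > 0.0) ll += counts(i, j) * std::log(P(i, j));
  return ll;
}
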