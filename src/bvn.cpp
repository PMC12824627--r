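// Bivariate normal orthant probabilities.
//
// C++ translation of Genz's BVND algorithm (Drezner & Wesolowsky quadrature
// for |r| < 0.925, Genz's tail expansion otherwise), double-precision
// accurate to ~1e-15.  Vectorised entry point for the posterior log odds
// ratio computation, which evaluates the orthant integral once per
// (draw, participant, arm).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double TWOPI = 6.283185307179586;

static inline double phid(double x) { return R::pnorm(x, 0.0, 1.0, 1, 0); }

// Gauss-Legendre points/weights, halved symmetric sets as in Genz's TVPACK.
static const double GL_W[3][10] = {
  {0.1713244923791705, 0.3607615730481384, 0.4679139345726904,
   0, 0, 0, 0, 0, 0, 0},
  {0.04717533638651177, 0.1069393259953183, 0.1600783285433464,
   0.2031674267230659, 0.2334925365383547, 0.2491470458134029,
   0, 0, 0, 0},
  {0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
   0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
   0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
   0.1527533871307259}};
static const double GL_X[3][10] = {
  {0.9324695142031522, 0.6612093864662647, 0.2386191860831970,
   0, 0, 0, 0, 0, 0, 0},
  {0.9815606342467191, 0.9041172563704750, 0.7699026741943050,
   0.5873179542866171, 0.3678314989981802, 0.1252334085114692,
   0, 0, 0, 0},
  {0.9931285991850949, 0.9639719272779138, 0.9122344282513259,
   0.8391169718222188, 0.7463319064601508, 0.6360536807265150,
   0.5108670019508271, 0.3737060887154196, 0.2277858511416451,
   0.07652652113349733}};

// P(X > dh, Y > dk) for standard bivariate normal with correlation r.
static double bvnd_upper(double dh, double dk, double r)
{
  int ng, lg;
  double ar = std::fabs(r);
  if (ar < 0.3)       { ng = 0; lg = 3; }
  else if (ar < 0.75) { ng = 1; lg = 6; }
  else                { ng = 2; lg = 10; }

  double h = dh, k = dk;
  double hk = h * k, bvn = 0.0;

  if (ar < 0.925) {
    if (ar > 0.0) {
      double hs = (h * h + k * k) / 2.0;
      double asr = std::asin(r);
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double sn = std::sin(asr * (is * GL_X[ng][i] + 1.0) / 2.0);
          bvn += GL_W[ng][i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
        }
      }
      bvn = bvn * asr / (2.0 * TWOPI);
    }
    bvn += phid(-h) * phid(-k);
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
        double sp = std::sqrt(TWOPI) * phid(-b / a);
        bvn -= std::exp(-hk / 2.0) * sp * b *
               (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a = a / 2.0;
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double xs = a * (is * GL_X[ng][i] + 1.0);
          xs = xs * xs;
          double rs = std::sqrt(1.0 - xs);
          double asr2 = -(bs / xs + hk) / 2.0;
          if (asr2 > -100.0) {
            double sp = 1.0 + c * xs * (1.0 + d * xs);
            double ep = std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs;
            bvn += a * GL_W[ng][i] * std::exp(asr2) * (ep - sp);
          }
        }
      }
      bvn = -bvn / TWOPI;
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

//' Upper-orthant probability of the standard bivariate normal
//'
//' Computes \eqn{P(X > h, Y > k)} for a standard bivariate normal vector
//' \eqn{(X, Y)} with correlation \code{rho}, by Genz's quadrature/expansion
//' algorithm. All three arguments are recycled to a common length.
//'
//' @param h,k Numeric vectors of lower bounds (probability of exceeding).
//' @param rho Numeric vector of correlations, each in (-1, 1).
//' @return Numeric vector of probabilities.
//' @examples
//' pbvn_upper(0, 0, 0)            # 0.25
//' pbvn_upper(0, 0, 0.5)          # 1/4 + asin(0.5)/(2*pi) = 1/3
//' @export
// [[Rcpp::export]]
NumericVector pbvn_upper(NumericVector h, NumericVector k, NumericVector rho)
{
  R_xlen_t n = std::max(h.size(), std::max(k.size(), rho.size()));
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    double r = rho[i % rho.size()];
    if (!(r > -1.0 && r < 1.0))
      stop("correlation must lie strictly inside (-1, 1)");
    out[i] = bvnd_upper(h[i % h.size()], k[i % k.size()], r);
  }
  return out;
}

// Per-draw subtrial log odds ratio for the latent-variable model.
//
// For each posterior draw (rows of the parameter vectors) and each
// participant covariate value lx[j], evaluates the counterfactual responder
// probabilities under t=1 and t=0 and aggregates the individual log odds
// ratios (mean or sum over participants).
// [[Rcpp::export]]
NumericVector lor_abba_cpp(NumericVector b1, NumericVector b2,
                           NumericVector g1, NumericVector g2,
                           NumericVector t1, NumericVector t2,
                           NumericVector sigma1, NumericVector rho,
                           NumericVector lx, double threshold, bool mean_agg)
{
  R_xlen_t nd = b1.size(), np = lx.size();
  NumericVector out(nd);
  for (R_xlen_t d = 0; d < nd; d++) {
    double s1 = sigma1[d], r = rho[d];
    double acc = 0.0;
    for (R_xlen_t j = 0; j < np; j++) {
      double m1c = b1[d] + g1[d] * lx[j];
      double m2c = b2[d] + g2[d] * lx[j];
      double rt = bvnd_upper((threshold - m1c - t1[d]) / s1, -(m2c + t2[d]), r);
      double rc = bvnd_upper((threshold - m1c) / s1, -m2c, r);
      acc += (R::qlogis(rt, 0, 1, 1, 0) - R::qlogis(rc, 0, 1, 1, 0));
    }
    out[d] = mean_agg ? acc / np : acc;
  }
  return out;
}
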