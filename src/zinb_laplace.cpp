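#include <Rcpp.h>
using namespace Rcpp;

// Zero-inflated negative binomial (NB2) per-stay log-likelihood and its
// derivatives with respect to the hospital random intercepts, plus the
// per-hospital Laplace approximation of the marginal likelihood.
//
// Mixture: P(Y=0) = pi + (1-pi) * p0,  P(Y=y>0) = (1-pi) * NB2(y; mu, theta)
// with pi = plogis(eta_z + b_z), mu = exp(eta_c + b_c) (eta_c includes the
// log-DP offset), p0 = (theta/(theta+mu))^theta.

static inline double log1p_exp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// log-likelihood of one stay
static inline double stay_ll(double y, double etac, double etaz, double theta) {
  double log_pi = -log1p_exp_(-etaz);        // log plogis(etaz)
  double log_1mpi = -log1p_exp_(etaz);
  double mu = std::exp(etac);
  double log_p0 = theta * (std::log(theta) - std::log(theta + mu));
  if (y > 0.0) {
    double ll_nb = R::lgammafn(y + theta) - R::lgammafn(theta) -
                   R::lgammafn(y + 1.0) + log_p0 +
                   y * (etac - std::log(theta + mu));
    return log_1mpi + ll_nb;
  }
  // log(pi + (1-pi) p0), stable via log-sum-exp
  double a = log_pi, b = log_1mpi + log_p0;
  double m = std::max(a, b);
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// derivatives of one stay's ll wrt (b_c, b_z)
static inline void stay_grad(double y, double etac, double etaz, double theta,
                             double &gc, double &gz) {
  double pi = 1.0 / (1.0 + std::exp(-etaz));
  double mu = std::exp(etac);
  if (y > 0.0) {
    gz = -pi;
    gc = y - (y + theta) * mu / (theta + mu);
  } else {
    double log_p0 = theta * (std::log(theta) - std::log(theta + mu));
    double p0 = std::exp(log_p0);
    double D = pi + (1.0 - pi) * p0;
    gz = pi * (1.0 - pi) * (1.0 - p0) / D;
    gc = -(1.0 - pi) * p0 * theta * mu / (theta + mu) / D;
  }
}

// [[Rcpp::export]]
double cpp_zinb_negll(NumericVector y, NumericVector etac, NumericVector etaz,
                      double theta) {
  double s = 0.0;
  for (int i = 0; i < y.size(); ++i)
    s += stay_ll(y[i], etac[i], etaz[i], theta);
  if (!std::isfinite(s)) return 1e10;
  return -s;
}

struct HospData {
  const double *y, *etac, *etaz;
  int n;
  double theta, s2c, s2z;
};

static double joint_logpost(const HospData &d, double bc, double bz) {
  double s = 0.0;
  for (int i = 0; i < d.n; ++i)
    s += stay_ll(d.y[i], d.etac[i] + bc, d.etaz[i] + bz, d.theta);
  s += -0.5 * std::log(2.0 * M_PI * d.s2c) - bc * bc / (2.0 * d.s2c);
  s += -0.5 * std::log(2.0 * M_PI * d.s2z) - bz * bz / (2.0 * d.s2z);
  return s;
}

static void joint_grad(const HospData &d, double bc, double bz,
                       double &gc, double &gz) {
  gc = 0.0; gz = 0.0;
  for (int i = 0; i < d.n; ++i) {
    double gci, gzi;
    stay_grad(d.y[i], d.etac[i] + bc, d.etaz[i] + bz, d.theta, gci, gzi);
    gc += gci; gz += gzi;
  }
  gc -= bc / d.s2c;
  gz -= bz / d.s2z;
}

// numerical Hessian (central differences of the analytic gradient)
static void joint_hess(const HospData &d, double bc, double bz, double H[4]) {
  const double h = 1e-5;
  double gcp, gzp, gcm, gzm;
  joint_grad(d, bc + h, bz, gcp, gzp);
  joint_grad(d, bc - h, bz, gcm, gzm);
  H[0] = (gcp - gcm) / (2 * h);          // d2/dbc2
  double Hcz1 = (gzp - gzm) / (2 * h);   // d2/dbz dbc
  joint_grad(d, bc, bz + h, gcp, gzp);
  joint_grad(d, bc, bz - h, gcm, gzm);
  H[3] = (gzp - gzm) / (2 * h);          // d2/dbz2
  double Hcz2 = (gcp - gcm) / (2 * h);
  H[1] = H[2] = 0.5 * (Hcz1 + Hcz2);
}

// Newton ascent to the posterior mode of one hospital's intercept pair.
// Returns the Laplace-approximated log marginal likelihood contribution and
// leaves the mode and the negative Hessian determinant in the out-args.
static double hospital_laplace(const HospData &d, double &bc, double &bz,
                               double &logdet_negH) {
  double f = joint_logpost(d, bc, bz);
  if (!std::isfinite(f)) { bc = 0.0; bz = 0.0; f = joint_logpost(d, bc, bz); }
  for (int it = 0; it < 100; ++it) {
    double gc, gz;
    joint_grad(d, bc, bz, gc, gz);
    double gnorm = std::max(std::fabs(gc), std::fabs(gz));
    if (gnorm < 1e-8 * (1.0 + std::fabs(f))) break;
    double H[4];
    joint_hess(d, bc, bz, H);
    // negative Hessian, ridged to PD if needed
    double a = -H[0], b = -H[1], c = -H[3];
    double det = a * c - b * b;
    if (a <= 0.0 || det <= 0.0) {
      double ridge = 1e-4 + std::max(0.0, -std::min(a, c));
      a += ridge; c += ridge;
      det = a * c - b * b;
      if (det <= 0.0) { a += std::fabs(b); c += std::fabs(b); det = a * c - b * b; }
    }
    // Newton step: solve [a b; b c] s = g
    double sc = (c * gc - b * gz) / det;
    double sz = (a * gz - b * gc) / det;
    double step = 1.0;
    bool moved = false;
    for (int ls = 0; ls < 30; ++ls) {
      double nbc = bc + step * sc, nbz = bz + step * sz;
      double nf = joint_logpost(d, nbc, nbz);
      if (std::isfinite(nf) && nf >= f - 1e-12) {
        bc = nbc; bz = nbz;
        moved = (nf > f + 1e-12);
        f = nf;
        break;
      }
      step *= 0.5;
    }
    if (!moved && step < 1.0) break;
  }
  double H[4];
  joint_hess(d, bc, bz, H);
  double a = -H[0], b = -H[1], c = -H[3];
  double det = a * c - b * b;
  if (det <= 0.0 || a <= 0.0) {  // fall back to prior curvature
    a = std::max(a, 1.0 / d.s2c);
    c = std::max(c, 1.0 / d.s2z);
    b = 0.0;
    det = a * c;
  }
  logdet_negH = std::log(det);
  return f + std::log(2.0 * M_PI) - 0.5 * logdet_negH;
}

// Marginal negative log-likelihood via per-hospital Laplace approximation.
// hosp_start: 0-based start indices per hospital plus total n at the end;
// stays must be sorted by hospital.  warm (nh x 2) holds warm-start modes
// and is updated in place.
// [[Rcpp::export]]
List cpp_laplace_marginal(NumericVector y, NumericVector etac,
                          NumericVector etaz, double theta,
                          double s2c, double s2z,
                          IntegerVector hosp_start, NumericMatrix warm) {
  int nh = hosp_start.size() - 1;
  NumericVector ll_h(nh), logdet(nh);
  NumericMatrix modes(nh, 2);
  double total = 0.0;
  for (int h = 0; h < nh; ++h) {
    int s = hosp_start[h], e = hosp_start[h + 1];
    HospData d;
    d.y = &y[s]; d.etac = &etac[s]; d.etaz = &etaz[s];
    d.n = e - s; d.theta = theta; d.s2c = s2c; d.s2z = s2z;
    double bc = warm(h, 0), bz = warm(h, 1), ld;
    double ll = hospital_laplace(d, bc, bz, ld);
    warm(h, 0) = bc; warm(h, 1) = bz;
    modes(h, 0) = bc; modes(h, 1) = bz;
    ll_h[h] = ll; logdet[h] = ld;
    total += ll;
  }
  if (!std::isfinite(total)) total = -1e10;
  return List::create(_["nll"] = -total, _["ll_by_hospital"] = ll_h,
                      _["modes"] = modes, _["logdet_negH"] = logdet);
}
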