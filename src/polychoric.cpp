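#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Bivariate standard normal CDF and the polychoric cell log-likelihood.
// Phi2 uses the correlation-integral identity
//   Phi2(h, k, rho) = Phi(h) Phi(k)
//     + (1/2pi) int_0^rho exp(-(h^2 + k^2 - 2 t h k) / (2 (1 - t^2))) / sqrt(1 - t^2) dt
// evaluated by fixed 48-node Gauss-Legendre quadrature on [0, rho].

static const int GL_N = 48;
static double gl_x[GL_N];  // nodes on (-1, 1)
static double gl_w[GL_N];
static bool gl_ready = false;

// Newton iteration on Legendre polynomials; nodes are symmetric.
static void gl_init() {
  if (gl_ready) return;
  const int n = GL_N;
  for (int i = 0; i < (n + 1) / 2; ++i) {
    double x = std::cos(M_PI * (i + 0.75) / (n + 0.5));
    double pp = 0.0;
    for (int it = 0; it < 100; ++it) {
      double p0 = 1.0, p1 = x;
      for (int k = 2; k <= n; ++k) {
        double p2 = ((2.0 * k - 1.0) * x * p1 - (k - 1.0) * p0) / k;
        p0 = p1; p1 = p2;
      }
      pp = n * (x * p1 - p0) / (x * x - 1.0);
      double dx = p1 / pp;
      x -= dx;
      if (std::fabs(dx) < 1e-15) break;
    }
    gl_x[i] = -x;
    gl_x[n - 1 - i] = x;
    gl_w[i] = gl_w[n - 1 - i] = 2.0 / ((1.0 - x * x) * pp * pp);
  }
  gl_ready = true;
}

static inline double phi1(double x) { return R::pnorm(x, 0.0, 1.0, 1, 0); }

// [[Rcpp::export]]
double phi2_cpp(double h, double k, double rho) {
  if (!R_FINITE(h) && h > 0) return phi1(k);   // h = +Inf
  if (!R_FINITE(k) && k > 0) return phi1(h);
  if (!R_FINITE(h) || !R_FINITE(k)) {
    if ((!R_FINITE(h) && h < 0) || (!R_FINITE(k) && k < 0)) return 0.0;
  }
  if (rho > 0.9999) rho = 0.9999;
  if (rho < -0.9999) rho = -0.9999;
  gl_init();
  double acc = 0.0;
  const double half = 0.5 * rho;
  for (int i = 0; i < GL_N; ++i) {
    double t = half * (gl_x[i] + 1.0);           // map (-1,1) -> (0, rho)
    double omt2 = 1.0 - t * t;
    double e = std::exp(-(h * h + k * k - 2.0 * t * h * k) / (2.0 * omt2));
    acc += gl_w[i] * e / std::sqrt(omt2);
  }
  acc *= half / (2.0 * M_PI);
  double v = phi1(h) * phi1(k) + acc;
  if (v < 0.0) v = 0.0;
  if (v > 1.0) v = 1.0;
  return v;
}

// Log-likelihood of a two-way ordinal contingency table under the latent
// bivariate-normal model with fixed marginal thresholds and correlation rho.
// tau_r, tau_c are the *interior* thresholds (length = ncat - 1, increasing).
// [[Rcpp::export]]
double polychoric_loglik_cpp(const arma::mat& counts,
                             const arma::vec& tau_r, const arma::vec& tau_c,
                             double rho) {
  const arma::uword R = counts.n_rows, C = counts.n_cols;
  // grid of Phi2 at threshold crossings, with -Inf/+Inf borders
  arma::mat G(R + 1, C + 1);
  for (arma::uword i = 0; i <= R; ++i) {
    double a = (i == 0) ? -INFINITY : (i == R ? INFINITY : tau_r(i - 1));
    for (arma::uword j = 0; j <= C; ++j) {
      double b = (j == 0) ? -INFINITY : (j == C ? INFINITY : tau_c(j - 1));
      if (i == 0 || j == 0) G(i, j) = 0.0;
      else G(i, j) = phi2_cpp(a, b, rho);
    }
  }
  // border rows/cols: Phi2(-Inf, .) = 0 handled above; recompute top/left edges
  for (arma::uword i = 1; i <= R; ++i) {
    double a = (i == R) ? INFINITY : tau_r(i - 1);
    G(i, 0) = 0.0;
    (void)a;
  }
  double ll = 0.0;
  for (arma::uword i = 0; i < R; ++i) {
    for (arma::uword j = 0; j < C; ++j) {
      double n = counts(i, j);
      if (n <= 0) continue;
      double pr = G(i + 1, j + 1) - G(i, j + 1) - G(i + 1, j) + G(i, j);
      if (pr < 1e-12) pr = 1e-12;
      ll += n * std::log(pr);
    }
  }
  return ll;
}
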