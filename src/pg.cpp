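// Polya-Gamma PG(1, z) sampling (Devroye-type exact rejection sampler on the
// tilted Jacobi distribution) and the Gibbs sweep for Bayesian logistic
// regression under PG data augmentation. All randomness comes from R's RNG so
// results are reproducible under set.seed().

#include <RcppArmadillo.h>
using namespace Rcpp;

static const double PG_TRUNC = 0.64; // series crossover point t

// n-th alternating-series coefficient a_n(x) of the Jacobi density
static double pg_acoef(int n, double x) {
  double nph = n + 0.5;
  if (x > PG_TRUNC) {
    return M_PI * nph * std::exp(-nph * nph * M_PI * M_PI * x / 2.0);
  }
  return M_PI * nph * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * nph * nph / x);
}

// CDF of inverse-Gaussian with mean 1/z, shape 1, parameterized by z >= 0
static double pg_pigauss(double x, double z) {
  double rx = std::sqrt(1.0 / x);
  double b = rx * (x * z - 1.0);
  double a = rx * (x * z + 1.0);
  return R::pnorm(b, 0.0, 1.0, 1, 0) +
         std::exp(2.0 * z) * R::pnorm(-a, 0.0, 1.0, 1, 0);
}

// draw from IG(1/z, 1) truncated to (0, t]; z may be 0
static double pg_rtigauss(double z, double t) {
  double X;
  double mu = (z > 0.0) ? 1.0 / z : R_PosInf;
  if (mu > t) {
    // sample truncated inverse chi-square (z = 0 proposal), thin by exp tilt
    for (;;) {
      double E1 = R::exp_rand(), E2 = R::exp_rand();
      while (E1 * E1 > 2.0 * E2 / t) {
        E1 = R::exp_rand();
        E2 = R::exp_rand();
      }
      X = t / ((1.0 + t * E1) * (1.0 + t * E1));
      if (R::unif_rand() <= std::exp(-0.5 * z * z * X)) break;
    }
  } else {
    // standard IG(mu, 1) sampler, repeat until within truncation
    for (;;) {
      double Y = R::norm_rand();
      Y = Y * Y;
      double muY = mu * Y;
      X = mu + 0.5 * mu * muY - 0.5 * mu * std::sqrt(4.0 * muY + muY * muY);
      if (R::unif_rand() > mu / (mu + X)) X = mu * mu / X;
      if (X <= t) break;
    }
  }
  return X;
}

// one PG(1, z) draw
double pg_draw1(double z_in) {
  double z = std::fabs(z_in) * 0.5;
  double K = M_PI * M_PI / 8.0 + z * z / 2.0;
  double p = (M_PI / (2.0 * K)) * std::exp(-K * PG_TRUNC);
  double q = 2.0 * std::exp(-z) * pg_pigauss(PG_TRUNC, z);
  for (;;) {
    double X;
    if (R::unif_rand() < p / (p + q)) {
      X = PG_TRUNC + R::exp_rand() / K;
    } else {
      X = pg_rtigauss(z, PG_TRUNC);
    }
    // squeeze accept/reject on the alternating series
    double S = pg_acoef(0, X);
    double Y = R::unif_rand() * S;
    int n = 0;
    bool accept = false, done = false;
    while (!done) {
      ++n;
      if (n % 2 == 1) {
        S -= pg_acoef(n, X);
        if (Y <= S) { accept = true; done = true; }
      } else {
        S += pg_acoef(n, X);
        if (Y > S) done = true;
      }
    }
    if (accept) return X / 4.0;
  }
}

//' @noRd
// [[Rcpp::export(name = "cpp_rpolyagamma")]]
NumericVector cpp_rpolyagamma(int n, NumericVector z) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pg_draw1(z[i % z.size()]);
  return out;
}

// Gibbs sweep(s) for logistic regression: y_i ~ Bern(logistic(x_i' alpha)),
// alpha ~ N(b, diag(1/prior_prec)). Returns n_iter draws (rows).
// [[Rcpp::export(name = "cpp_logistic_gibbs")]]
arma::mat cpp_logistic_gibbs(const arma::mat& X, const arma::vec& y,
                             const arma::vec& b, const arma::vec& prior_prec,
                             int n_iter, arma::vec alpha) {
  const int N = X.n_rows, d = X.n_cols;
  arma::vec kappa = y - 0.5;
  arma::vec rhs0 = X.t() * kappa + prior_prec % b;
  arma::mat out(n_iter, d);
  arma::vec om(N);
  for (int it = 0; it < n_iter; ++it) {
    arma::vec psi = X * alpha;
    for (int i = 0; i < N; ++i) om[i] = pg_draw1(psi[i]);
    arma::mat P = X.t() * (X.each_col() % om);
    P.diag() += prior_prec;
    arma::mat L = arma::chol(P, "lower");
    arma::vec mu = arma::solve(arma::trimatu(L.t()),
                               arma::solve(arma::trimatl(L), rhs0));
    arma::vec zr(d);
    for (int j = 0; j < d; ++j) zr[j] = R::norm_rand();
    alpha = mu + arma::solve(arma::trimatu(L.t()), zr);
    out.row(it) = alpha.t();
  }
  return out;
}
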