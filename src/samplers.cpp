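// MCMC engines for the two imputation-model fits. Both mirror the package's
// R reference implementations call-for-call in their use of the R RNG, so a
// seeded run produces identical draws from either engine.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double P_EPS = 1e-16;

// Inverse-Wishart draw via Bartlett decomposition; scalar draw order
// (diagonal chi-square, then sub-diagonal normals, column-major) matches
// riwish_bartlett() in R.
static arma::mat riwish_bartlett_cpp(double df, const arma::mat& S) {
  const int p = S.n_cols;
  arma::mat V = arma::inv_sympd(arma::symmatu(S));
  arma::mat Lv = arma::chol(arma::symmatu(V), "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int j = 0; j < p; ++j) {
    A(j, j) = std::sqrt(R::rchisq(df - j));
    for (int i = j + 1; i < p; ++i) A(i, j) = norm_rand();
  }
  arma::mat LA = Lv * A;
  arma::mat W = LA * LA.t();
  return arma::symmatu(arma::inv_sympd(arma::symmatu(W)));
}

// Data-augmentation chain for the continuous-scale multivariate normal fit
// (Jeffreys prior). y has NaN for missing entries; d gives each row's count
// of leading observed visits (monotone missingness).
// [[Rcpp::export]]
List cpp_da_mvn(const arma::mat& y_in, const arma::ivec& d, int burn_in,
                int thin, int n_draws, const arma::vec& mu0,
                const arma::mat& sigma0) {
  arma::mat y = y_in;
  const int n = y.n_rows, p = y.n_cols;
  arma::vec mu = mu0;
  arma::mat sigma = sigma0;

  // group rows by deviation time, ascending
  std::map<int, std::vector<int> > groups;
  for (int i = 0; i < n; ++i) groups[d(i)].push_back(i);

  arma::mat mu_draws(n_draws, p);
  List sigma_draws(n_draws);
  int got = 0;
  const int total = burn_in + (n_draws - 1) * thin + 1;

  for (int t = 1; t <= total; ++t) {
    // I-step
    for (std::map<int, std::vector<int> >::iterator it = groups.begin();
         it != groups.end(); ++it) {
      const int dd = it->first;
      if (dd >= p) continue;
      const std::vector<int>& idx = it->second;
      arma::uvec o(dd), m(p - dd);
      for (int j = 0; j < dd; ++j) o(j) = j;
      for (int j = dd; j < p; ++j) m(j - dd) = j;
      arma::mat Soo = sigma.submat(o, o);
      arma::mat Som = sigma.submat(o, m);
      arma::mat B = arma::solve(Soo, Som);
      arma::mat Cm = arma::symmatu(sigma.submat(m, m) - Som.t() * B);
      arma::mat L = arma::chol(Cm, "lower");
      for (size_t r = 0; r < idx.size(); ++r) {
        const int i = idx[r];
        arma::vec yo = y.row(i).cols(0, dd - 1).t();
        arma::vec cm = mu.elem(m) + B.t() * (yo - mu.elem(o));
        arma::vec eps(p - dd);
        for (int j = 0; j < p - dd; ++j) eps(j) = norm_rand();
        arma::vec draw = cm + L * eps;
        for (int j = 0; j < p - dd; ++j) y(i, m(j)) = draw(j);
      }
    }
    // P-step
    arma::rowvec ybar = arma::mean(y, 0);
    arma::mat yc = y.each_row() - ybar;
    arma::mat S = yc.t() * yc;
    sigma = riwish_bartlett_cpp(n - 1.0, S);
    arma::vec eps(p);
    for (int j = 0; j < p; ++j) eps(j) = norm_rand();
    mu = ybar.t() + arma::chol(sigma, "lower") * eps / std::sqrt((double)n);

    if (t > burn_in && (t - burn_in - 1) % thin == 0 && got < n_draws) {
      mu_draws.row(got) = mu.t();
      sigma_draws[got] = wrap(sigma);
      ++got;
    }
  }
  return List::create(_["mu"] = mu_draws, _["sigma"] = sigma_draws);
}

// One truncated-normal draw by inverse CDF, with the uniform supplied.
static double trunc_draw(double cm, double s, int yval, double u) {
  double plo = 0.0, phi = 1.0;
  if (yval == 0) {               // z > 0
    plo = R::pnorm(-cm / s, 0.0, 1.0, 1, 0);
  } else if (yval == 1) {        // z <= 0
    phi = R::pnorm(-cm / s, 0.0, 1.0, 1, 0);
  }
  double q = plo + u * (phi - plo);
  if (q < P_EPS) q = P_EPS;
  if (q > 1.0 - P_EPS) q = 1.0 - P_EPS;
  return cm + s * R::qnorm(q, 0.0, 1.0, 1, 0);
}

// Latent-normal (multivariate probit) Gibbs sampler for one arm.
// y: 0/1 with NA_INTEGER for missing. Means have a flat prior; the
// correlation matrix (unit diagonal) has a flat prior on the positive-
// definite region and is updated element-wise by random-walk Metropolis.
// [[Rcpp::export]]
List cpp_latent_gibbs(const IntegerMatrix& y, int burn_in, int thin,
                      int n_draws, double prop_sd, bool adapt) {
  const int n = y.nrow(), p = y.ncol();
  arma::mat z(n, p, arma::fill::zeros);
  arma::vec mu(p, arma::fill::zeros);
  arma::mat Om = arma::eye(p, p);
  arma::mat sd(p, p); sd.fill(prop_sd);
  arma::mat acc_win(p, p, arma::fill::zeros), att_win(p, p, arma::fill::zeros);
  arma::mat acc_post(p, p, arma::fill::zeros), att_post(p, p, arma::fill::zeros);

  arma::mat mu_draws(n_draws, p);
  List om_draws(n_draws);
  int got = 0;
  const int total = burn_in + (n_draws - 1) * thin + 1;

  for (int t = 1; t <= total; ++t) {
    // refresh latent values from their full conditionals, truncated to the
    // sign-consistent region when the binary outcome is observed
    for (int j = 0; j < p; ++j) {
      arma::uvec rest(p - 1);
      for (int kk = 0, c = 0; kk < p; ++kk) if (kk != j) rest(c++) = kk;
      arma::uvec jv(1); jv(0) = j;
      arma::vec w(p - 1, arma::fill::zeros);
      double v = 1.0;
      if (p > 1) {
        w = arma::solve(Om.submat(rest, rest), Om.submat(rest, jv));
        v = 1.0 - arma::dot(Om.submat(jv, rest), w);
      }
      if (v < 1e-12) v = 1e-12;
      const double s = std::sqrt(v);
      for (int i = 0; i < n; ++i) {
        double cm = mu(j);
        for (int kk = 0; kk < p - 1; ++kk) cm += w(kk) * (z(i, rest(kk)) - mu(rest(kk)));
        const double u = unif_rand();
        const int yv = y(i, j) == NA_INTEGER ? -1 : y(i, j);
        z(i, j) = trunc_draw(cm, s, yv, u);
      }
    }
    // mean update: flat prior => N(zbar, Om / n)
    arma::rowvec zbar = arma::mean(z, 0);
    arma::vec eps(p);
    for (int j = 0; j < p; ++j) eps(j) = norm_rand();
    mu = zbar.t() + arma::chol(Om, "lower") * eps / std::sqrt((double)n);

    arma::mat zc = z.each_row() - mu.t();
    arma::mat S = zc.t() * zc;

    // element-wise Metropolis on the off-diagonal correlations
    double logdet, sign;
    arma::log_det(logdet, sign, Om);
    arma::mat Oinv = arma::inv_sympd(arma::symmatu(Om));
    for (int k = 1; k < p; ++k) {
      for (int j = 0; j < k; ++j) {
        att_win(j, k) += 1; if (t > burn_in) att_post(j, k) += 1;
        const double step = norm_rand() * sd(j, k);
        const double rp = Om(j, k) + step;
        if (std::fabs(rp) >= 0.9999) continue;       // reject, no uniform used
        arma::mat Omp = Om;
        Omp(j, k) = Omp(k, j) = rp;
        arma::mat R_;
        if (!arma::chol(R_, arma::symmatu(Omp))) continue;   // non-PD: reject
        double logdet_p = 2.0 * arma::sum(arma::log(R_.diag()));
        arma::mat Oinv_p = arma::inv_sympd(arma::symmatu(Omp));
        const double delta = -0.5 * n * (logdet_p - logdet)
          - 0.5 * (arma::accu(Oinv_p % S) - arma::accu(Oinv % S));
        const double u = unif_rand();
        if (std::log(u) < delta) {
          Om = Omp; logdet = logdet_p; Oinv = Oinv_p;
          acc_win(j, k) += 1; if (t > burn_in) acc_post(j, k) += 1;
        }
      }
    }
    // deterministic proposal-scale adaptation during burn-in only
    if (adapt && t <= burn_in && t % 50 == 0) {
      for (int k = 1; k < p; ++k) {
        for (int j = 0; j < k; ++j) {
          const double rate = att_win(j, k) > 0 ? acc_win(j, k) / att_win(j, k) : 0.0;
          if (rate > 0.5) sd(j, k) *= 1.25;
          else if (rate < 0.35) sd(j, k) *= 0.8;
        }
      }
      acc_win.zeros(); att_win.zeros();
    }

    if (t > burn_in && (t - burn_in - 1) % thin == 0 && got < n_draws) {
      mu_draws.row(got) = mu.t();
      om_draws[got] = wrap(arma::symmatu(Om));
      ++got;
    }
  }
  arma::mat acc_rate(p, p, arma::fill::zeros);
  for (int k = 1; k < p; ++k)
    for (int j = 0; j < k; ++j)
      if (att_post(j, k) > 0) acc_rate(j, k) = acc_rate(k, j) = acc_post(j, k) / att_post(j, k);
  return List::create(_["mu"] = mu_draws, _["omega"] = om_draws,
                      _["accept_rate"] = acc_rate, _["prop_sd"] = sd);
}
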