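#include <Rcpp.h>
using namespace Rcpp;

// Log-likelihood of a single Gaussian at its MLE.
static double loglik1(const NumericVector& x, double floor_sd) {
  int n = x.size();
  double mu = mean(x);
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (x[i] - mu) * (x[i] - mu);
  double sd = std::sqrt(ss / n);
  if (sd < floor_sd) sd = floor_sd;
  double ll = 0.0;
  for (int i = 0; i < n; ++i)
    ll += R::dnorm(x[i], mu, sd, 1);
  return ll;
}

struct Gmm2 {
  double w, mu1, mu2, sd, ll;
};

// Equal-variance two-component Gaussian mixture, EM from a fixed start.
static Gmm2 em2_once(const NumericVector& x, double mu1, double mu2,
                     double sd0, double floor_sd, int max_iter) {
  int n = x.size();
  double w = 0.5, sd = std::max(sd0, floor_sd);
  double ll = R_NegInf;
  NumericVector r(n);
  for (int it = 0; it < max_iter; ++it) {
    // E step
    double ll_new = 0.0;
    for (int i = 0; i < n; ++i) {
      double a = std::log(w) + R::dnorm(x[i], mu1, sd, 1);
      double b = std::log(1.0 - w) + R::dnorm(x[i], mu2, sd, 1);
      double m = std::max(a, b);
      double lse = m + std::log(std::exp(a - m) + std::exp(b - m));
      r[i] = std::exp(a - lse);
      ll_new += lse;
    }
    // M step
    double sw = 0.0, s1 = 0.0, s2 = 0.0, n2 = 0.0;
    for (int i = 0; i < n; ++i) {
      sw += r[i];
      s1 += r[i] * x[i];
      s2 += (1.0 - r[i]) * x[i];
      n2 += 1.0 - r[i];
    }
    if (sw < 1e-10 || n2 < 1e-10) break; // component died
    w = sw / n;
    mu1 = s1 / sw;
    mu2 = s2 / n2;
    double ssw = 0.0;
    for (int i = 0; i < n; ++i)
      ssw += r[i] * (x[i] - mu1) * (x[i] - mu1) +
             (1.0 - r[i]) * (x[i] - mu2) * (x[i] - mu2);
    sd = std::sqrt(ssw / n);
    if (sd < floor_sd) sd = floor_sd;
    if (std::abs(ll_new - ll) < 1e-8 * (std::abs(ll_new) + 1.0)) {
      ll = ll_new;
      break;
    }
    ll = ll_new;
  }
  Gmm2 out;
  out.w = w; out.mu1 = mu1; out.mu2 = mu2; out.sd = sd; out.ll = ll;
  return out;
}

// Best of a deterministic set of starts: split the sorted sample at a grid
// of fractions and start from the part means.
static Gmm2 em2_best(const NumericVector& x, double floor_sd,
                     int n_restarts, int max_iter) {
  int n = x.size();
  NumericVector xs = clone(x).sort();
  double sd0 = sd(x);
  Gmm2 best;
  best.ll = R_NegInf;
  for (int r = 1; r <= n_restarts; ++r) {
    double frac = (double)r / (n_restarts + 1.0);
    int k = std::max(1, std::min(n - 1, (int)std::floor(frac * n)));
    double m1 = 0.0, m2 = 0.0;
    for (int i = 0; i < k; ++i) m1 += xs[i];
    for (int i = k; i < n; ++i) m2 += xs[i];
    m1 /= k; m2 /= (n - k);
    Gmm2 fit = em2_once(x, m1, m2, sd0 * 0.5, floor_sd, max_iter);
    if (fit.ll > best.ll) best = fit;
  }
  return best;
}

static double lrt_stat(const NumericVector& x, double floor_sd,
                       int n_restarts, int max_iter) {
  double ll1 = loglik1(x, floor_sd);
  Gmm2 fit = em2_best(x, floor_sd, n_restarts, max_iter);
  double t = 2.0 * (fit.ll - ll1);
  return t > 0.0 ? t : 0.0;
}

// [[Rcpp::export(name = ".lrt_stat_only")]]
double lrt_stat_only(NumericVector x, int n_restarts = 10, int max_iter = 100) {
  double s = sd(x);
  double floor_sd = std::max(1e-4 * (s > 0 ? s : 1.0), 1e-9);
  return lrt_stat(x, floor_sd, n_restarts, max_iter);
}

// [[Rcpp::export(name = ".gmm2_responsibility")]]
NumericVector gmm2_responsibility(NumericVector x, int n_restarts = 10,
                                  int max_iter = 100) {
  int n = x.size();
  double s = sd(x);
  double floor_sd = std::max(1e-4 * (s > 0 ? s : 1.0), 1e-9);
  Gmm2 fit = em2_best(x, floor_sd, n_restarts, max_iter);
  NumericVector resp(n);
  for (int i = 0; i < n; ++i) {
    double a = std::log(fit.w) + R::dnorm(x[i], fit.mu1, fit.sd, 1);
    double b = std::log(1.0 - fit.w) + R::dnorm(x[i], fit.mu2, fit.sd, 1);
    double m = std::max(a, b);
    resp[i] = std::exp(a - m) / (std::exp(a - m) + std::exp(b - m));
  }
  return resp;
}

// [[Rcpp::export(name = ".lrt_bimodal")]]
List lrt_bimodal(NumericVector x, int n_boot = 200, int n_restarts = 10,
                 int max_iter = 100) {
  int n = x.size();
  double s = sd(x);
  double floor_sd = std::max(1e-4 * (s > 0 ? s : 1.0), 1e-9);
  double t_obs = lrt_stat(x, floor_sd, n_restarts, max_iter);
  // parametric bootstrap under the fitted unimodal null (uses R's RNG)
  double mu0 = mean(x);
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (x[i] - mu0) * (x[i] - mu0);
  double sd0 = std::max(std::sqrt(ss / n), floor_sd);
  int ge = 0;
  NumericVector xb(n);
  for (int b = 0; b < n_boot; ++b) {
    for (int i = 0; i < n; ++i) xb[i] = R::rnorm(mu0, sd0);
    if (lrt_stat(xb, floor_sd, n_restarts, max_iter) >= t_obs) ++ge;
  }
  double pval = (1.0 + ge) / (double)(n_boot + 1);
  // responsibilities of the bimodal fit, for splitting
  Gmm2 fit = em2_best(x, floor_sd, n_restarts, max_iter);
  NumericVector resp(n);
  for (int i = 0; i < n; ++i) {
    double a = std::log(fit.w) + R::dnorm(x[i], fit.mu1, fit.sd, 1);
    double b = std::log(1.0 - fit.w) + R::dnorm(x[i], fit.mu2, fit.sd, 1);
    double m = std::max(a, b);
    resp[i] = std::exp(a - m) / (std::exp(a - m) + std::exp(b - m));
  }
  return List::create(_["statistic"] = t_obs, _["p_value"] = pval,
                      _["responsibility"] = resp,
                      _["mu1"] = fit.mu1, _["mu2"] = fit.mu2,
                      _["sd"] = fit.sd, _["w"] = fit.w);
}
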