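// Adaptive random-walk Metropolis-within-Gibbs sampler for the hierarchical
// linear-plus-plateau dilution model.
//
// Parameter vector layout (k = number of date groups):
//   [0]          A1   dilution-curve intercept
//   [1]          A2   dilution exponent
//   [2 .. k+1]   Bmax_i  per-date plateau
//   [k+2 .. 2k+1] beta_i per-date linear-limb slope
//   [2k+2]       sigma  observation noise SD
// All priors are uniform on [lower, upper]; a parameter with
// lower == upper is held fixed and never updated.

#include <Rcpp.h>
using namespace Rcpp;

static inline double lpp_mu(double N, double Bmax, double beta, double Nc) {
  double w = (N < Nc) ? Bmax * (1.0 - beta * (Nc - N)) : Bmax;
  return w > 0.0 ? w : 0.0;
}

static double group_ll(const std::vector<double>& W,
                       const std::vector<double>& N,
                       double Bmax, double beta, double Nc, double sigma) {
  double ll = 0.0;
  for (size_t j = 0; j < W.size(); ++j)
    ll += R::dnorm(W[j], lpp_mu(N[j], Bmax, beta, Nc), sigma, 1);
  return ll;
}

// [[Rcpp::export]]
List mcmc_lpp_chain(List groups_W, List groups_N,
                    NumericVector lower, NumericVector upper,
                    NumericVector init, int n_burn, int n_keep, int thin,
                    int noise_proportional) {
  const int k = groups_W.size();
  // observation SD: sigma * Bmax_i (relative noise) or sigma (W units)
  auto sdv = [&](double sig, double bmax) {
    return noise_proportional ? sig * bmax : sig;
  };
  const int n_par = 2 * k + 3;
  if (lower.size() != n_par || upper.size() != n_par || init.size() != n_par)
    stop("parameter vector length mismatch: expected %d parameters", n_par);

  std::vector<std::vector<double>> W(k), N(k);
  for (int i = 0; i < k; ++i) {
    W[i] = as<std::vector<double>>(groups_W[i]);
    N[i] = as<std::vector<double>>(groups_N[i]);
    if (W[i].size() != N[i].size()) stop("group %d: W and N lengths differ", i + 1);
  }

  std::vector<double> th(init.begin(), init.end());
  for (int p = 0; p < n_par; ++p)
    if (th[p] < lower[p] || th[p] > upper[p])
      stop("initial value of parameter %d outside prior support", p + 1);

  std::vector<double> Nc(k), gll(k);
  double sigma = th[n_par - 1];
  for (int i = 0; i < k; ++i) {
    Nc[i] = th[0] * std::pow(th[2 + i], -th[1]);
    gll[i] = group_ll(W[i], N[i], th[2 + i], th[2 + k + i], Nc[i],
                      sdv(sigma, th[2 + i]));
  }

  std::vector<double> lsc(n_par), acc(n_par, 0.0), tries(n_par, 0.0),
      bacc(n_par, 0.0), btry(n_par, 0.0);
  std::vector<bool> fixed(n_par);
  for (int p = 0; p < n_par; ++p) {
    fixed[p] = (upper[p] - lower[p]) <= 0.0;
    lsc[p] = std::log(std::max(0.05 * (upper[p] - lower[p]), 1e-8));
  }

  const int total = n_burn + n_keep * thin;
  NumericMatrix draws(n_keep, n_par);
  int stored = 0, batch = 0;

  // Full-dimensional adaptive Metropolis block (Haario-style) over all free
  // parameters, with A1 handled on the log scale: the posterior ridge ties
  // A1, A2 and every group's slope together (log Nc = log A1 - A2 log W),
  // so only a proposal aligned with the full empirical covariance traverses
  // it; the single-site sweep above supplies local exploration and the
  // history the covariance is learned from. The covariance estimator is
  // restarted twice during burn-in to shed the initial transient.
  std::vector<int> free_idx;
  for (int p = 0; p < n_par; ++p) if (!fixed[p]) free_idx.push_back(p);
  const int nf = (int)free_idx.size();
  const bool am_on = nf >= 2 && th[0] > 0.0;
  const bool log_a1 = !fixed[0];
  std::vector<double> am_mu(nf, 0.0), am_x(nf), am_d(nf);
  std::vector<double> am_C(nf * nf, 0.0), am_L(nf * nf, 0.0);
  long am_n = 0;
  bool am_ready = false;
  double am_scale = 1.0, am_acc = 0.0, am_try = 0.0, am_bacc = 0.0,
      am_btry = 0.0;
  const int am_reps = 6 + nf / 3;
  auto get_x = [&](std::vector<double>& x) {
    for (int j = 0; j < nf; ++j) {
      int p = free_idx[j];
      x[j] = (p == 0 && log_a1) ? std::log(th[0]) : th[p];
    }
  };
  // lower-triangular Cholesky of s * C/(n-1) + jitter
  auto am_chol = [&]() {
    double s = 5.6644 / nf * am_scale * am_scale; // 2.38^2 / d
    std::vector<double> A(nf * nf);
    for (int a = 0; a < nf * nf; ++a) A[a] = s * am_C[a] / (am_n - 1);
    for (int a = 0; a < nf; ++a) A[a * nf + a] += 1e-12;
    for (int i2 = 0; i2 < nf; ++i2) {
      for (int j2 = 0; j2 <= i2; ++j2) {
        double sum = A[i2 * nf + j2];
        for (int k2 = 0; k2 < j2; ++k2)
          sum -= am_L[i2 * nf + k2] * am_L[j2 * nf + k2];
        if (i2 == j2) {
          am_L[i2 * nf + i2] = std::sqrt(sum > 1e-14 ? sum : 1e-14);
        } else {
          am_L[i2 * nf + j2] = sum / am_L[j2 * nf + j2];
        }
      }
      for (int j2 = i2 + 1; j2 < nf; ++j2) am_L[i2 * nf + j2] = 0.0;
    }
    am_ready = true;
  };

  for (int it = 0; it < total; ++it) {
    for (int p = 0; p < n_par; ++p) {
      if (fixed[p]) continue;
      double prop = th[p] + std::exp(lsc[p]) * R::norm_rand();
      tries[p] += 1.0; btry[p] += 1.0;
      if (prop < lower[p] || prop > upper[p]) continue; // reject: flat prior
      double delta = 0.0;
      std::vector<double> new_ll, new_Nc;
      if (p == 0 || p == 1) { // A1 or A2: every group's Nc changes
        double a1 = (p == 0) ? prop : th[0];
        double a2 = (p == 1) ? prop : th[1];
        new_ll.resize(k); new_Nc.resize(k);
        for (int i = 0; i < k; ++i) {
          new_Nc[i] = a1 * std::pow(th[2 + i], -a2);
          new_ll[i] = group_ll(W[i], N[i], th[2 + i], th[2 + k + i], new_Nc[i],
                               sdv(sigma, th[2 + i]));
          delta += new_ll[i] - gll[i];
        }
      } else if (p == n_par - 1) { // sigma
        new_ll.resize(k);
        for (int i = 0; i < k; ++i) {
          new_ll[i] = group_ll(W[i], N[i], th[2 + i], th[2 + k + i], Nc[i],
                               sdv(prop, th[2 + i]));
          delta += new_ll[i] - gll[i];
        }
      } else if (p < 2 + k) { // Bmax_i: group i's mean and Nc change
        int i = p - 2;
        double nc_i = th[0] * std::pow(prop, -th[1]);
        double ll_i = group_ll(W[i], N[i], prop, th[2 + k + i], nc_i,
                               sdv(sigma, prop));
        delta = ll_i - gll[i];
        new_ll.assign(1, ll_i); new_Nc.assign(1, nc_i);
      } else { // beta_i
        int i = p - 2 - k;
        double ll_i = group_ll(W[i], N[i], th[2 + i], prop, Nc[i],
                               sdv(sigma, th[2 + i]));
        delta = ll_i - gll[i];
        new_ll.assign(1, ll_i);
      }
      if (std::log(R::unif_rand()) < delta) {
        acc[p] += 1.0; bacc[p] += 1.0;
        th[p] = prop;
        if (p == 0 || p == 1) { gll = new_ll; Nc = new_Nc; }
        else if (p == n_par - 1) { gll = new_ll; sigma = prop; }
        else if (p < 2 + k) { int i = p - 2; gll[i] = new_ll[0]; Nc[i] = new_Nc[0]; }
        else { int i = p - 2 - k; gll[i] = new_ll[0]; }
      }
    }

    if (am_on && th[0] > 0.0) {
      // restart the covariance estimator twice to shed the initial transient
      if (it == n_burn / 4 || it == n_burn / 2) {
        am_n = 0;
        std::fill(am_C.begin(), am_C.end(), 0.0);
        am_scale = 1.0; am_bacc = am_btry = 0.0; am_ready = false;
      }
      // Welford update of mean and covariance with the current state
      get_x(am_x);
      ++am_n;
      for (int j = 0; j < nf; ++j) am_d[j] = am_x[j] - am_mu[j];
      for (int j = 0; j < nf; ++j) am_mu[j] += am_d[j] / am_n;
      for (int i2 = 0; i2 < nf; ++i2)
        for (int j2 = 0; j2 <= i2; ++j2) {
          double cval = am_d[i2] * (am_x[j2] - am_mu[j2]);
          am_C[i2 * nf + j2] += cval;
          if (i2 != j2) am_C[j2 * nf + i2] += cval;
        }
      if (am_n >= 10 * nf && (am_n % 25 == 0 || !am_ready)) am_chol();

      if (am_ready) for (int rep = 0; rep < am_reps; ++rep) {
        get_x(am_x);
        std::vector<double> z(nf), xp(nf), thp(th);
        for (int j = 0; j < nf; ++j) z[j] = R::norm_rand();
        for (int i2 = 0; i2 < nf; ++i2) {
          double step = 0.0;
          for (int j2 = 0; j2 <= i2; ++j2) step += am_L[i2 * nf + j2] * z[j2];
          xp[i2] = am_x[i2] + step;
        }
        am_try += 1.0; am_btry += 1.0;
        bool ok = true;
        double jac = 0.0;
        for (int j = 0; j < nf && ok; ++j) {
          int p = free_idx[j];
          double v = (p == 0 && log_a1) ? std::exp(xp[j]) : xp[j];
          if (v < lower[p] || v > upper[p]) ok = false;
          thp[p] = v;
          if (p == 0 && log_a1) jac = xp[j] - am_x[j]; // flat prior, log scale
        }
        if (!ok) continue;
        double delta = jac;
        std::vector<double> new_ll(k), new_Nc(k);
        double sigp = thp[n_par - 1];
        for (int i2 = 0; i2 < k; ++i2) {
          new_Nc[i2] = thp[0] * std::pow(thp[2 + i2], -thp[1]);
          new_ll[i2] = group_ll(W[i2], N[i2], thp[2 + i2], thp[2 + k + i2],
                                new_Nc[i2], sdv(sigp, thp[2 + i2]));
          delta += new_ll[i2] - gll[i2];
        }
        if (std::log(R::unif_rand()) < delta) {
          am_acc += 1.0; am_bacc += 1.0;
          th = thp; gll = new_ll; Nc = new_Nc; sigma = sigp;
        }
        if (rep == am_reps - 1 && it < n_burn && (it + 1) % 50 == 0 &&
            am_btry > 0) {
          double step = std::min(0.05, 1.0 / std::sqrt((double)(it / 50 + 1)));
          am_scale *= std::exp((am_bacc / am_btry > 0.234) ? step : -step);
          am_bacc = am_btry = 0.0;
        }
      }
    }

    // diminishing adaptation toward 0.44 acceptance, burn-in only
    if (it < n_burn && (it + 1) % 50 == 0) {
      ++batch;
      double step = std::min(0.05, 1.0 / std::sqrt((double)batch));
      for (int p = 0; p < n_par; ++p) {
        if (fixed[p] || btry[p] == 0) continue;
        lsc[p] += (bacc[p] / btry[p] > 0.44) ? step : -step;
        bacc[p] = btry[p] = 0.0;
      }
    }

    if (it >= n_burn && (it - n_burn) % thin == 0 && stored < n_keep) {
      for (int p = 0; p < n_par; ++p) draws(stored, p) = th[p];
      ++stored;
    }
  }

  NumericVector arate(n_par);
  for (int p = 0; p < n_par; ++p)
    arate[p] = tries[p] > 0 ? acc[p] / tries[p] : NA_REAL;

  return List::create(_["draws"] = draws, _["acceptance"] = arate,
                      _["block_acceptance"] = am_try > 0 ? am_acc / am_try
                                                         : NA_REAL,
                      _["block_scale"] = am_scale);
}
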