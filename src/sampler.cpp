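// Metropolis-within-Gibbs sampler for the joint GPCM + biometric twin model.
//
// Model: theta_j = A_j + C_f + D_j + E_j with
//   MZ pairs sharing A (and D), DZ pairs correlating 0.5 (A) / 0.25 (D),
//   C shared within family (ACE), and E_j ~ N(0, exp(beta0 + beta1 * g_j))
//   with g_j the additive (AE/ACE) or total (ADE) genetic value.
// Measurement: GPCM category probabilities at theta_j; originally missing
// item scores are imputed from the GPCM predictive each iteration and do
// not enter the recorded deviance.
//
// GPCM likelihood evaluations factor the cumulative sums as
//   exp(s_k) = exp(alpha * theta)^k * exp(-alpha * cumsum(b)_k),
// so one person-item evaluation costs a single exp + log once the
// per-item tables are cached; a max-subtraction fallback guards states
// outside the tables' safe numeric range.
//
// Individuals must be ordered family-major: persons 2f and 2f+1 form
// family f. Uses R's RNG so runs are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// safe (max-subtraction) evaluation; also fills category probabilities
// into p when p != nullptr
static double item_ll_safe(int y, double theta, double alpha,
                           const double* b, int K, double* s, double* p) {
  double run = 0.0, mx = -1e300;
  for (int k = 0; k < K; ++k) {
    run += alpha * (theta - b[k]);
    s[k] = run;
    if (run > mx) mx = run;
  }
  double denom = 0.0;
  for (int k = 0; k < K; ++k) { s[k] = std::exp(s[k] - mx); denom += s[k]; }
  if (p) for (int k = 0; k < K; ++k) p[k] = s[k] / denom;
  return std::log(s[y - 1] / denom);
}

struct ItemTables {
  int I, Kmax;
  std::vector<int> K;
  std::vector<double> alpha;     // I
  std::vector<double> thr;       // I x Kmax, first threshold 0
  std::vector<double> w;         // I x Kmax: alpha * cumsum(thr)
  std::vector<double> q;         // I x Kmax: exp(-w)
  std::vector<char> safe;        // I: tables usable?

  void refresh(int i) {
    double cb = 0.0;
    bool ok = true;
    for (int k = 0; k < K[i]; ++k) {
      cb += thr[i * Kmax + k];
      double wk = alpha[i] * cb;
      if (std::fabs(wk) > 250.0) ok = false;
      w[i * Kmax + k] = wk;
      q[i * Kmax + k] = std::exp(-wk);
    }
    safe[i] = ok;
  }

  // log P(Y = y | theta) for item i
  inline double loglik(int i, int y, double theta, double* scratch) const {
    double u = alpha[i] * theta;
    if (!safe[i] || std::fabs(u) > 50.0)
      return item_ll_safe(y, theta, alpha[i], &thr[i * Kmax], K[i], scratch,
                          (double*)0);
    const double* qi = &q[i * Kmax];
    double t = std::exp(u), pw = 1.0, denom = 0.0;
    for (int k = 0; k < K[i]; ++k) { pw *= t; denom += qi[k] * pw; }
    return y * u - w[i * Kmax + y - 1] - std::log(denom);
  }

  // category probabilities at theta into p
  inline void probs(int i, double theta, double* p, double* scratch) const {
    double u = alpha[i] * theta;
    if (!safe[i] || std::fabs(u) > 50.0) {
      item_ll_safe(1, theta, alpha[i], &thr[i * Kmax], K[i], scratch, p);
      return;
    }
    const double* qi = &q[i * Kmax];
    double t = std::exp(u), pw = 1.0, denom = 0.0;
    for (int k = 0; k < K[i]; ++k) { pw *= t; p[k] = qi[k] * pw; denom += p[k]; }
    for (int k = 0; k < K[i]; ++k) p[k] /= denom;
  }
};

// log density of pair component values (MZ share one draw; DZ bivariate
// with correlation rho), summed over families
static double pair_logdens(const std::vector<double>& x, const LogicalVector& mz,
                           double s2, double rho) {
  int F = mz.size();
  double out = 0.0;
  const double l2pi = std::log(2.0 * M_PI);
  for (int f = 0; f < F; ++f) {
    double a = x[2 * f], b = x[2 * f + 1];
    if (mz[f]) {
      out += -0.5 * l2pi - 0.5 * std::log(s2) - a * a / (2.0 * s2);
    } else {
      double om = 1.0 - rho * rho;
      out += -l2pi - 0.5 * std::log(s2 * s2 * om)
             - (a * a + b * b - 2.0 * rho * a * b) / (2.0 * s2 * om);
    }
  }
  return out;
}

// anchor_mode: 0 = parameter-expanded sampling with all discriminations
// free; every recorded draw is rescaled to the identified scale on which
// the geometric mean of the discriminations is 1 (the likelihood is
// invariant under the rescaling, so this is a deterministic functional of
// the draw). 1 = hard anchor alpha_1 = 1 (first discrimination never
// updated), draws recorded as-is.
// [[Rcpp::export]]
List sampler_run(IntegerMatrix y_in, LogicalMatrix miss, IntegerVector K,
                 LogicalVector mz, int flavour, bool interaction,
                 int anchor_mode, List priors, List init,
                 int n_burn, int n_keep, int thin) {
  const int N = y_in.nrow(), I = y_in.ncol(), F = N / 2;
  int Kmax = 0;
  for (int i = 0; i < I; ++i) if (K[i] > Kmax) Kmax = K[i];

  const double sigma_scale = as<double>(priors["sigma_scale"]);
  const double beta_sd     = as<double>(priors["beta_sd"]);
  const double thr_sd      = as<double>(priors["threshold_sd"]);
  const double a_meanlog   = as<double>(priors["alpha_meanlog"]);
  const double a_sdlog     = as<double>(priors["alpha_sdlog"]);

  // --- state ---
  std::vector<double> A  = as<std::vector<double> >(init["A"]);
  std::vector<double> Cc = as<std::vector<double> >(init["C"]);   // length F
  std::vector<double> Dd = as<std::vector<double> >(init["D"]);
  std::vector<double> E  = as<std::vector<double> >(init["E"]);

  ItemTables it;
  it.I = I; it.Kmax = Kmax;
  it.K = as<std::vector<int> >(K);
  it.alpha = as<std::vector<double> >(init["alpha"]);
  NumericMatrix thr0 = init["thresholds"];                        // I x Kmax
  it.thr.assign(I * Kmax, 0.0);
  it.w.assign(I * Kmax, 0.0);
  it.q.assign(I * Kmax, 0.0);
  it.safe.assign(I, 1);
  for (int i = 0; i < I; ++i) {
    for (int k = 0; k < K[i]; ++k) it.thr[i * Kmax + k] = thr0(i, k);
    it.refresh(i);
  }

  double s2A = as<double>(init["s2A"]);
  double s2C = as<double>(init["s2C"]);
  double s2D = as<double>(init["s2D"]);
  double b0  = as<double>(init["beta0"]);
  double b1  = as<double>(init["beta1"]);

  IntegerMatrix ycur = clone(y_in);
  std::vector<double> theta(N), g(N);
  for (int j = 0; j < N; ++j) {
    theta[j] = A[j] + Cc[j / 2] + Dd[j] + E[j];
    g[j] = (flavour == 2) ? A[j] + Dd[j] : A[j];
  }

  std::vector<double> llmat(N * I), pll(N, 0.0);
  std::vector<double> s(Kmax), pbuf(Kmax), tmprow(I), tmpcol(N);
  std::vector<double> r1(I), r2(I);

  // initial imputation of missing cells: start at the middle category
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < I; ++i)
      if (miss(j, i)) ycur(j, i) = (K[i] + 1) / 2;

  for (int j = 0; j < N; ++j) {
    double tot = 0.0;
    for (int i = 0; i < I; ++i) {
      double v = it.loglik(i, ycur(j, i), theta[j], &s[0]);
      llmat[j * I + i] = v; tot += v;
    }
    pll[j] = tot;
  }

  // --- adaptation bookkeeping ---
  std::vector<double> stepE(N, 0.6), stepA(N, 0.4), stepD(N, 0.4), stepC(F, 0.4);
  std::vector<double> stepAl(I, 0.15), stepThr(I * Kmax, 0.25);
  double stepS2A = 0.3, stepS2CD = 0.3, stepB0 = 0.15, stepB1 = 0.15;
  std::vector<int> accE(N, 0), accA(N, 0), accD(N, 0), accC(F, 0);
  std::vector<int> accAl(I, 0), accThr(I * Kmax, 0);
  int accS2A = 0, accS2CD = 0, accB0 = 0, accB1 = 0;
  const int window = 50;
  const double target = 0.44;

  // --- output ---
  int n_par = 2 + (flavour != 0 ? 1 : 0) + (interaction ? 1 : 0) + I;
  for (int i = 0; i < I; ++i) n_par += K[i] - 1;
  NumericMatrix draws(n_keep, n_par);
  NumericVector devtrace(n_keep);
  std::vector<double> theta_sum(N, 0.0), A_sum(N, 0.0), alpha_sum(I, 0.0);
  std::vector<double> thr_sum(I * Kmax, 0.0);

  RNGScope scope;
  const int n_total = n_burn + n_keep * thin;
  int kept = 0;

  auto row_ll = [&](int j, double th, double* out) {
    double tot = 0.0;
    for (int i = 0; i < I; ++i) {
      double v = it.loglik(i, ycur(j, i), th, &s[0]);
      out[i] = v; tot += v;
    }
    return tot;
  };
  auto accept_row = [&](int j, double th, double tot, const double* row) {
    theta[j] = th;
    for (int i = 0; i < I; ++i) llmat[j * I + i] = row[i];
    pll[j] = tot;
  };
  auto e_term = [&](int j, double gj) {
    double lv = b0 + b1 * gj;
    return -0.5 * lv - E[j] * E[j] / (2.0 * std::exp(lv));
  };
  auto adapt = [&](double& step, int& acc, double scale) {
    double rate = (double)acc / window;
    step *= std::exp(scale * (rate - target));
    if (step < 1e-4) step = 1e-4;
    if (step > 25.0) step = 25.0;
    acc = 0;
  };

  for (int iter = 0; iter < n_total; ++iter) {
    bool adapting = iter < n_burn;
    // 1. impute missing responses from the GPCM predictive
    for (int j = 0; j < N; ++j) {
      for (int i = 0; i < I; ++i) {
        if (!miss(j, i)) continue;
        it.probs(i, theta[j], &pbuf[0], &s[0]);
        double u = unif_rand(), cum = 0.0;
        int pick = K[i];
        for (int k = 0; k < K[i]; ++k) {
          cum += pbuf[k];
          if (u <= cum) { pick = k + 1; break; }
        }
        ycur(j, i) = pick;
        double newll = std::log(pbuf[pick - 1]);
        pll[j] += newll - llmat[j * I + i];
        llmat[j * I + i] = newll;
      }
    }

    // 2. unique-environment values E_j
    for (int j = 0; j < N; ++j) {
      double e_new = E[j] + stepE[j] * norm_rand();
      double th = theta[j] - E[j] + e_new;
      double prop = row_ll(j, th, &tmprow[0]);
      double v = std::exp(b0 + b1 * g[j]);
      double lr = prop - pll[j] - (e_new * e_new - E[j] * E[j]) / (2.0 * v);
      if (std::log(unif_rand()) < lr) {
        E[j] = e_new; accept_row(j, th, prop, &tmprow[0]); ++accE[j];
      }
    }

    // 3. additive genetic values A
    for (int f = 0; f < F; ++f) {
      int j1 = 2 * f, j2 = 2 * f + 1;
      if (mz[f]) {
        double a_new = A[j1] + stepA[j1] * norm_rand();
        double d = a_new - A[j1];
        double th1 = theta[j1] + d, th2 = theta[j2] + d;
        double p1 = row_ll(j1, th1, &r1[0]);
        double p2 = row_ll(j2, th2, &r2[0]);
        double lr = p1 + p2 - pll[j1] - pll[j2]
          - (a_new * a_new - A[j1] * A[j1]) / (2.0 * s2A);
        double g1 = a_new + (flavour == 2 ? Dd[j1] : 0.0);
        double g2 = a_new + (flavour == 2 ? Dd[j2] : 0.0);
        lr += e_term(j1, g1) - e_term(j1, g[j1]);
        lr += e_term(j2, g2) - e_term(j2, g[j2]);
        if (std::log(unif_rand()) < lr) {
          A[j1] = A[j2] = a_new; g[j1] = g1; g[j2] = g2;
          accept_row(j1, th1, p1, &r1[0]); accept_row(j2, th2, p2, &r2[0]);
          ++accA[j1];
        }
      } else {
        for (int t = 0; t < 2; ++t) {
          int j = 2 * f + t, c = 2 * f + (1 - t);
          double a_new = A[j] + stepA[j] * norm_rand();
          double th = theta[j] + (a_new - A[j]);
          double prop = row_ll(j, th, &tmprow[0]);
          double m = 0.5 * A[c], v = 0.75 * s2A;
          double lr = prop - pll[j]
            - ((a_new - m) * (a_new - m) - (A[j] - m) * (A[j] - m)) / (2.0 * v);
          double gn = a_new + (flavour == 2 ? Dd[j] : 0.0);
          lr += e_term(j, gn) - e_term(j, g[j]);
          if (std::log(unif_rand()) < lr) {
            A[j] = a_new; g[j] = gn;
            accept_row(j, th, prop, &tmprow[0]); ++accA[j];
          }
        }
      }
    }

    // 4. dominance values D (ADE)
    if (flavour == 2) {
      for (int f = 0; f < F; ++f) {
        int j1 = 2 * f, j2 = 2 * f + 1;
        if (mz[f]) {
          double d_new = Dd[j1] + stepD[j1] * norm_rand();
          double d = d_new - Dd[j1];
          double th1 = theta[j1] + d, th2 = theta[j2] + d;
          double p1 = row_ll(j1, th1, &r1[0]);
          double p2 = row_ll(j2, th2, &r2[0]);
          double lr = p1 + p2 - pll[j1] - pll[j2]
            - (d_new * d_new - Dd[j1] * Dd[j1]) / (2.0 * s2D);
          double g1 = A[j1] + d_new, g2 = A[j2] + d_new;
          lr += e_term(j1, g1) - e_term(j1, g[j1]);
          lr += e_term(j2, g2) - e_term(j2, g[j2]);
          if (std::log(unif_rand()) < lr) {
            Dd[j1] = Dd[j2] = d_new; g[j1] = g1; g[j2] = g2;
            accept_row(j1, th1, p1, &r1[0]); accept_row(j2, th2, p2, &r2[0]);
            ++accD[j1];
          }
        } else {
          for (int t = 0; t < 2; ++t) {
            int j = 2 * f + t, c = 2 * f + (1 - t);
            double d_new = Dd[j] + stepD[j] * norm_rand();
            double th = theta[j] + (d_new - Dd[j]);
            double prop = row_ll(j, th, &tmprow[0]);
            double m = 0.25 * Dd[c], v = (1.0 - 0.0625) * s2D;
            double lr = prop - pll[j]
              - ((d_new - m) * (d_new - m) - (Dd[j] - m) * (Dd[j] - m)) / (2.0 * v);
            double gn = A[j] + d_new;
            lr += e_term(j, gn) - e_term(j, g[j]);
            if (std::log(unif_rand()) < lr) {
              Dd[j] = d_new; g[j] = gn;
              accept_row(j, th, prop, &tmprow[0]); ++accD[j];
            }
          }
        }
      }
    }

    // 5. shared-environment values C (ACE)
    if (flavour == 1) {
      for (int f = 0; f < F; ++f) {
        int j1 = 2 * f, j2 = 2 * f + 1;
        double c_new = Cc[f] + stepC[f] * norm_rand();
        double d = c_new - Cc[f];
        double th1 = theta[j1] + d, th2 = theta[j2] + d;
        double p1 = row_ll(j1, th1, &r1[0]);
        double p2 = row_ll(j2, th2, &r2[0]);
        double lr = p1 + p2 - pll[j1] - pll[j2]
          - (c_new * c_new - Cc[f] * Cc[f]) / (2.0 * s2C);
        if (std::log(unif_rand()) < lr) {
          Cc[f] = c_new;
          accept_row(j1, th1, p1, &r1[0]); accept_row(j2, th2, p2, &r2[0]);
          ++accC[f];
        }
      }
    }

    // 6. item parameters (GPCM), alpha_1 optionally anchored at 1
    for (int i = 0; i < I; ++i) {
      const int Ki = K[i];
      double colsum = 0.0;
      for (int j = 0; j < N; ++j) colsum += llmat[j * I + i];
      if (!(anchor_mode == 1 && i == 0)) {
        double la = std::log(it.alpha[i]);
        double la_new = la + stepAl[i] * norm_rand();
        double a_old = it.alpha[i];
        it.alpha[i] = std::exp(la_new);
        it.refresh(i);
        double prop = 0.0;
        for (int j = 0; j < N; ++j) {
          tmpcol[j] = it.loglik(i, ycur(j, i), theta[j], &s[0]);
          prop += tmpcol[j];
        }
        double lr = prop - colsum
          - ((la_new - a_meanlog) * (la_new - a_meanlog)
             - (la - a_meanlog) * (la - a_meanlog)) / (2.0 * a_sdlog * a_sdlog);
        if (std::log(unif_rand()) < lr) {
          for (int j = 0; j < N; ++j) {
            pll[j] += tmpcol[j] - llmat[j * I + i];
            llmat[j * I + i] = tmpcol[j];
          }
          colsum = prop; ++accAl[i];
        } else {
          it.alpha[i] = a_old;
          it.refresh(i);
        }
      }
      for (int k = 1; k < Ki; ++k) {
        double bk = it.thr[i * Kmax + k];
        double bk_new = bk + stepThr[i * Kmax + k] * norm_rand();
        it.thr[i * Kmax + k] = bk_new;
        it.refresh(i);
        double prop = 0.0;
        for (int j = 0; j < N; ++j) {
          tmpcol[j] = it.loglik(i, ycur(j, i), theta[j], &s[0]);
          prop += tmpcol[j];
        }
        double lr = prop - colsum
          - (bk_new * bk_new - bk * bk) / (2.0 * thr_sd * thr_sd);
        if (std::log(unif_rand()) < lr) {
          for (int j = 0; j < N; ++j) {
            pll[j] += tmpcol[j] - llmat[j * I + i];
            llmat[j * I + i] = tmpcol[j];
          }
          colsum = prop; ++accThr[i * Kmax + k];
        } else {
          it.thr[i * Kmax + k] = bk;
          it.refresh(i);
        }
      }
    }

    // 7. hyperparameters
    {
      // sigma2_A (log scale; half-normal prior on the SD)
      double u = std::log(s2A);
      double u_new = u + stepS2A * norm_rand();
      double s2_new = std::exp(u_new);
      double lr = pair_logdens(A, mz, s2_new, 0.5) - pair_logdens(A, mz, s2A, 0.5)
        - (s2_new - s2A) / (2.0 * sigma_scale * sigma_scale)
        + 0.5 * (u_new - u);
      if (std::log(unif_rand()) < lr) { s2A = s2_new; ++accS2A; }
    }
    if (flavour == 1) {
      double u = std::log(s2C);
      double u_new = u + stepS2CD * norm_rand();
      double s2_new = std::exp(u_new);
      double ld = 0.0;
      for (int f = 0; f < F; ++f)
        ld += -0.5 * std::log(s2_new) + 0.5 * std::log(s2C)
          - Cc[f] * Cc[f] / 2.0 * (1.0 / s2_new - 1.0 / s2C);
      double lr = ld - (s2_new - s2C) / (2.0 * sigma_scale * sigma_scale)
        + 0.5 * (u_new - u);
      if (std::log(unif_rand()) < lr) { s2C = s2_new; ++accS2CD; }
    }
    if (flavour == 2) {
      double u = std::log(s2D);
      double u_new = u + stepS2CD * norm_rand();
      double s2_new = std::exp(u_new);
      double lr = pair_logdens(Dd, mz, s2_new, 0.25) - pair_logdens(Dd, mz, s2D, 0.25)
        - (s2_new - s2D) / (2.0 * sigma_scale * sigma_scale)
        + 0.5 * (u_new - u);
      if (std::log(unif_rand()) < lr) { s2D = s2_new; ++accS2CD; }
    }
    {
      // beta0 (and beta1): heteroscedastic normal log-likelihood of E
      auto e_loglik = [&](double bb0, double bb1) {
        double out = 0.0;
        for (int j = 0; j < N; ++j) {
          double lv = bb0 + bb1 * g[j];
          out += -0.5 * lv - E[j] * E[j] / (2.0 * std::exp(lv));
        }
        return out;
      };
      double cur = e_loglik(b0, b1);
      double b0_new = b0 + stepB0 * norm_rand();
      double lr = e_loglik(b0_new, b1) - cur
        - (b0_new * b0_new - b0 * b0) / (2.0 * beta_sd * beta_sd);
      if (std::log(unif_rand()) < lr) { b0 = b0_new; cur = e_loglik(b0, b1); ++accB0; }
      if (interaction) {
        double b1_new = b1 + stepB1 * norm_rand();
        double lr1 = e_loglik(b0, b1_new) - cur
          - (b1_new * b1_new - b1 * b1) / (2.0 * beta_sd * beta_sd);
        if (std::log(unif_rand()) < lr1) { b1 = b1_new; ++accB1; }
      }
    }

    // adaptation (burn-in only, every `window` iterations)
    if (adapting && (iter + 1) % window == 0) {
      double sc = std::max(0.05, 2.0 / std::sqrt((double)(iter / window + 1)));
      for (int j = 0; j < N; ++j) adapt(stepE[j], accE[j], sc);
      for (int j = 0; j < N; ++j) adapt(stepA[j], accA[j], sc);
      if (flavour == 2) for (int j = 0; j < N; ++j) adapt(stepD[j], accD[j], sc);
      if (flavour == 1) for (int f = 0; f < F; ++f) adapt(stepC[f], accC[f], sc);
      for (int i = 0; i < I; ++i) adapt(stepAl[i], accAl[i], sc);
      for (int i = 0; i < I; ++i)
        for (int k = 1; k < K[i]; ++k)
          adapt(stepThr[i * Kmax + k], accThr[i * Kmax + k], sc);
      adapt(stepS2A, accS2A, sc); adapt(stepS2CD, accS2CD, sc);
      adapt(stepB0, accB0, sc); adapt(stepB1, accB1, sc);
    }

    // record (rescaled to the identified scale under anchor_mode 0)
    if (iter >= n_burn && (iter - n_burn) % thin == 0) {
      double cs = 1.0;
      if (anchor_mode == 0) {
        double sa = 0.0;
        for (int i = 0; i < I; ++i) sa += std::log(it.alpha[i]);
        cs = std::exp(sa / I);
      }
      int r = kept;
      int c = 0;
      draws(r, c++) = s2A * cs * cs;
      if (flavour == 1) draws(r, c++) = s2C * cs * cs;
      if (flavour == 2) draws(r, c++) = s2D * cs * cs;
      draws(r, c++) = b0 + 2.0 * std::log(cs);
      if (interaction) draws(r, c++) = b1 / cs;
      for (int i = 0; i < I; ++i) draws(r, c++) = it.alpha[i] / cs;
      for (int i = 0; i < I; ++i)
        for (int k = 1; k < K[i]; ++k) draws(r, c++) = it.thr[i * Kmax + k] * cs;
      double dev = 0.0;
      for (int j = 0; j < N; ++j)
        for (int i = 0; i < I; ++i)
          if (!miss(j, i)) dev += llmat[j * I + i];
      devtrace[r] = -2.0 * dev;
      for (int j = 0; j < N; ++j) {
        theta_sum[j] += cs * theta[j]; A_sum[j] += cs * A[j];
      }
      for (int i = 0; i < I; ++i) alpha_sum[i] += it.alpha[i] / cs;
      for (int i = 0; i < I; ++i)
        for (int k = 0; k < K[i]; ++k)
          thr_sum[i * Kmax + k] += cs * it.thr[i * Kmax + k];
      ++kept;
    }
  }

  NumericVector theta_mean(N), A_mean(N), alpha_mean(I);
  NumericMatrix thr_mean(I, Kmax);
  for (int j = 0; j < N; ++j) {
    theta_mean[j] = theta_sum[j] / kept;
    A_mean[j] = A_sum[j] / kept;
  }
  for (int i = 0; i < I; ++i) {
    alpha_mean[i] = alpha_sum[i] / kept;
    for (int k = 0; k < Kmax; ++k) thr_mean(i, k) = thr_sum[i * Kmax + k] / kept;
  }
  return List::create(_["draws"] = draws, _["deviance"] = devtrace,
                      _["theta_mean"] = theta_mean, _["A_mean"] = A_mean,
                      _["alpha_mean"] = alpha_mean, _["thr_mean"] = thr_mean);
}

// Total GPCM log-likelihood of the observed (non-NA) cells of a response
// matrix at given latent traits and item parameters.
// [[Rcpp::export]]
double cpp_table_loglik(IntegerMatrix y, NumericVector theta,
                        NumericVector alpha, List thresholds) {
  const int N = y.nrow(), I = y.ncol();
  double out = 0.0;
  std::vector<double> s;
  for (int i = 0; i < I; ++i) {
    NumericVector b = thresholds[i];
    int K = b.size();
    if ((int)s.size() < K) s.resize(K);
    for (int j = 0; j < N; ++j) {
      int yj = y(j, i);
      if (yj == NA_INTEGER) continue;
      out += item_ll_safe(yj, theta[j], alpha[i], &b[0], K, &s[0], (double*)0);
    }
  }
  return out;
}
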