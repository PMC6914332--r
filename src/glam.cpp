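#include <Rcpp.h>
using namespace Rcpp;

// Inverse-Gaussian (Wald) first-passage machinery for a linear accumulator
// with drift d, noise sd sigma and absorbing boundary b:
//   mu = b / d, lambda = b^2 / sigma^2.
// All densities are evaluated in log space; the CDF's exp(2*lambda/mu) term
// is combined with the log normal-CDF before exponentiating, so it cannot
// overflow (the combined exponent is always <= 0).

static const double DRIFT_FLOOR = 1e-10;
static const double SURV_FLOOR = 1e-300;

static inline double ig_logpdf(double t, double mu, double lambda) {
    if (t <= 0.0) return R_NegInf;
    double d = t - mu;
    return 0.5 * (std::log(lambda) - std::log(2.0 * M_PI) - 3.0 * std::log(t))
        - lambda * d * d / (2.0 * mu * mu * t);
}

static inline double ig_cdf(double t, double mu, double lambda) {
    if (t <= 0.0) return 0.0;
    double s = std::sqrt(lambda / t);
    double a = s * (t / mu - 1.0);
    double c = -s * (t / mu + 1.0);
    double term1 = R::pnorm(a, 0.0, 1.0, 1, 0);
    double log_term2 = 2.0 * lambda / mu + R::pnorm(c, 0.0, 1.0, 1, 1);
    double F = term1 + ((log_term2 > -745.0) ? std::exp(log_term2) : 0.0);
    if (F < 0.0) F = 0.0;
    if (F > 1.0) F = 1.0;
    return F;
}

// log p_i(t) = log f_i(t) + sum_{j != i} log(1 - F_j(t))
static double race_logdensity(double t, int winner,
                              const std::vector<double> &drift,
                              double sigma, double b) {
    double lambda = b * b / (sigma * sigma);
    int n = drift.size();
    double lp = ig_logpdf(t, b / std::max(drift[winner], DRIFT_FLOOR), lambda);
    for (int j = 0; j < n; ++j) {
        if (j == winner) continue;
        double surv = 1.0 - ig_cdf(t, b / std::max(drift[j], DRIFT_FLOOR), lambda);
        if (surv < SURV_FLOOR) surv = SURV_FLOOR;
        lp += std::log(surv);
    }
    return lp;
}

static inline double recycle(const NumericVector &x, int i) {
    return (x.size() == 1) ? x[0] : x[i];
}

// Per-trial GLAM log-likelihood (Eqs 1-10): gaze-weighted signals, logistic
// scaling, inverse-Gaussian race, epsilon-mixture with the subject-specific
// uniform contaminant (log_u = log(1 / (N * (rt_max - rt_min))), per trial).
// v, gamma, s, tau may be scalars or per-trial vectors.
// [[Rcpp::export]]
NumericVector cpp_glam_loglik(NumericMatrix value, NumericMatrix gaze,
                              IntegerVector choice, NumericVector rt,
                              NumericVector v, NumericVector gamma,
                              NumericVector s, NumericVector tau,
                              double eps, NumericVector log_u,
                              double boundary = 1.0) {
    int n = value.nrow(), m = value.ncol();
    NumericVector out(n);
    std::vector<double> abar(m), drift(m);
    double log1meps = (eps < 1.0) ? std::log1p(-eps) : R_NegInf;
    double logeps = (eps > 0.0) ? std::log(eps) : R_NegInf;
    for (int i = 0; i < n; ++i) {
        double vi = recycle(v, i), gi = recycle(gamma, i);
        double si = recycle(s, i), ti = recycle(tau, i);
        for (int j = 0; j < m; ++j) {
            double g = gaze(i, j), r = value(i, j);
            // gamma = 1 removes the gaze dependence exactly
            abar[j] = (gi == 1.0) ? r : g * r + (1.0 - g) * gi * r;
        }
        for (int j = 0; j < m; ++j) {
            double mx = R_NegInf;
            for (int k = 0; k < m; ++k)
                if (k != j && abar[k] > mx) mx = abar[k];
            double rstar = abar[j] - mx;
            double R = 1.0 / (1.0 + std::exp(-ti * rstar));
            drift[j] = vi * R;
        }
        double lp_race = race_logdensity(rt[i], choice[i], drift, si, boundary);
        double lp;
        if (eps <= 0.0) {
            lp = lp_race;
        } else if (eps >= 1.0) {
            lp = recycle(log_u, i);
        } else {
            double a = log1meps + lp_race;
            double c = logeps + recycle(log_u, i);
            double hi = std::max(a, c);
            lp = hi + std::log(std::exp(a - hi) + std::exp(c - hi));
        }
        out[i] = lp;
    }
    return out;
}

// Discrete-time Euler simulation of the race (Eq 5 with step dt): used as an
// independent oracle for the analytic inverse-Gaussian sampler.
// [[Rcpp::export]]
List cpp_euler_race(NumericVector drift, double sigma, double boundary,
                    double dt, int n_draws, int max_steps = 10000000) {
    int m = drift.size();
    IntegerVector choice(n_draws);
    NumericVector rt(n_draws);
    double sqdt = std::sqrt(dt);
    RNGScope scope;
    std::vector<double> e(m);
    for (int d = 0; d < n_draws; ++d) {
        for (int j = 0; j < m; ++j) e[j] = 0.0;
        int step = 0, winner = -1;
        while (winner < 0 && step < max_steps) {
            ++step;
            double best = R_NegInf;
            for (int j = 0; j < m; ++j) {
                e[j] += drift[j] * dt + sigma * sqdt * norm_rand();
                if (e[j] >= boundary && e[j] > best) {
                    best = e[j];
                    winner = j;
                }
            }
        }
        choice[d] = (winner < 0) ? NA_INTEGER : winner;
        rt[d] = step * dt;
    }
    return List::create(_["choice"] = choice, _["rt"] = rt);
}
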