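// Monte-Carlo simulators: Euler-Maruyama DDM with (optionally) linearly
// collapsing bounds and lapse mixture, and the leaky competing accumulator.
// Both draw from R's RNG so runs are reproducible via set.seed().

#include "accumimic.h"
#include <cmath>

using namespace Rcpp;

//' @noRd
// [[Rcpp::export(name = ".sim_ddm_cpp")]]
List sim_ddm_cpp(NumericVector v, NumericVector a, NumericVector z,
                 NumericVector theta, NumericVector t0, NumericVector p_out,
                 int n_reps, double dt, double deadline) {
    int n_trials = v.size();
    int n = n_trials * n_reps;
    IntegerVector trial(n), choice(n);
    NumericVector rt(n);
    double sq = std::sqrt(dt);
    int idx = 0;
    for (int i = 0; i < n_trials; ++i) {
        double slope = std::tan(theta[i]);
        double b0 = a[i] / 2.0;
        double t_dec_max = deadline - t0[i];
        for (int r = 0; r < n_reps; ++r, ++idx) {
            trial[idx] = i + 1;
            if (p_out[i] > 0.0 && unif_rand() < p_out[i]) {
                // attentional lapse: uniform RT, fair-coin choice
                choice[idx] = (unif_rand() < 0.5) ? 1 : 0;
                rt[idx] = t0[i] + unif_rand() * (deadline - t0[i]);
                continue;
            }
            double x = (z[i] - 0.5) * a[i];
            double t = 0.0;
            int ch = -1;  // -1 = missed
            double tdec = NA_REAL;
            while (t < t_dec_max) {
                double b_prev = b0 - slope * t;
                double xn = x + v[i] * dt + sq * norm_rand();
                t += dt;
                double b = b0 - slope * t;
                if (b <= 0.0) break;  // boundaries met: no decision recorded
                if (xn >= b) { ch = 1; tdec = t; break; }
                if (xn <= -b) { ch = 0; tdec = t; break; }
                // within-step crossing of the linear barriers
                // (exact Brownian-bridge probability; removes the
                //  discrete-monitoring bias of plain Euler updates)
                double eu = 2.0 * (b_prev - x) * (b - xn) / dt;
                if (eu < 30.0 && unif_rand() < std::exp(-eu)) {
                    ch = 1; tdec = t; break;
                }
                double el = 2.0 * (x + b_prev) * (xn + b) / dt;
                if (el < 30.0 && unif_rand() < std::exp(-el)) {
                    ch = 0; tdec = t; break;
                }
                x = xn;
            }
            choice[idx] = ch;
            rt[idx] = (ch >= 0) ? t0[i] + tdec : NA_REAL;
        }
    }
    return List::create(_["trial"] = trial, _["choice"] = choice, _["rt"] = rt);
}

//' @noRd
// [[Rcpp::export(name = ".sim_lca_cpp")]]
List sim_lca_cpp(NumericVector I1, NumericVector I2, int n_reps, double k,
                 double w_inh, double s, double z0, double deadline,
                 double t0, double step) {
    int n_trials = I1.size();
    int n = n_trials * n_reps;
    IntegerVector trial(n), choice(n);
    NumericVector rt(n), dec(n);
    int n_steps = static_cast<int>(std::round(deadline / step));
    double sq = std::sqrt(step) * s;
    int idx = 0;
    for (int i = 0; i < n_trials; ++i) {
        for (int r = 0; r < n_reps; ++r, ++idx) {
            double y1 = 0.0, y2 = 0.0;
            int ch = -1;
            double t = deadline;
            for (int m = 1; m <= n_steps; ++m) {
                double y1n = y1 + step * (I1[i] - k * y1 - w_inh * y2) +
                             sq * norm_rand();
                double y2n = y2 + step * (I2[i] - k * y2 - w_inh * y1) +
                             sq * norm_rand();
                y1 = y1n;
                y2 = y2n;
                double tm = m * step;
                double b = z0 * (1.0 - tm / deadline);
                bool c1 = y1 >= b, c2 = y2 >= b;
                if (c1 || c2) {
                    if (c1 && c2) {
                        if (y1 > y2) ch = 1;
                        else if (y2 > y1) ch = 0;
                        else ch = (unif_rand() < 0.5) ? 1 : 0;
                    } else {
                        ch = c1 ? 1 : 0;
                    }
                    t = tm;
                    break;
                }
            }
            if (ch < 0) {
                // bound reached zero: larger activation wins, exact ties random
                if (y1 > y2) ch = 1;
                else if (y2 > y1) ch = 0;
                else ch = (unif_rand() < 0.5) ? 1 : 0;
                t = deadline;
            }
            trial[idx] = i + 1;
            choice[idx] = ch;
            dec[idx] = t;
            rt[idx] = t + t0;
        }
    }
    return List::create(_["trial"] = trial, _["choice"] = choice,
                        _["rt"] = rt, _["decision_time"] = dec);
}
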