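// Trial-level DDM log-likelihood with lapse mixture.
//
// Static bounds (theta == 0) use the analytic dual-series density.  Collapsing
// bounds dispatch to the deterministic solver; during model fitting the solver
// output is cached on a fixed parameter lattice and the density is
// multilinearly interpolated in (v, a, z, theta) and linearly in time, so the
// likelihood is continuous, deterministic, and cheap to evaluate inside MCMC.

#include "accumimic.h"
#include <cmath>
#include <unordered_map>

using namespace Rcpp;

// ---- parameter lattice (fit fidelity) --------------------------------------
static const double LAT_SV = 0.30, LAT_VMIN = -14.0, LAT_VMAX = 14.0;
static const double LAT_SA = 0.15, LAT_AMIN = 0.30, LAT_AMAX = 3.0;
static const double LAT_ST = 0.10, LAT_TMIN = 0.0, LAT_TMAX = 1.40;
static const double LAT_SZ = 0.0625, LAT_ZMIN = 0.0625, LAT_ZMAX = 0.9375;
static const double FIT_TCAP = 1.0;   // solved decision-time horizon (s)
static const double FIT_DT = 0.009;   // solver step at fit fidelity (s)
static const double FIT_CPS = 1.8;    // spatial cells per step-sd
static const size_t CACHE_MAX = 400000;

struct CornerGrid {
    float dt;
    float survival;
    std::vector<float> fu, fl;
};

static std::unordered_map<uint64_t, CornerGrid> g_cache;

static inline double clampd(double x, double lo, double hi) {
    return x < lo ? lo : (x > hi ? hi : x);
}

static const CornerGrid &corner(int iv, int ia, int it, int iz) {
    uint64_t key = (static_cast<uint64_t>(iv + 64) << 24) |
                   (static_cast<uint64_t>(ia) << 16) |
                   (static_cast<uint64_t>(it) << 8) |
                   static_cast<uint64_t>(iz);
    auto hit = g_cache.find(key);
    if (hit != g_cache.end()) return hit->second;
    if (g_cache.size() >= CACHE_MAX) g_cache.clear();
    FPTSolution s = fpt_solve_angle(iv * LAT_SV, ia * LAT_SA, iz * LAT_SZ,
                                    it * LAT_ST, FIT_TCAP, FIT_DT, FIT_CPS);
    CornerGrid g;
    g.dt = static_cast<float>(s.dt);
    g.survival = static_cast<float>(s.survival);
    g.fu.assign(s.f_upper.begin(), s.f_upper.end());
    g.fl.assign(s.f_lower.begin(), s.f_lower.end());
    return g_cache.emplace(key, std::move(g)).first->second;
}

// density at decision time td from a stored grid (midpoint linear interp)
static inline double grid_dens(const CornerGrid &g, double td, bool upper) {
    const std::vector<float> &f = upper ? g.fu : g.fl;
    int n = f.size();
    if (n == 0 || td <= 0.0) return 0.0;
    double u = td / g.dt - 0.5;
    if (u <= 0.0) return f[0] * (td / (0.5 * g.dt));
    int k = static_cast<int>(u);
    if (k >= n - 1) {
        // beyond the last midpoint: taper to zero at t_end
        double t_end = n * g.dt;
        if (td >= t_end) return 0.0;
        return f[n - 1] * (t_end - td) / (0.5 * g.dt);
    }
    double fr = u - k;
    return f[k] + (f[k + 1] - f[k]) * fr;
}

// multilinear interpolation of the collapsing-bound density over the lattice
static double angle_dens_cached(double v, double a, double z, double theta,
                                double td, bool upper) {
    v = clampd(v, LAT_VMIN, LAT_VMAX);
    a = clampd(a, LAT_AMIN, LAT_AMAX);
    theta = clampd(theta, LAT_TMIN, LAT_TMAX);
    z = clampd(z, LAT_ZMIN, LAT_ZMAX);
    double gv = v / LAT_SV, ga = a / LAT_SA, gt = theta / LAT_ST,
           gz = z / LAT_SZ;
    int iv = static_cast<int>(std::floor(gv)), ia = static_cast<int>(std::floor(ga)),
        it = static_cast<int>(std::floor(gt)), iz = static_cast<int>(std::floor(gz));
    double fv = gv - iv, fa = ga - ia, ft = gt - it, fz = gz - iz;
    double out = 0.0;
    for (int cv = 0; cv < 2; ++cv)
        for (int ca = 0; ca < 2; ++ca)
            for (int ct = 0; ct < 2; ++ct)
                for (int cz = 0; cz < 2; ++cz) {
                    double w = (cv ? fv : 1 - fv) * (ca ? fa : 1 - fa) *
                               (ct ? ft : 1 - ft) * (cz ? fz : 1 - fz);
                    if (w < 1e-12) continue;
                    out += w * grid_dens(corner(iv + cv, ia + ca, it + ct,
                                                iz + cz),
                                         td, upper);
                }
    return out;
}

static double angle_dens_exact(double v, double a, double z, double theta,
                               double td, bool upper, double t_max) {
    FPTSolution s = fpt_solve_angle(v, a, z, theta, t_max, 0.002, 12.0);
    CornerGrid g;
    g.dt = static_cast<float>(s.dt);
    g.fu.assign(s.f_upper.begin(), s.f_upper.end());
    g.fl.assign(s.f_lower.begin(), s.f_lower.end());
    return grid_dens(g, td, upper);
}

//' @noRd
// [[Rcpp::export(name = ".ddm_trial_loglik_cpp")]]
NumericVector ddm_trial_loglik_cpp(NumericVector rt, IntegerVector choice,
                                   NumericVector v, NumericVector a,
                                   NumericVector theta, NumericVector z,
                                   double t0, double p_out, double deadline,
                                   bool use_cache = true) {
    int n = rt.size();
    NumericVector out(n);
    double lapse = p_out * 0.5 / deadline;
    for (int i = 0; i < n; ++i) {
        double td = rt[i] - t0;
        bool upper = choice[i] == 1;
        double dens = 0.0;
        if (td > 1e-6) {
            if (theta[i] < 1e-8) {
                dens = upper ? wfpt_lower_pdf(td, -v[i], a[i], 1.0 - z[i], 1e-8)
                             : wfpt_lower_pdf(td, v[i], a[i], z[i], 1e-8);
            } else if (use_cache) {
                dens = angle_dens_cached(v[i], a[i], z[i], theta[i], td, upper);
            } else {
                dens = angle_dens_exact(v[i], a[i], z[i], theta[i], td, upper,
                                        deadline);
            }
        }
        double p = (1.0 - p_out) * dens + lapse;
        out[i] = std::log(p > 1e-300 ? p : 1e-300);
    }
    return out;
}

//' @noRd
// [[Rcpp::export(name = ".ddm_loglik_cpp")]]
double ddm_loglik_cpp(NumericVector rt, IntegerVector choice, NumericVector v,
                      NumericVector a, NumericVector theta, NumericVector z,
                      double t0, double p_out, double deadline,
                      bool use_cache = true) {
    NumericVector ll = ddm_trial_loglik_cpp(rt, choice, v, a, theta, z, t0,
                                            p_out, deadline, use_cache);
    double s = 0.0;
    for (int i = 0; i < ll.size(); ++i) s += ll[i];
    return s;
}

// survival (no decision by decision-time T) for the censored-likelihood option
//' @noRd
// [[Rcpp::export(name = ".ddm_survival_cpp")]]
NumericVector ddm_survival_cpp(NumericVector v, NumericVector a,
                               NumericVector theta, NumericVector z,
                               double t0, double deadline) {
    int n = v.size();
    NumericVector out(n);
    double T = deadline - t0;
    for (int i = 0; i < n; ++i) {
        FPTSolution s = fpt_solve_angle(v[i], a[i], z[i], theta[i],
                                        std::max(T, 1e-3), 0.002, 4.0);
        double absorbed = 0.0;
        int m = s.f_upper.size();
        for (int k = 0; k < m; ++k) {
            double tk = (k + 0.5) * s.dt;
            if (tk > T) break;
            absorbed += (s.f_upper[k] + s.f_lower[k]) * s.dt;
        }
        double surv = 1.0 - absorbed;
        out[i] = surv < 0.0 ? 0.0 : surv;
    }
    return out;
}

//' @noRd
// [[Rcpp::export(name = ".fpt_cache_size")]]
int fpt_cache_size() { return static_cast<int>(g_cache.size()); }

//' @noRd
// [[Rcpp::export(name = ".fpt_cache_clear")]]
void fpt_cache_clear() { g_cache.clear(); }
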