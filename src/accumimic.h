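#ifndef ACCUMIMIC_H
#define ACCUMIMIC_H

#include <Rcpp.h>
#include <vector>

// Analytic Wiener first-passage density at the LOWER boundary.
// Convention: evidence starts at w*a above the lower boundary, drift v is
// signed toward the upper boundary, unit diffusion. `t` is decision time.
double wfpt_lower_pdf(double t, double v, double a, double w, double eps);

// First-passage solution for a symmetric linearly collapsing boundary.
// Upper boundary b(t) = a/2 - t*tan(theta), lower -b(t); origin at
// (z - 0.5) * a.  Densities are reported at interval midpoints
// t_k = (k + 0.5) * dt for k = 0..n-1.
struct FPTSolution {
    double dt;
    std::vector<double> f_upper;
    std::vector<double> f_lower;
    double survival;  // unabsorbed mass at t_end
    double t_end;     // min(t_max, boundary-collision time)
    bool collapsed;   // boundary collision reached before t_max
};

FPTSolution fpt_solve_angle(double v, double a, double z, double theta,
                            double t_max, double dt, double cells_per_sigma);

#endif
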