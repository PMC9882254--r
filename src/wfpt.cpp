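// Analytic first-passage-time density for the constant-bound Wiener process,
// dual series expansion with automatic small-time / large-time selection
// (truncation chosen for relative tolerance eps).

#include "accumimic.h"
#include <cmath>

using namespace Rcpp;

double wfpt_lower_pdf(double t, double v, double a, double w, double eps) {
    if (t <= 0.0 || a <= 0.0 || w <= 0.0 || w >= 1.0) return 0.0;
    double tt = t / (a * a);  // normalised time

    // required number of terms for each expansion (Navarro-Fuss style bounds)
    double kl, ks;
    if (M_PI * tt * eps < 1.0) {
        kl = std::sqrt(-2.0 * std::log(M_PI * tt * eps) / (M_PI * M_PI * tt));
        kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
    } else {
        kl = 1.0 / (M_PI * std::sqrt(tt));
    }
    if (2.0 * std::sqrt(2.0 * M_PI * tt) * eps < 1.0) {
        ks = 2.0 + std::sqrt(-2.0 * tt *
                             std::log(2.0 * std::sqrt(2.0 * M_PI * tt) * eps));
        ks = std::max(ks, std::sqrt(tt) + 1.0);
    } else {
        ks = 2.0;
    }

    double p = 0.0;
    if (ks < kl) {  // small-time expansion
        int K = static_cast<int>(std::ceil(ks));
        int lo = static_cast<int>(-std::floor((K - 1) / 2.0));
        int hi = static_cast<int>(std::ceil((K - 1) / 2.0));
        for (int k = lo; k <= hi; ++k) {
            double wk = w + 2.0 * k;
            p += wk * std::exp(-wk * wk / (2.0 * tt));
        }
        p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
    } else {        // large-time expansion
        int K = static_cast<int>(std::ceil(kl));
        for (int k = 1; k <= K; ++k) {
            p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
                 std::sin(k * M_PI * w);
        }
        p *= M_PI;
    }
    if (p < 0.0) p = 0.0;  // series truncation can undershoot at extreme t
    return p * std::exp(-v * a * w - v * v * t / 2.0) / (a * a);
}

//' @noRd
// [[Rcpp::export(name = ".wfpt_pdf_cpp")]]
NumericVector wfpt_pdf_cpp(NumericVector t, double v, double a, double w,
                           bool upper, double eps = 1e-8) {
    int n = t.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        out[i] = upper ? wfpt_lower_pdf(t[i], -v, a, 1.0 - w, eps)
                       : wfpt_lower_pdf(t[i], v, a, w, eps);
    }
    return out;
}
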