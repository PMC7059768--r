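// Multivariate envelope mean for MEMD sifting.
//
// For each projection (column of Q) the local maxima are located
// (plateaus assigned to their midpoint), mirror-extended by two knots
// at each end, and a natural cubic spline is interpolated through the
// full p-variate signal samples at those knot times.  The direction
// envelopes are reduced on the fly to their mean m(t) and the RMS
// spread a(t) of the envelopes around the mean (the amplitude used by
// the stoppage rule): a(t)^2 = mean_v ||e_v(t)||^2 - ||m(t)||^2.
// This loop dominates the decomposition run time, hence C++.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".envelope_mean_cpp")]]
List envelope_mean_cpp(NumericMatrix Q, NumericMatrix S)
{
    const int T = Q.nrow(), V = Q.ncol(), p = S.ncol();
    int used = 0, few = 0;

    std::vector<double> msum((size_t) T * p, 0.0);  // p-major: [t*p + ch]
    std::vector<double> e2sum(T, 0.0);
    std::vector<double> ev(p);
    std::vector<int> maxidx;
    std::vector<double> xk, h, b;
    std::vector<int> src;
    std::vector<double> Yk, D, M;

    for (int v = 0; v < V; ++v) {
        const double* q = &Q(0, v);

        // --- strict local maxima with plateau-midpoint assignment ---
        maxidx.clear();
        int nmin = 0, last_sign = 0, last_idx = -1;
        for (int i = 0; i < T - 1; ++i) {
            double d = q[i + 1] - q[i];
            int s = (d > 0) - (d < 0);
            if (s == 0) continue;
            if (last_sign != 0 && s != last_sign) {
                int idx = (last_idx + 1 + i) / 2;
                if (last_sign > 0) maxidx.push_back(idx); else ++nmin;
            }
            last_sign = s;
            last_idx = i;
        }
        int nmax = (int) maxidx.size();
        if (nmax + nmin < 3) ++few;
        if (nmax < 2) continue;

        // --- mirror-extended knots (times are 1-based sample indices) ---
        xk.clear(); src.clear();
        for (int i = 1; i >= 0; --i) {
            double t = 2.0 - (maxidx[i] + 1);
            if (xk.empty() || t != xk.back()) { xk.push_back(t); src.push_back(maxidx[i]); }
        }
        for (int i = 0; i < nmax; ++i) {
            double t = maxidx[i] + 1;
            if (t != xk.back()) { xk.push_back(t); src.push_back(maxidx[i]); }
        }
        for (int i = 0; i < 2; ++i) {
            double t = 2.0 * T - (maxidx[nmax - 1 - i] + 1);
            if (t != xk.back()) { xk.push_back(t); src.push_back(maxidx[nmax - 1 - i]); }
        }
        const int k = (int) xk.size();

        // knot values for all channels, k-major per channel
        Yk.resize((size_t) k * p);
        for (int ch = 0; ch < p; ++ch)
            for (int i = 0; i < k; ++i)
                Yk[(size_t) ch * k + i] = S(src[i], ch);

        // --- natural cubic spline curvatures (Thomas, p RHS) ---
        const int nin = k - 2;
        h.resize(k - 1);
        for (int j = 0; j < k - 1; ++j) h[j] = xk[j + 1] - xk[j];
        M.assign((size_t) k * p, 0.0);
        if (nin > 0) {
            b.resize(nin);
            D.resize((size_t) nin * p);
            for (int i = 0; i < nin; ++i) {
                b[i] = 2.0 * (h[i] + h[i + 1]);
                for (int ch = 0; ch < p; ++ch) {
                    const double* y = &Yk[(size_t) ch * k];
                    D[(size_t) ch * nin + i] =
                        6.0 * ((y[i + 2] - y[i + 1]) / h[i + 1] -
                               (y[i + 1] - y[i]) / h[i]);
                }
            }
            for (int i = 1; i < nin; ++i) {
                double w = h[i] / b[i - 1];
                b[i] -= w * h[i];
                for (int ch = 0; ch < p; ++ch)
                    D[(size_t) ch * nin + i] -= w * D[(size_t) ch * nin + i - 1];
            }
            for (int ch = 0; ch < p; ++ch) {
                double* m = &M[(size_t) ch * k];
                const double* d = &D[(size_t) ch * nin];
                m[nin] = d[nin - 1] / b[nin - 1];
                for (int i = nin - 2; i >= 0; --i)
                    m[i + 1] = (d[i] - h[i + 1] * m[i + 2]) / b[i];
            }
        }

        // --- evaluate on the sample grid and accumulate moments ---
        int j = 0;
        for (int t = 0; t < T; ++t) {
            double x = t + 1;
            while (j < k - 2 && x >= xk[j + 1]) ++j;
            double hj = h[j];
            double A = (xk[j + 1] - x) / hj;
            double B = (x - xk[j]) / hj;
            double C1 = (A * A * A - A) * hj * hj / 6.0;
            double C2 = (B * B * B - B) * hj * hj / 6.0;
            double ss = 0.0;
            double* mrow = &msum[(size_t) t * p];
            for (int ch = 0; ch < p; ++ch) {
                const double* y = &Yk[(size_t) ch * k];
                const double* m = &M[(size_t) ch * k];
                double e = A * y[j] + B * y[j + 1] + C1 * m[j] + C2 * m[j + 1];
                mrow[ch] += e;
                ss += e * e;
            }
            e2sum[t] += ss;
        }
        ++used;
    }

    List res = List::create(_["used"] = used,
                            _["extrema_deficit"] = (double) few / V);
    if (used * 2 < V) return res;

    NumericMatrix mean_env(T, p);
    NumericVector amp(T);
    for (int t = 0; t < T; ++t) {
        double mm = 0.0;
        const double* mrow = &msum[(size_t) t * p];
        for (int ch = 0; ch < p; ++ch) {
            double m = mrow[ch] / used;
            mean_env(t, ch) = m;
            mm += m * m;
        }
        double a2 = e2sum[t] / used - mm;
        amp[t] = a2 > 0 ? std::sqrt(a2) : 0.0;
    }

    res["mean"] = mean_env;
    res["amplitude"] = amp;
    return res;
}
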