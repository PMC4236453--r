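#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median of the finite entries of v[0..m); NA if none
static double finite_median(std::vector<double> &buf) {
    size_t m = buf.size();
    if (m == 0) return NA_REAL;
    size_t half = m / 2;
    std::nth_element(buf.begin(), buf.begin() + half, buf.end());
    double hi = buf[half];
    if (m % 2 == 1) return hi;
    double lo = *std::max_element(buf.begin(), buf.begin() + half);
    return (lo + hi) / 2.0;
}

// average ranks (midranks for ties) of x[0..n)
static void midranks(const std::vector<double> &x, std::vector<double> &r) {
    size_t n = x.size();
    std::vector<size_t> ord(n);
    for (size_t i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](size_t a, size_t b) { return x[a] < x[b]; });
    r.resize(n);
    size_t i = 0;
    while (i < n) {
        size_t j = i;
        while (j + 1 < n && x[ord[j + 1]] == x[ord[i]]) ++j;
        double avg = (double)(i + j) / 2.0 + 1.0;
        for (size_t k = i; k <= j; ++k) r[ord[k]] = avg;
        i = j + 1;
    }
}

static double pearson(const std::vector<double> &x,
                      const std::vector<double> &y) {
    size_t n = x.size();
    double mx = 0, my = 0;
    for (size_t i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
    mx /= n; my /= n;
    double sxy = 0, sxx = 0, syy = 0;
    for (size_t i = 0; i < n; ++i) {
        double dx = x[i] - mx, dy = y[i] - my;
        sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
    }
    if (sxx <= 0 || syy <= 0) return NA_REAL;
    return sxy / std::sqrt(sxx * syy);
}

// Permutation null for the conditional-regulon statistics. For each of
// n_perm draws of k distinct genes (uniform, without replacement, the
// `exclude` index -- typically the tested TF -- never drawn) it records
// (a) the median of the genes' precomputed TF correlations and
// (b) optionally the |Spearman| correlation between the per-array
// cross-gene variance of the drawn set and the TF profile. `xset_t` is
// the arrays x genes slice (transposed for contiguous per-gene access).
// Uses R's RNG.
// [[Rcpp::export]]
List perm_null_stats(NumericVector r_all, NumericMatrix xset_t,
                     NumericVector tf_vals, int k, int n_perm,
                     bool do_disp, int exclude = -1) {
    int n_total = r_all.size();
    int a = tf_vals.size();
    if (do_disp && (xset_t.ncol() != n_total || xset_t.nrow() != a))
        stop("expression slice does not match r_all/tf profile");

    std::vector<int> idx(n_total);
    for (int i = 0; i < n_total; ++i) idx[i] = i;
    int n = n_total;
    if (exclude >= 0 && exclude < n_total) {
        std::swap(idx[exclude], idx[n_total - 1]);
        n = n_total - 1; // excluded index parked at the end, never sampled
    }
    if (k < 1 || k > n) stop("set size must lie in [1, n_genes]");

    NumericVector med(n_perm), disp(do_disp ? n_perm : 0);
    std::vector<double> buf; buf.reserve(k);
    std::vector<double> s1(a), s2(a); std::vector<int> cnt(a);
    std::vector<double> vx, vy, rx, ry;

    for (int p = 0; p < n_perm; ++p) {
        // partial Fisher-Yates: first k entries of idx become the draw
        for (int j = 0; j < k; ++j) {
            int jj = j + (int)(unif_rand() * (n - j));
            if (jj >= n) jj = n - 1;
            std::swap(idx[j], idx[jj]);
        }
        buf.clear();
        for (int j = 0; j < k; ++j) {
            double v = r_all[idx[j]];
            if (R_finite(v)) buf.push_back(v);
        }
        med[p] = finite_median(buf);

        if (do_disp) {
            std::fill(s1.begin(), s1.end(), 0.0);
            std::fill(s2.begin(), s2.end(), 0.0);
            std::fill(cnt.begin(), cnt.end(), 0);
            for (int j = 0; j < k; ++j) {
                const double *col = &xset_t(0, idx[j]);
                for (int c = 0; c < a; ++c) {
                    double v = col[c];
                    if (R_finite(v)) { s1[c] += v; s2[c] += v * v; ++cnt[c]; }
                }
            }
            vx.clear(); vy.clear();
            for (int c = 0; c < a; ++c) {
                if (cnt[c] >= 2 && R_finite(tf_vals[c])) {
                    double var = (s2[c] - s1[c] * s1[c] / cnt[c]) /
                                 (cnt[c] - 1);
                    vx.push_back(var);
                    vy.push_back(tf_vals[c]);
                }
            }
            if (vx.size() < 3) { disp[p] = NA_REAL; continue; }
            midranks(vx, rx);
            midranks(vy, ry);
            double r = pearson(rx, ry);
            disp[p] = R_finite(r) ? std::fabs(r) : NA_REAL;
        }
    }
    return List::create(_["median"] = med,
                        _["dispersion"] = disp);
}
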