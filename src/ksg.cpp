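#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// dig[i] = digamma(i), i = 1..n; precomputed once and shared across the
// shuffle loop (digamma dominates the per-evaluation cost otherwise)
static std::vector<double> digammaTable(int n) {
    std::vector<double> d((size_t)n + 1, 0.0);
    for (int i = 1; i <= n; ++i) d[i] = R::digamma((double)i);
    return d;
}

// Mixed discrete-continuous k-NN mutual information (Ross-type variant of
// the Kraskov estimator) evaluated from a pre-sorted sample. xs: values
// sorted ascending; gs: the label code of each sorted value. Samples whose
// label occurs only once must already be filtered out by the caller.
// Neighbor-counting conventions follow the reference implementation widely
// used in the field: for sample i, d_i is the distance to its k-th nearest
// neighbor among same-label samples and m_i counts all samples (self
// included) strictly inside d_i. Returns bits, clipped at zero.
static double mi_sorted(const std::vector<double>& xs, const std::vector<int>& gs,
                        int G, int k, const std::vector<double>& dig,
                        std::vector<std::vector<double> >& gx,
                        std::vector<int>& posg) {
    const int n = (int)xs.size();
    if (n < 2) return NA_REAL;
    for (int g = 0; g < G; ++g) gx[g].clear();
    posg.resize(n);
    for (int j = 0; j < n; ++j) {
        posg[j] = (int)gx[gs[j]].size();
        gx[gs[j]].push_back(xs[j]); // ascending by construction
    }
    int present = 0;
    for (int g = 0; g < G; ++g)
        if (!gx[g].empty()) present++;
    if (present < 2) return 0.0;

    double s_k = 0.0, s_c = 0.0, s_m = 0.0;
    for (int i = 0; i < n; ++i) {
        const std::vector<double>& gv = gx[gs[i]];
        const int c = (int)gv.size();
        const int kk = std::min(k, c - 1);
        const double xi = xs[i];
        int lo = posg[i] - 1, hi = posg[i] + 1;
        double d = 0.0;
        for (int t = 0; t < kk; ++t) {
            double dl = (lo >= 0) ? xi - gv[lo] : std::numeric_limits<double>::infinity();
            double dh = (hi < c) ? gv[hi] - xi : std::numeric_limits<double>::infinity();
            if (dl <= dh) {
                d = dl;
                --lo;
            } else {
                d = dh;
                ++hi;
            }
        }
        // count samples strictly inside distance d (self included); bound
        // the candidate range by binary search, then compare computed
        // distances so the k-th neighbor itself is never swept in by
        // rounding of xi +/- d
        size_t a = std::lower_bound(xs.begin(), xs.end(), xi - d) - xs.begin();
        if (a > 0) --a;
        size_t b = std::upper_bound(xs.begin(), xs.end(), xi + d) - xs.begin();
        if (b < xs.size()) ++b;
        int m = 0;
        for (size_t j = a; j < b; ++j)
            if (std::fabs(xs[j] - xi) < d) ++m;
        s_k += dig[kk];
        s_c += dig[c];
        s_m += dig[m > 0 ? m : 1];
    }
    double mi = dig[n] + (s_k - s_c - s_m) / (double)n;
    mi /= std::log(2.0);
    return mi > 0.0 ? mi : 0.0;
}

// Sort once, then score against one label set: filter out singleton-label
// samples, project the shared sort order onto the filtered sample and call
// mi_sorted.
static double mi_one_label(const std::vector<double>& xsort_all,
                           const std::vector<int>& ord,
                           const std::vector<int>& y, int G, int k,
                           const std::vector<double>& dig,
                           std::vector<double>& xs_buf, std::vector<int>& gs_buf,
                           std::vector<std::vector<double> >& gx,
                           std::vector<int>& posg) {
    const int n0 = (int)xsort_all.size();
    std::vector<int> cnt(G, 0);
    for (int i = 0; i < n0; ++i) cnt[y[i]]++;
    xs_buf.clear();
    gs_buf.clear();
    for (int j = 0; j < n0; ++j) {
        const int g = y[ord[j]];
        if (cnt[g] > 1) {
            xs_buf.push_back(xsort_all[j]);
            gs_buf.push_back(g);
        }
    }
    return mi_sorted(xs_buf, gs_buf, G, k, dig, gx, posg);
}

// [[Rcpp::export]]
double ksg_mi_cpp(NumericVector x, IntegerVector y, int k) {
    const int n = x.size();
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return x[a] < x[b]; });
    std::vector<double> xsort(n);
    for (int j = 0; j < n; ++j) xsort[j] = x[ord[j]];
    int G = 0;
    std::vector<int> yv(y.begin(), y.end());
    for (int i = 0; i < n; ++i) G = std::max(G, yv[i] + 1);
    std::vector<double> dig = digammaTable(n);
    std::vector<double> xs_buf;
    std::vector<int> gs_buf, posg;
    std::vector<std::vector<double> > gx(G);
    return mi_one_label(xsort, ord, yv, G, k, dig, xs_buf, gs_buf, gx, posg);
}

// Null MI distributions from circular rotations of one event train, scored
// against several label sets at once. For each offset the 0-based event
// frames are rotated modulo n_frames, reconvolved with the (unit-sum)
// Gaussian kernel scaled by frame_rate, tie-broken with Gaussian jitter of
// sd jitter_sd (drawn from R's RNG), sorted once, and scored against every
// column of y. Returns an offsets x labels matrix of null MIS values (bits).
// [[Rcpp::export]]
NumericMatrix shuffle_null_multi_cpp(IntegerVector event_frames, int n_frames,
                                     IntegerMatrix y, NumericVector kernel,
                                     int kernel_center, double frame_rate,
                                     IntegerVector offsets, int k,
                                     double jitter_sd) {
    const int S = offsets.size();
    const int n = n_frames;
    const int L = y.ncol();
    const int Lk = kernel.size();
    const int ne = event_frames.size();
    NumericMatrix out(S, L);

    int G = 0;
    std::vector<std::vector<int> > yv(L, std::vector<int>(n));
    for (int l = 0; l < L; ++l)
        for (int i = 0; i < n; ++i) {
            yv[l][i] = y(i, l);
            G = std::max(G, y(i, l) + 1);
        }

    std::vector<double> dig = digammaTable(n);
    std::vector<double> rate((size_t)n), xsort((size_t)n), xs_buf;
    std::vector<int> ord((size_t)n), gs_buf, posg;
    std::vector<std::vector<double> > gx(G);

    for (int s = 0; s < S; ++s) {
        std::fill(rate.begin(), rate.end(), 0.0);
        const int off = offsets[s];
        for (int e = 0; e < ne; ++e) {
            int f = (event_frames[e] + off) % n;
            if (f < 0) f += n;
            for (int j = 0; j < Lk; ++j) {
                const int t = f + j - kernel_center;
                if (t >= 0 && t < n) rate[t] += kernel[j] * frame_rate;
            }
        }
        if (jitter_sd > 0.0)
            for (int t = 0; t < n; ++t) rate[t] += jitter_sd * norm_rand();
        for (int i = 0; i < n; ++i) ord[i] = i;
        std::sort(ord.begin(), ord.end(),
                  [&](int a, int b) { return rate[a] < rate[b]; });
        for (int j = 0; j < n; ++j) xsort[j] = rate[ord[j]];
        for (int l = 0; l < L; ++l)
            out(s, l) = mi_one_label(xsort, ord, yv[l], G, k, dig, xs_buf,
                                     gs_buf, gx, posg);
    }
    return out;
}
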