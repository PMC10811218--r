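#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR/FIR filter of one signal (a[0] assumed 1).
static void df2t_filter(const std::vector<double>& b, const std::vector<double>& a,
                        std::vector<double>& x) {
    const int nb = b.size(), na = a.size();
    const int nz = std::max(nb, na) - 1;
    if (nz == 0) {
        for (size_t t = 0; t < x.size(); ++t) x[t] *= b[0];
        return;
    }
    std::vector<double> z(nz, 0.0);
    for (size_t t = 0; t < x.size(); ++t) {
        const double xt = x[t];
        const double yt = b[0] * xt + z[0];
        for (int k = 0; k < nz - 1; ++k) {
            const double bk = (k + 1 < nb) ? b[k + 1] : 0.0;
            const double ak = (k + 1 < na) ? a[k + 1] : 0.0;
            z[k] = bk * xt + z[k + 1] - ak * yt;
        }
        const double bl = (nz < nb) ? b[nz] : 0.0;
        const double al = (nz < na) ? a[nz] : 0.0;
        z[nz - 1] = bl * xt - al * yt;
        x[t] = yt;
    }
}

// Zero-phase (forward-backward) filtering of each column of x.
// Columns are extended by odd-symmetric reflection of `pad` samples at both
// ends before filtering, which suppresses start-up transients at the epoch
// edges; pad is clipped to n - 1.
// [[Rcpp::export(name = ".zerophase_filter_cpp")]]
NumericMatrix zerophase_filter_cpp(NumericVector b, NumericVector a,
                                   NumericMatrix x, int pad) {
    const int n = x.nrow(), nc = x.ncol();
    if (n < 2) stop("signal too short to filter");
    if (pad > n - 1) pad = n - 1;
    if (pad < 0) pad = 0;
    std::vector<double> bv(b.begin(), b.end()), av(a.begin(), a.end());
    if (av.empty() || av[0] == 0.0) stop("invalid denominator coefficients");
    if (av[0] != 1.0) { // normalise
        for (auto& c : bv) c /= av[0];
        for (auto& c : av) c /= av[0];
    }
    NumericMatrix out(n, nc);
    std::vector<double> ext(n + 2 * pad);
    for (int j = 0; j < nc; ++j) {
        for (int t = 0; t < pad; ++t)
            ext[t] = 2.0 * x(0, j) - x(pad - t, j);
        for (int t = 0; t < n; ++t) ext[pad + t] = x(t, j);
        for (int t = 0; t < pad; ++t)
            ext[pad + n + t] = 2.0 * x(n - 1, j) - x(n - 2 - t, j);
        df2t_filter(bv, av, ext);
        std::reverse(ext.begin(), ext.end());
        df2t_filter(bv, av, ext);
        std::reverse(ext.begin(), ext.end());
        for (int t = 0; t < n; ++t) out(t, j) = ext[pad + t];
    }
    return out;
}
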