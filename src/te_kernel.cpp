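#include <Rcpp.h>
using namespace Rcpp;

// Box-kernel (Heaviside, max-norm) plug-in transfer entropy, history k.
// Inputs are z-normalised series; radius r is in sd units. Probabilities are
// the fractions of embedded sample points within the closed max-norm ball of
// radius r around each query point, in the 1-, (k+1)- and (k+2)-dimensional
// embedding spaces. Points at distance exactly r count as inside, so results
// are bit-reproducible. Counts include the query point itself, hence are
// never zero. Returned in bits (log base 2).

static double te_pair(const double* x, const double* y, int t, int k,
                      double r) {
    const int N = t - k;  // embedded observations: n = k .. t-1 (0-based)
    double sum = 0.0;
    for (int a = 0; a < N; ++a) {
        const int ia = a + k;
        int c1 = 0, c2t = 0, c2p = 0, c3 = 0;
        for (int b = 0; b < N; ++b) {
            const int ib = b + k;
            bool past = true;  // target history within r in all k lags
            for (int l = 1; l <= k && past; ++l)
                past = std::abs(y[ib - l] - y[ia - l]) <= r;
            if (!past) continue;
            const bool cur = std::abs(y[ib] - y[ia]) <= r;
            const bool src = std::abs(x[ib - 1] - x[ia - 1]) <= r;
            ++c1;
            if (cur) ++c2t;
            if (src) ++c2p;
            if (cur && src) ++c3;
        }
        sum += std::log2((double)c3 * (double)c1 /
                         ((double)c2t * (double)c2p));
    }
    return sum / N;
}

// [[Rcpp::export(name = ".teKernelCpp")]]
double teKernelCpp(NumericVector x, NumericVector y, int history,
                   double radius) {
    return te_pair(x.begin(), y.begin(), x.size(), history, radius);
}

// All ordered pairs for a community. z: t x n matrix of z-normalised series
// (columns = OTUs); zeroVar flags constant series, which give TE 0 in both
// directions by convention.
// [[Rcpp::export(name = ".teMatrixCpp")]]
NumericMatrix teMatrixCpp(NumericMatrix z, LogicalVector zeroVar, int history,
                          double radius) {
    const int n = z.ncol(), t = z.nrow();
    NumericMatrix out(n, n);
    std::fill(out.begin(), out.end(), NA_REAL);
    for (int i = 0; i < n; ++i) {
        for (int j = 0; j < n; ++j) {
            if (i == j) continue;
            if (zeroVar[i] || zeroVar[j]) {
                out(i, j) = 0.0;
            } else {
                out(i, j) = te_pair(&z(0, i), &z(0, j), t, history, radius);
            }
        }
        Rcpp::checkUserInterrupt();
    }
    return out;
}

// Surrogate TE estimates: TE(perm(x) -> y) for each column of perms, where
// perms holds permuted copies of the (normalised) source series.
// [[Rcpp::export(name = ".teSurrogatesCpp")]]
NumericVector teSurrogatesCpp(NumericMatrix perms, NumericVector y,
                              int history, double radius) {
    const int n = perms.ncol(), t = perms.nrow();
    NumericVector out(n);
    for (int s = 0; s < n; ++s) {
        out[s] = te_pair(&perms(0, s), y.begin(), t, history, radius);
        Rcpp::checkUserInterrupt();
    }
    return out;
}
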