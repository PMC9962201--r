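#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise global alignment (Needleman-Wunsch / Gotoh).
// Gap of length L costs open + L * ext (EMBOSS-needle convention).
// With free_ends, terminal gap runs in either sequence cost nothing
// (ends-free / "overlap" alignment).
//
// Three-state DP:
//   M[i][j] best score with a[i] aligned to b[j]
//   X[i][j] best score with a[i] aligned to a gap (gap in b)
//   Y[i][j] best score with b[j] aligned to a gap (gap in a)
// Tie-breaking prefers M (residue column), then Y (gap in a), then X.

static const double NEG_INF = -1e30;
static const double EPS = 1e-9;

// preference order M(0) > Y(2) > X(1) among values within EPS of the max
static inline int argmax3(double m, double x, double y) {
    double best = std::max({m, x, y});
    if (m >= best - EPS) return 0;
    if (y >= best - EPS) return 2;
    return 1;
}

// [[Rcpp::export(name = ".nw_align")]]
List nw_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
              double gap_open, double gap_ext, bool free_ends) {
    const int m = a.size(), n = b.size();
    const double go = gap_open + gap_ext;  // cost of first gapped column

    typedef std::vector<std::vector<double>> Mat;
    typedef std::vector<std::vector<signed char>> PMat;
    Mat M(m + 1, std::vector<double>(n + 1, NEG_INF)), X = M, Y = M;
    PMat pM(m + 1, std::vector<signed char>(n + 1, -1)), pX = pM, pY = pM;

    M[0][0] = 0.0;
    for (int i = 1; i <= m; ++i) {
        X[i][0] = free_ends ? 0.0 : -(gap_open + i * gap_ext);
        pX[i][0] = (i == 1) ? 0 : 1;  // opens from M[0][0], then extends
    }
    for (int j = 1; j <= n; ++j) {
        Y[0][j] = free_ends ? 0.0 : -(gap_open + j * gap_ext);
        pY[0][j] = (j == 1) ? 0 : 2;
    }

    for (int i = 1; i <= m; ++i) {
        for (int j = 1; j <= n; ++j) {
            double s = sub(a[i - 1], b[j - 1]);
            pM[i][j] = (signed char) argmax3(M[i - 1][j - 1], X[i - 1][j - 1],
                                             Y[i - 1][j - 1]);
            M[i][j] = s + std::max({M[i - 1][j - 1], X[i - 1][j - 1], Y[i - 1][j - 1]});
            pX[i][j] = (signed char) argmax3(M[i - 1][j] - go, X[i - 1][j] - gap_ext,
                                             Y[i - 1][j] - go);
            X[i][j] = std::max({M[i - 1][j] - go, X[i - 1][j] - gap_ext,
                                Y[i - 1][j] - go});
            pY[i][j] = (signed char) argmax3(M[i][j - 1] - go, X[i][j - 1] - go,
                                             Y[i][j - 1] - gap_ext);
            Y[i][j] = std::max({M[i][j - 1] - go, X[i][j - 1] - go,
                                Y[i][j - 1] - gap_ext});
        }
    }

    // End cell: (m, n) for strict global; with free ends the best over the
    // last row and column (the remaining overhang costs nothing).
    int ei = m, ej = n;
    double best = std::max({M[m][n], X[m][n], Y[m][n]});
    if (free_ends) {
        for (int i = m; i >= 0; --i) {
            double v = std::max({M[i][n], X[i][n], Y[i][n]});
            if (v > best + EPS) { best = v; ei = i; ej = n; }
        }
        for (int j = n; j >= 0; --j) {
            double v = std::max({M[m][j], X[m][j], Y[m][j]});
            if (v > best + EPS) { best = v; ei = m; ej = j; }
        }
    }

    // Traceback via pointers; emit columns reversed.
    std::vector<int> ca, cb;  // residue index + 1, or 0 for gap
    int i = ei, j = ej;
    int state = argmax3(M[i][j], X[i][j], Y[i][j]);
    while (i > 0 || j > 0) {
        if (state == 0) {
            ca.push_back(i); cb.push_back(j);
            state = pM[i][j]; --i; --j;
        } else if (state == 1) {
            ca.push_back(i); cb.push_back(0);
            state = pX[i][j]; --i;
        } else {
            ca.push_back(0); cb.push_back(j);
            state = pY[i][j]; --j;
        }
    }
    std::reverse(ca.begin(), ca.end());
    std::reverse(cb.begin(), cb.end());

    // Free-end overhang beyond (ei, ej).
    for (int k = ei + 1; k <= m; ++k) { ca.push_back(k); cb.push_back(0); }
    for (int k = ej + 1; k <= n; ++k) { ca.push_back(0); cb.push_back(k); }

    int L = (int) ca.size();
    IntegerVector ia(L), ib(L);
    for (int k = 0; k < L; ++k) {
        ia[k] = ca[k] == 0 ? NA_INTEGER : a[ca[k] - 1];
        ib[k] = cb[k] == 0 ? NA_INTEGER : b[cb[k] - 1];
    }
    return List::create(_["score"] = best, _["a"] = ia, _["b"] = ib);
}

// Brute-force reference: recursively enumerate every global alignment and
// return the maximum affine-gap score. Exponential; short sequences only.
// Algorithmically independent of the Gotoh DP above (no tables), so it can
// serve as an oracle in tests.
static double enum_rec(const IntegerVector &a, const IntegerVector &b,
                       const NumericMatrix &sub, int i, int j, int last,
                       double gap_open, double gap_ext, bool free_ends) {
    const int m = a.size(), n = b.size();
    if (i == m && j == n) return 0.0;
    double best = NEG_INF;
    if (i < m && j < n) {
        best = std::max(best, sub(a[i], b[j]) +
            enum_rec(a, b, sub, i + 1, j + 1, 0, gap_open, gap_ext, free_ends));
    }
    if (i < m) {  // a[i] against a gap (gap in b); terminal while j==0 or j==n
        bool terminal = free_ends && (j == 0 || j == n);
        double c = terminal ? 0.0 : ((last == 1) ? gap_ext : gap_open + gap_ext);
        best = std::max(best, -c +
            enum_rec(a, b, sub, i + 1, j, 1, gap_open, gap_ext, free_ends));
    }
    if (j < n) {  // gap in a; terminal while i==0 or i==m
        bool terminal = free_ends && (i == 0 || i == m);
        double c = terminal ? 0.0 : ((last == 2) ? gap_ext : gap_open + gap_ext);
        best = std::max(best, -c +
            enum_rec(a, b, sub, i, j + 1, 2, gap_open, gap_ext, free_ends));
    }
    return best;
}

// [[Rcpp::export(name = ".enum_align_score")]]
double enum_align_score(IntegerVector a, IntegerVector b, NumericMatrix sub,
                        double gap_open, double gap_ext, bool free_ends) {
    return enum_rec(a, b, sub, 0, 0, 0, gap_open, gap_ext, free_ends);
}
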