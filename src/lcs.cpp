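#include <Rcpp.h>
using namespace Rcpp;

// Longest common subsequence length of two integer label sequences,
// classic O(nm) dynamic programme with a rolling row.
static int lcs_len(const int* x, int n, const int* y, int m) {
    if (n == 0 || m == 0) return 0;
    std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            if (x[i - 1] == y[j - 1]) {
                cur[j] = prev[j - 1] + 1;
            } else {
                cur[j] = std::max(prev[j], cur[j - 1]);
            }
        }
        std::swap(prev, cur);
    }
    return prev[m];
}

// [[Rcpp::export]]
int lcs_length_cpp(IntegerVector x, IntegerVector y) {
    return lcs_len(INTEGER(x), x.size(), INTEGER(y), y.size());
}

// Pairwise LCS distance d(x, y) = |x| + |y| - 2 * LCS(x, y) over the rows
// of a label matrix.
// [[Rcpp::export]]
NumericMatrix lcs_distance_matrix_cpp(IntegerMatrix labels) {
    int n = labels.nrow(), L = labels.ncol();
    // copy rows to contiguous buffers (IntegerMatrix is column-major)
    std::vector<std::vector<int>> rows(n, std::vector<int>(L));
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < L; ++j) rows[i][j] = labels(i, j);
    NumericMatrix d(n, n);
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            int l = lcs_len(rows[i].data(), L, rows[j].data(), L);
            double dij = 2.0 * (L - l);
            d(i, j) = dij;
            d(j, i) = dij;
        }
    }
    return d;
}
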