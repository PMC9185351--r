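#include <Rcpp.h>
using namespace Rcpp;

// Maximal number of matched identical residues over all global alignments
// with match=1, mismatch=0, gap=0 scoring. Under that scoring the optimum
// equals the longest-common-subsequence length (two-row DP).
static int lcs_len(const std::string& a, const std::string& b) {
    const int n = a.size(), m = b.size();
    if (n == 0 || m == 0) return 0;
    std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
    for (int i = 1; i <= n; ++i) {
        const char ai = a[i - 1];
        for (int j = 1; j <= m; ++j) {
            cur[j] = (ai == b[j - 1]) ? prev[j - 1] + 1
                                      : std::max(prev[j], cur[j - 1]);
        }
        std::swap(prev, cur);
    }
    return prev[m];
}

// [[Rcpp::export]]
IntegerVector lcs_matches(std::string a, std::vector<std::string> b) {
    const int n = b.size();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) out[i] = lcs_len(a, b[i]);
    return out;
}
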