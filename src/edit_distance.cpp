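#include <Rcpp.h>
#include <cstdlib>
#include <string>
#include <vector>

using namespace Rcpp;

// Unit-cost Levenshtein distance with a diagonal band of half-width
// `max_dist` and row-minimum early exit.  Returns max_dist + 1 as soon as
// the true distance provably exceeds max_dist.
static int lev_banded(const std::string& a, const std::string& b, int max_dist) {
    const int m = (int)a.size();
    const int n = (int)b.size();
    if (std::abs(m - n) > max_dist) return max_dist + 1;
    const int INF = max_dist + 1;
    std::vector<int> prev(n + 1, INF), cur(n + 1, INF);
    for (int j = 0; j <= std::min(n, max_dist); ++j) prev[j] = j;
    for (int i = 1; i <= m; ++i) {
        const int lo = std::max(1, i - max_dist);
        const int hi = std::min(n, i + max_dist);
        std::fill(cur.begin(), cur.end(), INF);
        if (lo == 1 && i <= max_dist) cur[0] = i;
        int rowmin = cur[0];
        for (int j = lo; j <= hi; ++j) {
            int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
            int del = prev[j] + 1;
            int ins = cur[j - 1] + 1;
            int v = sub < del ? sub : del;
            if (ins < v) v = ins;
            if (v > INF) v = INF;
            cur[j] = v;
            if (v < rowmin) rowmin = v;
        }
        if (rowmin > max_dist) return INF;
        prev.swap(cur);
    }
    return prev[n] > max_dist ? INF : prev[n];
}

// [[Rcpp::export(name = ".lev_dist_cpp")]]
IntegerVector lev_dist_cpp(CharacterVector a, CharacterVector b) {
    if (a.size() != b.size())
        stop("'a' and 'b' must have the same length");
    const R_xlen_t n = a.size();
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string sa = as<std::string>(a[i]);
        std::string sb = as<std::string>(b[i]);
        int cap = (int)std::max(sa.size(), sb.size());
        out[i] = lev_banded(sa, sb, cap);
    }
    return out;
}

// All unordered pairs (i, j), i < j, of `vocab` with 1 <= d <= max_dist.
// Returns 1-based index pairs plus the exact distance.
// [[Rcpp::export(name = ".neighbor_pairs_cpp")]]
List neighbor_pairs_cpp(CharacterVector vocab, int max_dist) {
    const int n = vocab.size();
    std::vector<std::string> v(n);
    for (int i = 0; i < n; ++i) v[i] = as<std::string>(vocab[i]);
    std::vector<int> ia, ja, da;
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            if (std::abs((int)v[i].size() - (int)v[j].size()) > max_dist)
                continue;
            int d = lev_banded(v[i], v[j], max_dist);
            if (d >= 1 && d <= max_dist) {
                ia.push_back(i + 1);
                ja.push_back(j + 1);
                da.push_back(d);
            }
        }
    }
    return List::create(_["i"] = wrap(ia), _["j"] = wrap(ja),
                        _["d"] = wrap(da));
}
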