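#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Running-sum enrichment score from sorted 0-based member positions.
// w holds the per-gene hit weights (|score|^p) for the whole ranked list;
// hit increments are normalized by the sum of weights over the member
// positions (equal weights if that sum is zero), misses decrement by
// 1/(L - k). ES is the signed maximum deviation from zero; extremes occur
// immediately after a hit (peaks) or immediately before one (troughs), the
// prefix before the first hit and the tail ending at zero being covered by
// those candidates.
static double es_from_sorted_positions(const std::vector<double>& w,
                                       const std::vector<int>& pos) {
    const int L = static_cast<int>(w.size());
    const int k = static_cast<int>(pos.size());
    double sumw = 0.0;
    for (int i = 0; i < k; ++i) sumw += w[pos[i]];
    const bool equal = (sumw <= 0.0);
    const double d = (L > k) ? 1.0 / (L - k) : 0.0;
    double cum = 0.0, mx = 0.0, mn = 0.0;
    for (int i = 0; i < k; ++i) {
        const double missDrop = (pos[i] - i) * d;
        const double before = cum - missDrop;
        if (before < mn) mn = before;
        cum += equal ? 1.0 / k : w[pos[i]] / sumw;
        const double after = cum - missDrop;
        if (after > mx) mx = after;
    }
    return (mx >= -mn) ? mx : mn;
}

// [[Rcpp::export]]
double cppEsFromPositions(NumericVector w, IntegerVector pos0) {
    std::vector<double> wv(w.begin(), w.end());
    std::vector<int> pv(pos0.begin(), pos0.end());
    std::sort(pv.begin(), pv.end());
    return es_from_sorted_positions(wv, pv);
}

// Null enrichment scores for B gene-label permutations: each draw places
// the k member labels uniformly at random (without replacement) on the
// ranked list. Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector cppGseaNull(NumericVector w, int k, int B) {
    const int L = w.size();
    if (k < 1 || k > L) stop("need 1 <= k <= length(w)");
    std::vector<double> wv(w.begin(), w.end());
    std::vector<int> arr(L);
    std::iota(arr.begin(), arr.end(), 0);
    std::vector<int> pos(k);
    std::vector<int> swapped(k);
    NumericVector out(B);
    for (int b = 0; b < B; ++b) {
        for (int i = 0; i < k; ++i) {
            int j = i + static_cast<int>(unif_rand() * (L - i));
            if (j >= L) j = L - 1;
            std::swap(arr[i], arr[j]);
            swapped[i] = j;
            pos[i] = arr[i];
        }
        std::sort(pos.begin(), pos.end());
        out[b] = es_from_sorted_positions(wv, pos);
        for (int i = k - 1; i >= 0; --i) std::swap(arr[i], arr[swapped[i]]);
    }
    return out;
}
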