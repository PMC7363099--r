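#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Merge sort over y[lo, hi), counting strict inversions (pairs out of
// order).  Equal elements are taken from the left half first, so ties
// contribute no inversions.
static double mergeCount(std::vector<double>& y, std::vector<double>& buf,
                         int lo, int hi) {
    if (hi - lo < 2) return 0.0;
    int mid = (lo + hi) / 2;
    double inv = mergeCount(y, buf, lo, mid) + mergeCount(y, buf, mid, hi);
    int i = lo, j = mid, k = lo;
    while (i < mid && j < hi) {
        if (y[j] < y[i]) { inv += mid - i; buf[k++] = y[j++]; }
        else             { buf[k++] = y[i++]; }
    }
    while (i < mid) buf[k++] = y[i++];
    while (j < hi)  buf[k++] = y[j++];
    std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
    return inv;
}

// Knight-style O(n log n) concordant/discordant pair counting.
//
// Sort observations by (x, y); pairs tied in x are then in ascending y
// order and contribute no inversions.  Counting strict inversions of the
// y sequence with a merge sort yields exactly the discordant pairs.  Tie
// pair counts (in x, in y, in both) are read off run lengths, and
//   nc = n(n-1)/2 - tx - ty + txy - nd
// excludes pairs tied in either coordinate from both counts.
// [[Rcpp::export(name = ".kendall_counts")]]
List kendall_counts(NumericVector x, NumericVector y) {
    int n = x.size();
    if (y.size() != n) stop("'x' and 'y' must have equal length");
    if (n < 2) stop("need at least two observations");

    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        if (x[a] != x[b]) return x[a] < x[b];
        return y[a] < y[b];
    });

    // tie pair counts from run lengths in the (x, y)-sorted sequence
    double tx = 0.0, txy = 0.0;
    {
        double runx = 1.0, runxy = 1.0;
        for (int i = 1; i < n; ++i) {
            int a = ord[i - 1], b = ord[i];
            if (x[a] == x[b]) { runx += 1.0; } else { tx += runx * (runx - 1.0) / 2.0; runx = 1.0; }
            if (x[a] == x[b] && y[a] == y[b]) { runxy += 1.0; } else { txy += runxy * (runxy - 1.0) / 2.0; runxy = 1.0; }
        }
        tx += runx * (runx - 1.0) / 2.0;
        txy += runxy * (runxy - 1.0) / 2.0;
    }

    std::vector<double> ys(n), buf(n);
    for (int i = 0; i < n; ++i) ys[i] = y[ord[i]];
    double nd = mergeCount(ys, buf, 0, n);   // ys now sorted

    double ty = 0.0;
    {
        double run = 1.0;
        for (int i = 1; i < n; ++i) {
            if (ys[i] == ys[i - 1]) run += 1.0;
            else { ty += run * (run - 1.0) / 2.0; run = 1.0; }
        }
        ty += run * (run - 1.0) / 2.0;
    }

    double n0 = (double)n * (n - 1.0) / 2.0;
    double nc = n0 - tx - ty + txy - nd;
    return List::create(_["nc"] = nc, _["nd"] = nd,
                        _["tiedX"] = tx, _["tiedY"] = ty, _["tiedXY"] = txy);
}
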