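#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Approximate matching of probe windows against a genome sequence.
//
// A "hit" is a text position at which a whole pattern window aligns with
// edit distance <= max_edits (substitutions, insertions, deletions).  Hits
// are reported as 0-based exclusive end positions in the text; the caller
// converts ends to intervals and merges overlapping ones into loci.
//
// Two independent routes are provided:
//   cm_scan_ends  - full Sellers semi-global DP over the whole text
//                   (simple, exhaustive; used as the test oracle)
//   cm_seed_ends  - pigeonhole seed-and-verify with banded DP verification
//                   (the production path; provably reports the same end set)

// Sellers DP restricted to text[seg_start, seg_end): row 0 is all zeros
// (free alignment start), so D[m][j] is the minimum edit distance of the
// pattern against any text substring ending at absolute position j.
static void sellers_segment(const std::string& pat, const std::string& text,
                            int max_edits, int seg_start, int seg_end,
                            std::unordered_set<int>& ends) {
    const int m = (int)pat.size();
    const int n = seg_end - seg_start;
    if (n <= 0) return;
    std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
    for (int i = 1; i <= m; ++i) {
        cur[0] = i;
        const char pc = pat[i - 1];
        for (int j = 1; j <= n; ++j) {
            int d = prev[j - 1] + (pc != text[seg_start + j - 1]);
            int del = prev[j] + 1;
            if (del < d) d = del;
            int ins = cur[j - 1] + 1;
            if (ins < d) d = ins;
            cur[j] = d;
        }
        std::swap(prev, cur);
    }
    for (int j = 1; j <= n; ++j)
        if (prev[j] <= max_edits) ends.insert(seg_start + j);
}

// [[Rcpp::export(name = ".cm_scan_ends")]]
List cm_scan_ends(CharacterVector windows, std::string text, int max_edits) {
    const int n = (int)text.size();
    List out(windows.size());
    for (R_xlen_t w = 0; w < windows.size(); ++w) {
        std::string pat = as<std::string>(windows[w]);
        std::unordered_set<int> ends;
        sellers_segment(pat, text, max_edits, 0, n, ends);
        std::vector<int> v(ends.begin(), ends.end());
        std::sort(v.begin(), v.end());
        out[w] = IntegerVector(v.begin(), v.end());
    }
    return out;
}

static inline int base_code(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
    }
}

// Banded verification anchored at an exact seed match: the pattern offset o
// aligns to text position q, so every cell of a <= max_edits alignment path
// lies within max_edits diagonals of d0 = q - o.  Reports absolute end
// positions with banded distance <= max_edits; banded distance >= true
// distance, so every report is sound, and every true alignment through this
// anchor stays inside the band, so the union over anchors is complete.
static void banded_verify(const std::string& pat, const std::string& text,
                          int max_edits, int d0,
                          std::unordered_set<int>& ends) {
    const int m = (int)pat.size();
    const int n = (int)text.size();
    const int k = max_edits;
    const int INF = m + n + 1;
    // cell (i, j): pattern prefix i, text position j = i + d0 + b, b in [-k, k]
    std::vector<int> prev(2 * k + 1, 0), cur(2 * k + 1, INF);
    // row 0: free start anywhere -> 0 where j in range, INF where j < 0
    for (int b = -k; b <= k; ++b) {
        int j = 0 + d0 + b;
        prev[b + k] = (j >= 0 && j <= n) ? 0 : INF;
    }
    for (int i = 1; i <= m; ++i) {
        int rowmin = INF;
        for (int b = -k; b <= k; ++b) {
            int j = i + d0 + b;
            if (j < 0 || j > n) { cur[b + k] = INF; continue; }
            int d = INF;
            // diagonal (sub/match): prev row, same b
            if (prev[b + k] < INF) {
                int sub = prev[b + k] + (j >= 1 ? (pat[i - 1] != text[j - 1]) : 1);
                if (j >= 1 && sub < d) d = sub;
            }
            // deletion from pattern: prev row, b+1
            if (b + 1 <= k && prev[b + 1 + k] < INF) {
                int del = prev[b + 1 + k] + 1;
                if (del < d) d = del;
            }
            // insertion into pattern: cur row, b-1
            if (b - 1 >= -k && cur[b - 1 + k] < INF) {
                int ins = cur[b - 1 + k] + 1;
                if (ins < d) d = ins;
            }
            cur[b + k] = d;
            if (d < rowmin) rowmin = d;
        }
        std::swap(prev, cur);
        if (rowmin > k) return;  // no path can recover
    }
    for (int b = -k; b <= k; ++b) {
        int j = m + d0 + b;
        if (j >= 1 && j <= n && prev[b + k] <= k) ends.insert(j);
    }
}

// [[Rcpp::export(name = ".cm_seed_ends")]]
List cm_seed_ends(CharacterVector windows, std::string text, int max_edits,
                  int seed_len) {
    const int n = (int)text.size();
    // exact seed index over the text
    std::unordered_map<uint32_t, std::vector<int> > index;
    if (n >= seed_len) {
        uint32_t code = 0, mask = (1u << (2 * seed_len)) - 1u;
        int run = 0;
        for (int i = 0; i < n; ++i) {
            int c = base_code(text[i]);
            if (c < 0) { run = 0; code = 0; continue; }
            code = ((code << 2) | (uint32_t)c) & mask;
            if (++run >= seed_len) index[code].push_back(i - seed_len + 1);
        }
    }
    List out(windows.size());
    for (R_xlen_t w = 0; w < windows.size(); ++w) {
        std::string pat = as<std::string>(windows[w]);
        const int m = (int)pat.size();
        std::unordered_set<int> ends;
        std::unordered_set<int> anchors_seen;
        // non-overlapping seeds at offsets 0, seed_len, 2*seed_len, ...
        // (max_edits + 1 pieces guarantee one exact seed by pigeonhole when
        //  seed_len <= m / (max_edits + 1))
        for (int o = 0; o + seed_len <= m; o += seed_len) {
            uint32_t code = 0;
            bool ok = true;
            for (int t = 0; t < seed_len; ++t) {
                int c = base_code(pat[o + t]);
                if (c < 0) { ok = false; break; }
                code = (code << 2) | (uint32_t)c;
            }
            if (!ok) continue;
            std::unordered_map<uint32_t, std::vector<int> >::const_iterator it =
                index.find(code);
            if (it == index.end()) continue;
            for (size_t h = 0; h < it->second.size(); ++h) {
                int q = it->second[h];
                int d0 = q - o;  // anchor diagonal
                if (anchors_seen.insert(d0).second)
                    banded_verify(pat, text, max_edits, d0, ends);
            }
        }
        std::vector<int> v(ends.begin(), ends.end());
        std::sort(v.begin(), v.end());
        out[w] = IntegerVector(v.begin(), v.end());
    }
    return out;
}
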