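#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

static inline int b2i(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// DUST triplet score of window [start, start+wlen): sum c_t(c_t-1)/2 over the
// counted trinucleotides, divided by (L - 1) where L = number of counted
// (N-free) trinucleotides. Windows with fewer than 2 counted triplets score 0.
static double window_score(const std::string& s, int start, int wlen) {
    int counts[64];
    std::memset(counts, 0, sizeof(counts));
    int L = 0;
    for (int i = start; i + 3 <= start + wlen; ++i) {
        int a = b2i(s[i]), b = b2i(s[i + 1]), c = b2i(s[i + 2]);
        if (a < 0 || b < 0 || c < 0) continue;
        ++counts[(a << 4) | (b << 2) | c];
        ++L;
    }
    if (L < 2) return 0.0;
    double sum = 0.0;
    for (int t = 0; t < 64; ++t) sum += counts[t] * (counts[t] - 1) / 2.0;
    return sum / (L - 1);
}

// returns merged masked intervals (0-based half-open) for one sequence
static void dust_intervals(const std::string& s, int window, double level,
                           std::vector<int>& starts, std::vector<int>& ends) {
    const int n = (int)s.size();
    std::vector<std::pair<int, int>> spans;
    if (n >= 3) {
        const int wlen = std::min(window, n);
        for (int start = 0; start + wlen <= n; ++start) {
            if (window_score(s, start, wlen) > level)
                spans.push_back(std::make_pair(start, start + wlen));
        }
    }
    // N bases are always masked
    for (int i = 0; i < n; ++i) {
        if (b2i(s[i]) < 0) {
            int j = i;
            while (j < n && b2i(s[j]) < 0) ++j;
            spans.push_back(std::make_pair(i, j));
            i = j;
        }
    }
    if (spans.empty()) return;
    std::sort(spans.begin(), spans.end());
    int cs = spans[0].first, ce = spans[0].second;
    for (size_t i = 1; i < spans.size(); ++i) {
        if (spans[i].first <= ce) {
            if (spans[i].second > ce) ce = spans[i].second;
        } else {
            starts.push_back(cs); ends.push_back(ce);
            cs = spans[i].first; ce = spans[i].second;
        }
    }
    starts.push_back(cs); ends.push_back(ce);
}

// [[Rcpp::export]]
List cpp_dust_mask(std::string seq, int window, double level) {
    std::vector<int> starts, ends;
    dust_intervals(seq, window, level, starts, ends);
    long long masked = 0;
    for (size_t i = 0; i < starts.size(); ++i) masked += ends[i] - starts[i];
    double frac = seq.size() ? (double)masked / (double)seq.size() : 0.0;
    return List::create(_["start"] = wrap(starts), _["end"] = wrap(ends),
                        _["masked_fraction"] = frac);
}

// [[Rcpp::export]]
NumericVector cpp_dust_fractions(CharacterVector seqs, int window, double level) {
    NumericVector out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        std::vector<int> starts, ends;
        dust_intervals(s, window, level, starts, ends);
        long long masked = 0;
        for (size_t j = 0; j < starts.size(); ++j) masked += ends[j] - starts[j];
        out[i] = s.size() ? (double)masked / (double)s.size() : 0.0;
    }
    return out;
}

// [[Rcpp::export]]
LogicalVector cpp_all_n(CharacterVector seqs) {
    LogicalVector out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        bool alln = !s.empty();
        for (char c : s) if (b2i(c) >= 0) { alln = false; break; }
        out[i] = alln;
    }
    return out;
}
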