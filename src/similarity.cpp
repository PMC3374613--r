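#include <Rcpp.h>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

static inline int base2bit(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// distinct canonical k-mers of a set of sequences; k <= 31 (2-bit packed)
static void collect_kmers(const std::vector<std::string>& seqs, int k,
                          std::unordered_set<uint64_t>& out) {
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    const int shift = 2 * (k - 1);
    for (const std::string& s : seqs) {
        uint64_t fwd = 0, rev = 0;
        int run = 0;
        for (size_t i = 0; i < s.size(); ++i) {
            int b = base2bit(s[i]);
            if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
            fwd = ((fwd << 2) | (uint64_t)b) & mask;
            rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
            if (++run >= k) out.insert(fwd < rev ? fwd : rev);
        }
    }
}

static std::vector<std::string> as_strings(const CharacterVector& x) {
    std::vector<std::string> out;
    out.reserve(x.size());
    for (R_xlen_t i = 0; i < x.size(); ++i) out.push_back(as<std::string>(x[i]));
    return out;
}

// [[Rcpp::export]]
List cpp_kmer_containment(CharacterVector a, CharacterVector b, int k) {
    if (k < 1 || k > 31) stop("k must be between 1 and 31");
    std::vector<std::string> sa = as_strings(a), sb = as_strings(b);
    long long la = 0, lb = 0;
    for (const auto& s : sa) la += (long long)s.size();
    for (const auto& s : sb) lb += (long long)s.size();

    std::unordered_set<uint64_t> ka, kb;
    collect_kmers(sa, k, ka);
    collect_kmers(sb, k, kb);

    // denominator: distinct k-mers of the smaller genome (by total bases)
    const std::unordered_set<uint64_t>& small = (la <= lb) ? ka : kb;
    const std::unordered_set<uint64_t>& large = (la <= lb) ? kb : ka;
    long long shared = 0;
    for (uint64_t km : small) if (large.count(km)) ++shared;

    double denom = (double)small.size();
    double sim = (denom > 0) ? (double)shared / denom : 0.0;
    return List::create(_["shared"] = (double)shared,
                        _["denominator"] = denom,
                        _["similarity"] = sim,
                        _["n_kmers_a"] = (double)ka.size(),
                        _["n_kmers_b"] = (double)kb.size());
}
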