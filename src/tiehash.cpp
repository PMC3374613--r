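#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// order-independent, seeded tie selection: each read's choice among its tied
// best hits is a pure function of (seed, read_id), so resolution does not
// depend on input order or chunking.

static inline uint64_t fnv1a64(const char* s, size_t n) {
    uint64_t h = 1469598103934665603ULL;
    for (size_t i = 0; i < n; ++i) {
        h ^= (uint64_t)(unsigned char)s[i];
        h *= 1099511628211ULL;
    }
    return h;
}

static inline uint64_t splitmix64(uint64_t x) {
    x += 0x9E3779B97F4A7C15ULL;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
}

// [[Rcpp::export]]
IntegerVector cpp_tie_pick(CharacterVector read_ids, int seed, IntegerVector n_ties) {
    if (read_ids.size() != n_ties.size()) stop("length mismatch");
    IntegerVector out(read_ids.size());
    for (R_xlen_t i = 0; i < read_ids.size(); ++i) {
        int n = n_ties[i];
        if (n <= 0) { out[i] = NA_INTEGER; continue; }
        std::string id = as<std::string>(read_ids[i]);
        uint64_t h = fnv1a64(id.c_str(), id.size());
        h = splitmix64(h ^ splitmix64((uint64_t)(uint32_t)seed));
        out[i] = (int)(h % (uint64_t)n) + 1;  // 1-based pick
    }
    return out;
}
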