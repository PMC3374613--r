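// Seed-and-extend short-read mapper with length-fraction and identity filters.
//
// Canonical k-mer seed index over the reference; candidate loci are diagonal
// clusters of seed hits, extended by affine-gap dynamic programming inside a
// window of +/- band around the cluster (band = ceil(len*(1-min_sim)) + 2, so
// no alignment within the similarity filter can be clipped by the window).
// Extension reports the locus's best local alignment (query ends may be
// soft-clipped at zero cost); the length-fraction filter then measures that
// clipping, so a 100% length requirement admits only reads whose optimal
// alignment is end-to-end. Scoring: match +1, mismatch -2, gap of length L
// costs open + L*ext (default 3 + L).

#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <cmath>
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

static inline char comp(char c) {
    switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
    }
}

static std::string revcomp(const std::string& s) {
    std::string out(s.size(), 'N');
    for (size_t i = 0; i < s.size(); ++i) out[s.size() - 1 - i] = comp(s[i]);
    return out;
}

struct SeedIndex {
    int k;
    int max_occ;
    std::vector<std::string> names;
    std::vector<std::string> seqs;
    // canonical k-mer -> packed (seq << 33) | (pos << 1) | fwd_is_canonical
    std::unordered_map<uint64_t, std::vector<uint64_t>> tab;
    long long n_positions = 0;
    long long n_dropped = 0;
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs, int k, int max_occ) {
    if (k < 1 || k > 31) stop("seed length k must be between 1 and 31");
    SeedIndex* idx = new SeedIndex();
    idx->k = k;
    idx->max_occ = max_occ;
    const uint64_t mask = (1ULL << (2 * k)) - 1;
    const int shift = 2 * (k - 1);
    for (R_xlen_t si = 0; si < seqs.size(); ++si) {
        idx->names.push_back(as<std::string>(names[si]));
        idx->seqs.push_back(as<std::string>(seqs[si]));
        const std::string& s = idx->seqs.back();
        uint64_t fwd = 0, rev = 0;
        int run = 0;
        for (size_t i = 0; i < s.size(); ++i) {
            int b = b2i(s[i]);
            if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
            fwd = ((fwd << 2) | (uint64_t)b) & mask;
            rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
            if (++run >= k) {
                uint64_t canon = fwd < rev ? fwd : rev;
                uint64_t ori = (fwd <= rev) ? 1 : 0;
                uint64_t pos = (uint64_t)(i - k + 1);
                idx->tab[canon].push_back(((uint64_t)si << 33) | (pos << 1) | ori);
            }
        }
    }
    // drop repetitive seeds above the occupancy cutoff
    for (auto it = idx->tab.begin(); it != idx->tab.end();) {
        if ((int64_t)it->second.size() > (int64_t)max_occ) {
            ++idx->n_dropped;
            it = idx->tab.erase(it);
        } else {
            idx->n_positions += (long long)it->second.size();
            ++it;
        }
    }
    XPtr<SeedIndex> ptr(idx, true);
    return ptr;
}

// [[Rcpp::export]]
List cpp_index_stats(SEXP xp) {
    XPtr<SeedIndex> idx(xp);
    return List::create(_["k"] = idx->k, _["max_seed_occupancy"] = idx->max_occ,
                        _["n_seeds"] = (double)idx->tab.size(),
                        _["n_positions"] = (double)idx->n_positions,
                        _["n_dropped"] = (double)idx->n_dropped,
                        _["n_sequences"] = (int)idx->seqs.size());
}

// [[Rcpp::export]]
DataFrame cpp_index_lookup(SEXP xp, std::string kmer) {
    XPtr<SeedIndex> idx(xp);
    const int k = idx->k;
    if ((int)kmer.size() != k) stop("query k-mer length must equal index k");
    uint64_t fwd = 0, rev = 0;
    const int shift = 2 * (k - 1);
    for (int i = 0; i < k; ++i) {
        int b = b2i(kmer[i]);
        if (b < 0) stop("query k-mer contains a non-ACGT base");
        fwd = (fwd << 2) | (uint64_t)b;
        rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    }
    uint64_t canon = fwd < rev ? fwd : rev;
    uint64_t bq = (fwd <= rev) ? 1 : 0;
    std::vector<int> seqv, posv;
    std::vector<int> fwdmatch;
    auto it = idx->tab.find(canon);
    if (it != idx->tab.end()) {
        for (uint64_t e : it->second) {
            seqv.push_back((int)(e >> 33) + 1);
            posv.push_back((int)((e >> 1) & 0xFFFFFFFFULL));
            fwdmatch.push_back((int)((e & 1ULL) == bq));
        }
    }
    return DataFrame::create(_["seq"] = seqv, _["pos"] = posv,
                             _["forward_match"] = fwdmatch);
}

// ---- alignment extension ----------------------------------------------------

struct Aln {
    int seq, rstart, rend, qstart, qend, score, matches, columns, strand;
    std::string cigar;
};

// rolling-row DP workspace; `dir` holds one packed traceback byte per cell:
// bits 0-1 = H source (0 stop, 1 diag, 2 E, 3 F), bit 2 = E extends,
// bit 3 = F extends
struct Workspace {
    std::vector<int> Hprev, Hcur, Frow;
    std::vector<uint8_t> dir;
    std::vector<char> ops;
    void ensure(int m, int n) {
        size_t W = (size_t)n + 2;
        if (Hprev.size() < W) { Hprev.resize(W); Hcur.resize(W); Frow.resize(W); }
        size_t cells = (size_t)(m + 1) * (n + 1);
        if (dir.size() < cells) dir.resize(cells);
        std::fill(dir.begin(), dir.begin() + cells, (uint8_t)0);
    }
};

static const int NEG = -(1 << 28);

static std::string ops_to_cigar(const std::vector<char>& ops, int lead_clip, int tail_clip) {
    std::string out;
    char buf[16];
    if (lead_clip > 0) { snprintf(buf, sizeof(buf), "%dS", lead_clip); out += buf; }
    size_t i = 0;
    while (i < ops.size()) {
        size_t j = i;
        while (j < ops.size() && ops[j] == ops[i]) ++j;
        snprintf(buf, sizeof(buf), "%zu%c", j - i, ops[i]);
        out += buf;
        i = j;
    }
    if (tail_clip > 0) { snprintf(buf, sizeof(buf), "%dS", tail_clip); out += buf; }
    return out;
}

// shared traceback for local and fitting modes; fills qstart/rstart/cigar/
// matches/columns given the end cell (bi, bj)
static void traceback(Workspace& w, const char* ref, const std::string& q,
                      int n, int bi, int bj, Aln& a) {
    const int W = n + 1;
    w.ops.clear();
    int i = bi, j = bj, state = 0;  // 0=H, 1=E, 2=F
    int matches = 0;
    while (true) {
        uint8_t d = w.dir[(size_t)i * W + j];
        if (state == 0) {
            uint8_t p = d & 3;
            if (p == 0) break;
            if (p == 1) {
                w.ops.push_back('M');
                if (b2i(q[i - 1]) >= 0 && b2i(q[i - 1]) == b2i(ref[j - 1]))
                    ++matches;
                --i; --j;
            } else if (p == 2) state = 1;
            else state = 2;
        } else if (state == 1) {  // gap consuming reference: CIGAR 'D'
            w.ops.push_back('D');
            --j;
            state = (d & 4) ? 1 : 0;
        } else {                  // gap consuming query: CIGAR 'I'
            w.ops.push_back('I');
            --i;
            state = (d & 8) ? 2 : 0;
        }
    }
    a.qstart = i; a.rstart = j; a.qend = bi; a.rend = bj;
    a.matches = matches;
    a.columns = (int)w.ops.size();
    std::reverse(w.ops.begin(), w.ops.end());
    a.cigar = ops_to_cigar(w.ops, a.qstart, (int)q.size() - a.qend);
}

// local alignment (Smith-Waterman, query ends free via soft clips), banded:
// only cells with dlo <= j - i <= dhi are computed
static bool extend_local(Workspace& w, const char* ref, int n, const std::string& q,
                         int dlo, int dhi,
                         int match, int mismatch, int gopen, int gext, Aln& a) {
    const int m = (int)q.size();
    const int W = n + 1;
    w.ensure(m, n);
    for (int j = 0; j <= n + 1; ++j) { w.Hprev[j] = 0; w.Frow[j] = NEG; }
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= m; ++i) {
        int jlo = i + dlo; if (jlo < 1) jlo = 1;
        int jhi = i + dhi; if (jhi > n) jhi = n;
        if (jlo > jhi) { if (i + dlo > n) break; else continue; }
        size_t row = (size_t)i * W;
        w.Hcur[jlo - 1] = 0;  // fresh-start baseline at the band edge
        int e = NEG;
        const int qb = b2i(q[i - 1]);
        for (int j = jlo; j <= jhi; ++j) {
            int eOpen = w.Hcur[j - 1] - gopen - gext;
            int eExt = e - gext;
            uint8_t ebit = eExt >= eOpen ? 4 : 0;
            e = eExt >= eOpen ? eExt : eOpen;
            int fExt = w.Frow[j] - gext;
            int fOpen = w.Hprev[j] - gopen - gext;
            uint8_t fbit = fExt >= fOpen ? 8 : 0;
            int f = fExt >= fOpen ? fExt : fOpen;
            w.Frow[j] = f;
            int d = w.Hprev[j - 1] + ((qb >= 0 && qb == b2i(ref[j - 1])) ? match : -mismatch);
            int h = 0; uint8_t p = 0;
            if (d > h) { h = d; p = 1; }
            if (e > h) { h = e; p = 2; }
            if (f > h) { h = f; p = 3; }
            w.Hcur[j] = h;
            w.dir[row + j] = p | ebit | fbit;
            if (h > best) { best = h; bi = i; bj = j; }
        }
        // guard cells beyond the band for the next row
        w.Hcur[jhi + 1] = NEG;
        w.Frow[jhi + 1] = NEG;
        std::swap(w.Hprev, w.Hcur);
    }
    if (best <= 0) return false;
    a.score = best;
    traceback(w, ref, q, n, bi, bj, a);
    return true;
}

// ---- read mapping -----------------------------------------------------------

struct SeedHit { int32_t seq; int32_t diag; };

static void collect_seeds(const SeedIndex& idx, const std::string& q,
                          std::vector<SeedHit>& seeds) {
    seeds.clear();
    const int k = idx.k;
    if ((int)q.size() < k) return;
    const uint64_t mask = (1ULL << (2 * k)) - 1;
    const int shift = 2 * (k - 1);
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (size_t i = 0; i < q.size(); ++i) {
        int b = b2i(q[i]);
        if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
        if (++run >= k) {
            uint64_t canon = fwd < rev ? fwd : rev;
            uint64_t bq = (fwd <= rev) ? 1 : 0;
            auto it = idx.tab.find(canon);
            if (it == idx.tab.end()) continue;
            int32_t qpos = (int32_t)(i - k + 1);
            for (uint64_t e : it->second) {
                if ((e & 1ULL) != bq) continue;  // ref forward != query k-mer
                int32_t seq = (int32_t)(e >> 33);
                int32_t pos = (int32_t)((e >> 1) & 0xFFFFFFFFULL);
                seeds.push_back({seq, pos - qpos});
            }
        }
    }
}

// [[Rcpp::export]]
List cpp_map(SEXP xp, CharacterVector reads,
             double min_length_fraction, double min_similarity,
             int match, int mismatch, int gap_open, int gap_ext) {
    XPtr<SeedIndex> idx(xp);
    const double eps = 1e-9;
    Workspace w;
    std::vector<SeedHit> seeds;
    std::vector<Aln> cands;

    std::vector<int> o_read, o_seq, o_start, o_end, o_strand, o_score,
        o_matches, o_columns, o_qstart, o_qend;
    std::vector<std::string> o_cigar;
    const R_xlen_t nr = reads.size();
    IntegerVector r_best(nr, NA_INTEGER), r_nhits(nr, 0), r_supp(nr, 0);

    for (R_xlen_t ri = 0; ri < nr; ++ri) {
        std::string fwdread = as<std::string>(reads[ri]);
        const int qlen = (int)fwdread.size();
        if (qlen < idx->k || qlen == 0) continue;
        std::string revread = revcomp(fwdread);
        const int band = (int)std::ceil(qlen * (1.0 - min_similarity)) + 2;
        cands.clear();

        for (int strand = 0; strand < 2; ++strand) {
            const std::string& q = strand ? revread : fwdread;
            collect_seeds(*idx, q, seeds);
            if (seeds.empty()) continue;
            std::sort(seeds.begin(), seeds.end(), [](const SeedHit& a, const SeedHit& b) {
                return a.seq != b.seq ? a.seq < b.seq : a.diag < b.diag;
            });
            size_t c0 = 0;
            for (size_t si = 1; si <= seeds.size(); ++si) {
                bool close_cluster = (si == seeds.size()) ||
                    seeds[si].seq != seeds[c0].seq ||
                    seeds[si].diag - seeds[si - 1].diag > band ||
                    seeds[si].diag - seeds[c0].diag > 2 * band;
                if (!close_cluster) continue;
                // process cluster [c0, si)
                const int seq = seeds[c0].seq;
                const std::string& ref = idx->seqs[seq];
                const int rlen = (int)ref.size();
                const int d0 = seeds[c0].diag, d1 = seeds[si - 1].diag;
                // exact full-length match fast path (provably optimal)
                bool exact_found = false;
                int32_t prev_diag = INT32_MIN;
                for (size_t sj = c0; sj < si; ++sj) {
                    int32_t d = seeds[sj].diag;
                    if (d == prev_diag) continue;
                    prev_diag = d;
                    if (d < 0 || d + qlen > rlen) continue;
                    if (memcmp(ref.data() + d, q.data(), qlen) == 0) {
                        Aln a;
                        a.seq = seq; a.rstart = d; a.rend = d + qlen;
                        a.qstart = 0; a.qend = qlen;
                        a.score = qlen * match;
                        a.matches = qlen; a.columns = qlen;
                        a.strand = strand;
                        a.cigar = std::to_string(qlen) + "M";
                        cands.push_back(a);
                        exact_found = true;
                    }
                }
                if (!exact_found) {
                    int w0 = d0 - band; if (w0 < 0) w0 = 0;
                    int w1 = d1 + qlen + band; if (w1 > rlen) w1 = rlen;
                    if (w1 > w0) {
                        Aln a;
                        if (extend_local(w, ref.data() + w0, w1 - w0, q,
                                         d0 - band - w0, d1 + band - w0,
                                         match, mismatch, gap_open, gap_ext, a)) {
                            a.seq = seq; a.strand = strand;
                            a.rstart += w0; a.rend += w0;
                            cands.push_back(a);
                        }
                    }
                }
                c0 = si;
            }
        }

        // filter, dedupe on (seq, rstart, strand), rank by score
        std::vector<Aln*> passing;
        for (Aln& a : cands) {
            if (a.score <= 0 || a.columns <= 0) continue;
            double identity = (double)a.matches / a.columns;
            double qaf = (double)(a.qend - a.qstart) / qlen;
            if (identity < min_similarity - eps) continue;
            if (qaf < min_length_fraction - eps) continue;
            passing.push_back(&a);
        }
        if (passing.empty()) continue;
        std::sort(passing.begin(), passing.end(), [](const Aln* a, const Aln* b) {
            if (a->seq != b->seq) return a->seq < b->seq;
            if (a->rstart != b->rstart) return a->rstart < b->rstart;
            if (a->strand != b->strand) return a->strand < b->strand;
            return a->score > b->score;
        });
        std::vector<Aln*> uniq;
        for (Aln* a : passing) {
            if (!uniq.empty() && uniq.back()->seq == a->seq &&
                uniq.back()->rstart == a->rstart && uniq.back()->strand == a->strand)
                continue;
            uniq.push_back(a);
        }
        int best = NEG;
        for (Aln* a : uniq) if (a->score > best) best = a->score;
        int nh = 0, ns = 0;
        for (Aln* a : uniq) {
            if (a->score == best) {
                ++nh;
                o_read.push_back((int)ri + 1);
                o_seq.push_back(a->seq + 1);
                o_start.push_back(a->rstart);
                o_end.push_back(a->rend);
                o_strand.push_back(a->strand);
                o_score.push_back(a->score);
                o_matches.push_back(a->matches);
                o_columns.push_back(a->columns);
                o_qstart.push_back(a->qstart);
                o_qend.push_back(a->qend);
                o_cigar.push_back(a->cigar);
            } else ++ns;
        }
        r_best[ri] = best; r_nhits[ri] = nh; r_supp[ri] = ns;
    }

    return List::create(
        _["hits"] = List::create(
            _["read"] = wrap(o_read), _["seq"] = wrap(o_seq),
            _["start"] = wrap(o_start), _["end"] = wrap(o_end),
            _["strand"] = wrap(o_strand), _["score"] = wrap(o_score),
            _["matches"] = wrap(o_matches), _["columns"] = wrap(o_columns),
            _["qstart"] = wrap(o_qstart), _["qend"] = wrap(o_qend),
            _["cigar"] = wrap(o_cigar)),
        _["best_score"] = r_best, _["n_hits"] = r_nhits, _["suppressed"] = r_supp);
}
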