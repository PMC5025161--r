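#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include "kmer_utils.h"

using namespace Rcpp;

// Reference seed index: canonical k-mer -> (position, strand-of-canonical),
// positions of multi-copy k-mers are marked ambiguous and never used.
struct SeedIndex {
    int k;
    // value: pos (>=0) with bit flag in strand; pos == -1 => ambiguous
    std::unordered_map<std::string, std::pair<long, bool>> map; // bool: canonical == forward ref kmer
};

static void build_seed_index(const std::string &ref, int k, SeedIndex &idx) {
    idx.k = k;
    long last_bad = -1;
    std::string kmer;
    for (size_t j = 0; j < ref.size(); ++j) {
        if (!pl_valid_base(ref[j])) last_bad = (long)j;
        if ((long)j >= k - 1 && last_bad < (long)j - (k - 1)) {
            kmer.assign(ref, j - (k - 1), k);
            std::string canon = pl_canonical(kmer);
            auto it = idx.map.find(canon);
            if (it == idx.map.end()) {
                idx.map[canon] = {(long)(j - (k - 1)), canon == kmer};
            } else {
                it->second.first = -1; // ambiguous
            }
        }
    }
}

// Exact-seed ungapped placement of one read; returns reference start of the
// read's projection and strand (+1/-1), or start = -1 when no unique seed.
// The first unique seed scanning from the read's 5' end decides placement.
static void place_read(const SeedIndex &idx, const std::string &read,
                       long &start, int &strand) {
    start = -1;
    strand = 0;
    const int k = idx.k;
    if ((int)read.size() < k) return;
    long last_bad = -1;
    std::string kmer;
    for (size_t j = 0; j < read.size(); ++j) {
        if (!pl_valid_base(read[j])) last_bad = (long)j;
        if ((long)j < k - 1 || last_bad >= (long)j - (k - 1)) continue;
        size_t i = j - (k - 1); // read offset of this window
        kmer.assign(read, i, k);
        std::string canon = pl_canonical(kmer);
        auto it = idx.map.find(canon);
        if (it == idx.map.end()) continue;
        if (it->second.first < 0) continue; // ambiguous seed: try next
        long p = it->second.first;
        bool canon_is_fwd_ref = it->second.second;
        bool canon_is_fwd_read = (canon == kmer);
        bool same_strand = (canon_is_fwd_ref == canon_is_fwd_read);
        if (same_strand) {
            start = p - (long)i;
            strand = 1;
        } else {
            // revcomp(read) aligns forward; window sits at offset L-k-i there
            start = p - (long)(read.size() - k - i);
            strand = -1;
        }
        return;
    }
}

// [[Rcpp::export]]
IntegerVector cpp_read_coverage(std::string reference, CharacterVector reads, int seed_k) {
    SeedIndex idx;
    build_seed_index(reference, seed_k, idx);
    IntegerVector depth(reference.size(), 0);
    long L = (long)reference.size();
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        if (reads[r] == NA_STRING) continue;
        std::string read = as<std::string>(reads[r]);
        long start;
        int strand;
        place_read(idx, read, start, strand);
        if (strand == 0) continue;
        long a = std::max(0L, start);
        long b = std::min(L, start + (long)read.size());
        for (long p = a; p < b; ++p) depth[p]++;
    }
    return depth;
}

// Anchor a flank sequence onto the reference by its first unique exact seed;
// returns c(ref_start_of_flank, strand) with ref_start_of_flank the reference
// coordinate (0-based) of the flank's first base under ungapped projection,
// or c(-1, 0) when unanchorable.
// [[Rcpp::export]]
IntegerVector cpp_anchor_flank(std::string reference, std::string flank, int seed_k) {
    SeedIndex idx;
    build_seed_index(reference, seed_k, idx);
    long start;
    int strand;
    place_read(idx, flank, start, strand);
    return IntegerVector::create((int)start, strand);
}

// All maximal exact matches (length >= min_anchor) between the genome and its
// reverse complement, reported as genome-coordinate interval pairs
// (start1, start2, len), 0-based, with start1 <= start2. Each inverted match
// pair is reported once.
// [[Rcpp::export]]
DataFrame cpp_ir_matches(std::string g, int min_anchor) {
    const long n = (long)g.size();
    std::string R = pl_revcomp(g);
    const int k = min_anchor;
    std::unordered_map<std::string, std::vector<long>> rindex;
    {
        long last_bad = -1;
        std::string kmer;
        for (long j = 0; j < n; ++j) {
            if (!pl_valid_base(R[j])) last_bad = j;
            if (j >= k - 1 && last_bad < j - (k - 1)) {
                kmer.assign(R, j - (k - 1), k);
                rindex[kmer].push_back(j - (k - 1));
            }
        }
    }
    std::vector<long> v_s1, v_s2, v_len;
    long last_bad = -1;
    std::string kmer;
    for (long i = 0; i + k <= n; ++i) {
        if (i == 0) {
            for (long t = 0; t < k && t < n; ++t)
                if (!pl_valid_base(g[t])) last_bad = t;
        } else if (i + k - 1 < n && !pl_valid_base(g[i + k - 1])) {
            last_bad = i + k - 1;
        }
        if (last_bad >= i) continue;
        kmer.assign(g, i, k);
        auto it = rindex.find(kmer);
        if (it == rindex.end()) continue;
        for (long j : it->second) {
            // leftmost-only: skip if extendable to the left
            if (i > 0 && j > 0 && g[i - 1] == R[j - 1] &&
                pl_valid_base(g[i - 1]))
                continue;
            long len = k;
            while (i + len < n && j + len < n && g[i + len] == R[j + len] &&
                   pl_valid_base(g[i + len]))
                ++len;
            long s2 = n - j - len; // genome coords of the revcomp copy
            if (i < s2) {
                v_s1.push_back(i);
                v_s2.push_back(s2);
                v_len.push_back(len);
            }
        }
    }
    return DataFrame::create(_["start1"] = wrap(v_s1), _["start2"] = wrap(v_s2),
                             _["len"] = wrap(v_len));
}

// Paired-k-mer link votes: each reference k-mer pair whose two members land
// in different contigs (unique canonical occurrence across all contigs)
// contributes one vote for the implied end-to-end junction with a gap
// estimate derived from the pair separation d (start-to-start).
// Ends are encoded 0 = head (5' of the stored contig string), 1 = tail.
// [[Rcpp::export]]
DataFrame cpp_collect_links(CharacterVector contigs, CharacterVector left,
                            CharacterVector right, IntegerVector d) {
    // unique canonical k-mer -> (contig, pos); multi-hits removed
    if (left.size() == 0)
        return DataFrame::create(_["a"] = IntegerVector(0), _["end_a"] = IntegerVector(0),
                                 _["b"] = IntegerVector(0), _["end_b"] = IntegerVector(0),
                                 _["gap"] = IntegerVector(0));
    int k = (int)std::string(as<std::string>(left[0])).size();
    std::unordered_map<std::string, std::tuple<int, long, bool, bool>> idx;
    // value: contig, pos, canonical==forward-in-contig, ambiguous
    std::vector<long> clen(contigs.size());
    std::string kmer;
    for (R_xlen_t c = 0; c < contigs.size(); ++c) {
        std::string s = as<std::string>(contigs[c]);
        clen[c] = (long)s.size();
        if ((long)s.size() < k) continue;
        long last_bad = -1;
        for (size_t j = 0; j < s.size(); ++j) {
            if (!pl_valid_base(s[j])) last_bad = (long)j;
            if ((long)j >= k - 1 && last_bad < (long)j - (k - 1)) {
                kmer.assign(s, j - (k - 1), k);
                std::string canon = pl_canonical(kmer);
                auto it = idx.find(canon);
                if (it == idx.end())
                    idx[canon] = std::make_tuple((int)c, (long)(j - (k - 1)), canon == kmer, false);
                else
                    std::get<3>(it->second) = true;
            }
        }
    }
    std::vector<int> va, vea, vb, veb, vgap;
    for (R_xlen_t i = 0; i < left.size(); ++i) {
        std::string lk = as<std::string>(left[i]);
        std::string rk = as<std::string>(right[i]);
        if (!pl_valid_kmer(lk) || !pl_valid_kmer(rk)) continue;
        auto itl = idx.find(pl_canonical(lk));
        auto itr = idx.find(pl_canonical(rk));
        if (itl == idx.end() || itr == idx.end()) continue;
        if (std::get<3>(itl->second) || std::get<3>(itr->second)) continue;
        int ca = std::get<0>(itl->second), cb = std::get<0>(itr->second);
        if (ca == cb) continue;
        // orientation of contig relative to reference: + if the reference
        // forward k-mer occurs forward in the contig
        bool l_canon_fwd_ref = (pl_canonical(lk) == lk);
        bool l_canon_fwd_ctg = std::get<2>(itl->second);
        bool sa = (l_canon_fwd_ref == l_canon_fwd_ctg); // true: contig a is forward
        bool r_canon_fwd_ref = (pl_canonical(rk) == rk);
        bool r_canon_fwd_ctg = std::get<2>(itr->second);
        bool sb = (r_canon_fwd_ref == r_canon_fwd_ctg);
        long pa = std::get<1>(itl->second), pb = std::get<1>(itr->second);
        long la = clen[ca], lb = clen[cb];
        // reference-oriented start of each k-mer within its contig
        long qa = sa ? pa : la - pa - k;
        long qb = sb ? pb : lb - pb - k;
        long gap = (long)d[i] - (la - qa) - qb;
        // junction: reference-3' side of a (tail if forward) to reference-5'
        // side of b (head if forward)
        int ea = sa ? 1 : 0;
        int eb = sb ? 0 : 1;
        va.push_back(ca + 1);
        vea.push_back(ea);
        vb.push_back(cb + 1);
        veb.push_back(eb);
        vgap.push_back((int)gap);
    }
    return DataFrame::create(_["a"] = wrap(va), _["end_a"] = wrap(vea),
                             _["b"] = wrap(vb), _["end_b"] = wrap(veb),
                             _["gap"] = wrap(vgap));
}
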