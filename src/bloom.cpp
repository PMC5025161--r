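#include <Rcpp.h>
#include <cmath>
#include "kmer_utils.h"

using namespace Rcpp;

// Probe positions by double hashing over two streams derived from the
// strand-symmetric canonical window hash: g_i = h1 + i*h2 mod m.
static const uint64_t PL_S1 = 0xA24BAED4963EE407ULL;
static const uint64_t PL_S2 = 0x9FB21C651E98DF25ULL;

static inline void bloom_set(Rbyte *bits, uint64_t m, uint64_t h, uint64_t canon) {
    uint64_t h1 = pl_splitmix(canon ^ PL_S1);
    uint64_t h2 = pl_splitmix(canon ^ PL_S2) | 1ULL;
    for (uint64_t i = 0; i < h; ++i) {
        uint64_t pos = (h1 + i * h2) % m;
        bits[pos >> 3] |= (Rbyte)(1u << (pos & 7u));
    }
}

static inline bool bloom_get(const Rbyte *bits, uint64_t m, uint64_t h, uint64_t canon) {
    uint64_t h1 = pl_splitmix(canon ^ PL_S1);
    uint64_t h2 = pl_splitmix(canon ^ PL_S2) | 1ULL;
    for (uint64_t i = 0; i < h; ++i) {
        uint64_t pos = (h1 + i * h2) % m;
        if (!(bits[pos >> 3] & (Rbyte)(1u << (pos & 7u)))) return false;
    }
    return true;
}

// Visit every valid (A/C/G/T-only) window of every sequence with its rolling
// canonical hash.
template <typename F>
static void for_each_window(const CharacterVector &seqs, int k, F fun) {
    PlRoll roll(k);
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        if (seqs[i] == NA_STRING) continue;
        const char *s = CHAR(STRING_ELT(seqs, i));
        long n = (long)LENGTH(STRING_ELT(seqs, i));
        if (n < k) continue;
        long run = 0; // length of current valid run ending at j
        for (long j = 0; j < n; ++j) {
            if (pl_base_idx(s[j]) < 0) {
                run = 0;
                continue;
            }
            ++run;
            if (run == k) {
                roll.init(s + j - k + 1);
                fun(roll.canon(), i);
            } else if (run > k) {
                roll.roll(s[j - k], s[j]);
                fun(roll.canon(), i);
            }
        }
    }
}

static double count_windows(const CharacterVector &seqs, int k) {
    double n = 0;
    for_each_window(seqs, k, [&](uint64_t, R_xlen_t) { n += 1; });
    return n;
}

// [[Rcpp::export]]
List cpp_bloom_build(CharacterVector seqs, int k, double fpr) {
    double n = count_windows(seqs, k);
    double n_eff = std::max(n, 1.0);
    double ln2 = std::log(2.0);
    uint64_t m = (uint64_t)std::ceil(-n_eff * std::log(fpr) / (ln2 * ln2));
    if (m < 64) m = 64;
    uint64_t h = (uint64_t)std::llround(((double)m / n_eff) * ln2);
    if (h < 1) h = 1;
    RawVector bits((m + 7) / 8);
    std::fill(bits.begin(), bits.end(), (Rbyte)0);
    Rbyte *bp = bits.begin();
    for_each_window(seqs, k, [&](uint64_t canon, R_xlen_t) {
        bloom_set(bp, m, h, canon);
    });
    return List::create(_["bits"] = bits, _["k"] = k, _["m"] = (double)m,
                        _["h"] = (double)h, _["n"] = n, _["target_fpr"] = fpr);
}

// [[Rcpp::export]]
LogicalVector cpp_bloom_contains(RawVector bits, double m, double h, int k,
                                 CharacterVector kmers) {
    LogicalVector out(kmers.size());
    const Rbyte *bp = bits.begin();
    uint64_t mm = (uint64_t)m, hh = (uint64_t)h;
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        if (kmers[i] == NA_STRING) { out[i] = false; continue; }
        std::string s = as<std::string>(kmers[i]);
        if ((int)s.size() != k || !pl_valid_kmer(s)) { out[i] = false; continue; }
        uint64_t fh, rh;
        pl_hash_pair(s.c_str(), k, fh, rh);
        out[i] = bloom_get(bp, mm, hh, pl_canon_hash(fh, rh));
    }
    return out;
}

// Per-read fraction of its valid k-mers present in the filter.
// Reads shorter than k (or with no valid window) score 0.
// [[Rcpp::export]]
NumericVector cpp_bloom_share(RawVector bits, double m, double h, int k,
                              CharacterVector reads) {
    NumericVector out(reads.size());
    const Rbyte *bp = bits.begin();
    uint64_t mm = (uint64_t)m, hh = (uint64_t)h;
    std::vector<double> tot(reads.size(), 0.0), hit(reads.size(), 0.0);
    for_each_window(reads, k, [&](uint64_t canon, R_xlen_t i) {
        tot[i] += 1;
        if (bloom_get(bp, mm, hh, canon)) hit[i] += 1;
    });
    for (R_xlen_t i = 0; i < reads.size(); ++i) {
        out[i] = tot[i] > 0 ? hit[i] / tot[i] : 0.0;
    }
    return out;
}
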