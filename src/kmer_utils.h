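#ifndef PLASTIDLINKER_KMER_UTILS_H
#define PLASTIDLINKER_KMER_UTILS_H

#include <string>
#include <cstdint>
#include <unordered_map>

// Implicit de Bruijn graph: a multiset of canonical k-mers (vertices); edges
// are (k-1)-base overlaps queried on the fly. Shared between the graph code
// and the path-search oracle.
struct KGraph {
    int k;
    std::unordered_map<std::string, int> counts;
};

// Base complement; non-ACGT maps to 'N' so callers can reject it.
inline char pl_comp(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

inline bool pl_valid_base(char c) {
    return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

inline bool pl_valid_kmer(const std::string &s) {
    for (char c : s) if (!pl_valid_base(c)) return false;
    return !s.empty();
}

inline std::string pl_revcomp(const std::string &s) {
    std::string r(s.size(), 'N');
    for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = pl_comp(s[i]);
    return r;
}

// Canonical form: lexicographic minimum of a k-mer and its reverse complement.
inline std::string pl_canonical(const std::string &s) {
    std::string r = pl_revcomp(s);
    return (r < s) ? r : s;
}

// Allocation-free canonical form for hot loops: writes the reverse
// complement into a caller-owned buffer and returns a reference to the
// lexicographically smaller spelling.
inline const std::string &pl_canonical_buf(const std::string &s, std::string &rbuf) {
    rbuf.resize(s.size());
    for (size_t i = 0; i < s.size(); ++i) rbuf[s.size() - 1 - i] = pl_comp(s[i]);
    return (rbuf < s) ? rbuf : s;
}

// FNV-1a 64-bit over bytes, with a caller-chosen offset basis so two
// independent hash streams can be derived for double hashing.
inline uint64_t pl_fnv1a(const std::string &s, uint64_t basis) {
    uint64_t h = basis;
    for (char c : s) {
        h ^= static_cast<uint64_t>(static_cast<unsigned char>(c));
        h *= 1099511628211ULL;
    }
    return h;
}

// ---- strand-symmetric rolling k-mer hashing (ntHash-style) ----------------
//
// Polynomial rolling hash mod 2^64 with an odd multiplier r:
//   fh(w) = sum_i val(w[i])  * r^(k-1-i)   (forward)
//   rh(w) = sum_i cval(w[i]) * r^i         (reverse complement direction)
// For any window, fh(revcomp(w)) == rh(w), so min(fh, rh) identifies the
// unordered {k-mer, revcomp} pair — the canonical identity the Bloom filter
// needs — in O(1) per slid window.

static const uint64_t PL_R = 0x9E3779B97F4A7C15ULL; // odd
static const uint64_t PL_VAL[4] = {0x3C8BFBB395C60475ULL,  // A
                                   0x3193C18562A02B4DULL,  // C
                                   0x20323ED082572324ULL,  // G
                                   0x295549F54BE24456ULL}; // T

inline int pl_base_idx(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

inline uint64_t pl_val(char c) { return PL_VAL[pl_base_idx(c)]; }
inline uint64_t pl_cval(char c) { return PL_VAL[3 - pl_base_idx(c)]; }

// modular inverse of the odd multiplier mod 2^64 (Newton iteration)
inline uint64_t pl_r_inverse() {
    uint64_t x = PL_R;
    for (int i = 0; i < 6; ++i) x *= 2 - PL_R * x;
    return x;
}

inline uint64_t pl_pow_r(int e) {
    uint64_t p = 1, b = PL_R;
    while (e > 0) {
        if (e & 1) p *= b;
        b *= b;
        e >>= 1;
    }
    return p;
}

inline uint64_t pl_splitmix(uint64_t x) {
    x += 0x9E3779B97F4A7C15ULL;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
}

// O(k) hash pair of one window (for isolated probes)
inline void pl_hash_pair(const char *s, int k, uint64_t &fh, uint64_t &rh) {
    fh = 0;
    rh = 0;
    uint64_t rp = 1;
    for (int i = 0; i < k; ++i) {
        fh = fh * PL_R + pl_val(s[i]);
        rh += pl_cval(s[i]) * rp;
        rp *= PL_R;
    }
}

inline uint64_t pl_canon_hash(uint64_t fh, uint64_t rh) {
    return fh < rh ? fh : rh;
}

struct PlRoll {
    int k;
    uint64_t rk1;  // r^(k-1)
    uint64_t rinv; // r^-1
    uint64_t fh, rh;
    explicit PlRoll(int k_) : k(k_), rk1(pl_pow_r(k_ - 1)), rinv(pl_r_inverse()),
                              fh(0), rh(0) {}
    void init(const char *s) { pl_hash_pair(s, k, fh, rh); }
    void roll(char out, char in) {
        fh = (fh - pl_val(out) * rk1) * PL_R + pl_val(in);
        rh = (rh - pl_cval(out)) * rinv + pl_cval(in) * rk1;
    }
    uint64_t canon() const { return pl_canon_hash(fh, rh); }
};

#endif
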