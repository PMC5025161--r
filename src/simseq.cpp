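#include <Rcpp.h>
#include "kmer_utils.h"

using namespace Rcpp;

// Extract read sequences from source genomes with origin wrap-around for
// circular sources and i.i.d. substitution errors. Randomness comes from R's
// RNG (RNGScope via Rcpp attributes), so set.seed() upstream fixes output.
//   src:    1-based genome index per read
//   start:  0-based forward-strand start of the read's projection
//   len:    read length
//   rc:     emit the reverse complement of the window (read on minus strand)
//   circular: per-genome flag for wrap-around
// [[Rcpp::export]]
CharacterVector cpp_extract_reads(CharacterVector genomes, IntegerVector src,
                                  NumericVector start, IntegerVector len,
                                  LogicalVector rc, LogicalVector circular,
                                  double error_rate) {
    R_xlen_t n = src.size();
    CharacterVector out(n);
    std::vector<std::string> gs(genomes.size());
    for (R_xlen_t i = 0; i < genomes.size(); ++i) gs[i] = as<std::string>(genomes[i]);
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    for (R_xlen_t i = 0; i < n; ++i) {
        const std::string &g = gs[src[i] - 1];
        long L = (long)g.size();
        long rl = len[i];
        long s = (long)start[i];
        bool circ = circular[src[i] - 1];
        std::string read(rl, 'N');
        for (long j = 0; j < rl; ++j) {
            long p = s + j;
            if (circ) {
                p %= L;
                if (p < 0) p += L;
            }
            read[j] = (p >= 0 && p < L) ? g[p] : 'N';
        }
        if (rc[i]) read = pl_revcomp(read);
        if (error_rate > 0) {
            for (long j = 0; j < rl; ++j) {
                if (unif_rand() < error_rate) {
                    char cur = read[j];
                    char nb = cur;
                    while (nb == cur) nb = bases[(int)(unif_rand() * 4) & 3];
                    read[j] = nb;
                }
            }
        }
        out[i] = read;
    }
    return out;
}

// 3' quality trimming by the running-sum argmax rule: remove the suffix
// [c, len) maximising sum(q - Q_i); keep everything when no positive-score
// suffix exists. Returns kept length per read.
// [[Rcpp::export]]
IntegerVector cpp_trim_point(CharacterVector quals, double q) {
    R_xlen_t n = quals.size();
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string s = as<std::string>(quals[i]);
        long len = (long)s.size();
        double run = 0, best = 0;
        long bestc = len;
        for (long c = len - 1; c >= 0; --c) {
            run += q - (double)(s[c] - 33);
            if (run > best) {
                best = run;
                bestc = c;
            }
        }
        out[i] = (int)bestc;
    }
    return out;
}
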