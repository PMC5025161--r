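#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include "kmer_utils.h"

using namespace Rcpp;

static inline bool kg_has(const KGraph &g, const std::string &kmer) {
    return g.counts.find(pl_canonical(kmer)) != g.counts.end();
}

// Oriented successors/predecessors of a k-mer spelled in a given orientation.
static std::vector<std::string> kg_succ(const KGraph &g, const std::string &s) {
    std::vector<std::string> out;
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    std::string t = s.substr(1) + "A";
    for (char b : bases) {
        t[t.size() - 1] = b;
        if (kg_has(g, t)) out.push_back(t);
    }
    return out;
}

static std::vector<std::string> kg_pred(const KGraph &g, const std::string &s) {
    std::vector<std::string> out;
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    std::string t = "A" + s.substr(0, s.size() - 1);
    for (char b : bases) {
        t[0] = b;
        if (kg_has(g, t)) out.push_back(t);
    }
    return out;
}

// [[Rcpp::export]]
SEXP cpp_kgraph_build(CharacterVector seqs, int k, int min_count) {
    XPtr<KGraph> g(new KGraph(), true);
    g->k = k;
    std::string kmer, rbuf;
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        if (seqs[i] == NA_STRING) continue;
        std::string s = as<std::string>(seqs[i]);
        if ((int)s.size() < k) continue;
        // track rightmost invalid base to skip windows cheaply
        long last_bad = -1;
        for (size_t j = 0; j < s.size(); ++j) {
            if (!pl_valid_base(s[j])) last_bad = (long)j;
            if ((long)j >= k - 1 && last_bad < (long)j - (k - 1)) {
                kmer.assign(s, j - (k - 1), k);
                g->counts[pl_canonical_buf(kmer, rbuf)]++;
            }
        }
    }
    if (min_count > 1) {
        for (auto it = g->counts.begin(); it != g->counts.end();) {
            if (it->second < min_count) it = g->counts.erase(it);
            else ++it;
        }
    }
    return g;
}

// [[Rcpp::export]]
int cpp_kgraph_k(SEXP gp) { return XPtr<KGraph>(gp)->k; }

// [[Rcpp::export]]
double cpp_kgraph_size(SEXP gp) { return (double)XPtr<KGraph>(gp)->counts.size(); }

// [[Rcpp::export]]
DataFrame cpp_kgraph_table(SEXP gp) {
    XPtr<KGraph> g(gp);
    std::vector<std::string> keys;
    keys.reserve(g->counts.size());
    for (auto &kv : g->counts) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());
    IntegerVector cnt(keys.size());
    for (size_t i = 0; i < keys.size(); ++i) cnt[i] = g->counts[keys[i]];
    return DataFrame::create(_["kmer"] = wrap(keys), _["count"] = cnt,
                             _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
LogicalVector cpp_kgraph_contains(SEXP gp, CharacterVector kmers) {
    XPtr<KGraph> g(gp);
    LogicalVector out(kmers.size());
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        std::string s = as<std::string>(kmers[i]);
        out[i] = pl_valid_kmer(s) && (int)s.size() == g->k && kg_has(*g, s);
    }
    return out;
}

// Fraction of vertices with no neighbour in at least one extension direction.
// Left/right are taken in the canonical spelling; existence of a neighbour is
// orientation-symmetric, so the fraction is strand-independent.
// [[Rcpp::export]]
double cpp_kgraph_blunt_fraction(SEXP gp) {
    XPtr<KGraph> g(gp);
    if (g->counts.empty()) stop("blunt-end fraction is undefined on an empty graph");
    double blunt = 0;
    for (auto &kv : g->counts) {
        if (kg_pred(*g, kv.first).empty() || kg_succ(*g, kv.first).empty()) blunt += 1.0;
    }
    return blunt / (double)g->counts.size();
}

static bool is_palindrome(const std::string &s) { return pl_revcomp(s) == s; }

// Maximal non-branching paths. Internal vertices must have exactly one
// predecessor and one successor; palindromic k-mers always break a chain
// (their two strands coincide, so a walk through them is ill-defined).
// Branch-free circular components are emitted once, opened at the
// lexicographically minimal canonical k-mer.
// [[Rcpp::export]]
List cpp_kgraph_unitigs(SEXP gp, int min_len) {
    XPtr<KGraph> g(gp);
    const int k = g->k;
    std::unordered_set<std::string> visited;
    std::vector<std::string> seqs;
    std::vector<double> covs;

    auto chain_from = [&](const std::string &start,
                          std::vector<std::string> &chain, bool &circular) {
        chain.clear();
        circular = false;
        chain.push_back(start);
        if (is_palindrome(start)) return;
        std::unordered_set<std::string> local;
        local.insert(pl_canonical(start));
        // extend right
        std::string cur = start;
        while (true) {
            auto s = kg_succ(*g, cur);
            if (s.size() != 1) break;
            std::string t = s[0];
            if (kg_pred(*g, t).size() != 1) break;
            if (is_palindrome(t)) break;
            std::string ct = pl_canonical(t);
            if (ct == pl_canonical(start)) { circular = true; break; }
            if (local.count(ct) || visited.count(ct)) break;
            chain.push_back(t);
            local.insert(ct);
            cur = t;
        }
        if (circular) return;
        // extend left
        cur = start;
        while (true) {
            auto p = kg_pred(*g, cur);
            if (p.size() != 1) break;
            std::string t = p[0];
            if (kg_succ(*g, t).size() != 1) break;
            if (is_palindrome(t)) break;
            std::string ct = pl_canonical(t);
            if (local.count(ct) || visited.count(ct)) break;
            chain.insert(chain.begin(), t);
            local.insert(ct);
            cur = t;
        }
    };

    std::vector<std::string> keys;
    keys.reserve(g->counts.size());
    for (auto &kv : g->counts) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());

    for (const std::string &key : keys) {
        if (visited.count(key)) continue;
        std::vector<std::string> chain;
        bool circular = false;
        chain_from(key, chain, circular);
        if (circular) {
            // restart deterministically at the minimal canonical k-mer of the cycle
            std::string kmin = key;
            for (auto &c : chain) kmin = std::min(kmin, pl_canonical(c));
            std::vector<std::string> cyc;
            std::string cur = kmin;
            cyc.push_back(cur);
            while (true) {
                auto s = kg_succ(*g, cur);
                if (s.size() != 1) break; // cannot happen on a clean cycle
                cur = s[0];
                if (pl_canonical(cur) == kmin) break;
                cyc.push_back(cur);
            }
            chain = cyc;
        }
        double cov = 0;
        std::string seq = chain[0];
        for (size_t i = 0; i < chain.size(); ++i) {
            if (i > 0) seq.push_back(chain[i][k - 1]);
            visited.insert(pl_canonical(chain[i]));
            cov += g->counts[pl_canonical(chain[i])];
        }
        cov /= (double)chain.size();
        if ((int)seq.size() < min_len) continue;
        std::string rc = pl_revcomp(seq);
        seqs.push_back(rc < seq ? rc : seq);
        covs.push_back(cov);
    }
    // deterministic output order: sort by canonical-orientation sequence
    std::vector<size_t> ord(seqs.size());
    for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) { return seqs[a] < seqs[b]; });
    CharacterVector out_seq(seqs.size());
    NumericVector out_cov(seqs.size());
    for (size_t i = 0; i < ord.size(); ++i) {
        out_seq[i] = seqs[ord[i]];
        out_cov[i] = covs[ord[i]];
    }
    return List::create(_["sequence"] = out_seq, _["coverage"] = out_cov);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
    CharacterVector out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
        out[i] = pl_revcomp(as<std::string>(seqs[i]));
    }
    return out;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector kmers) {
    CharacterVector out(kmers.size());
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        if (kmers[i] == NA_STRING) { out[i] = NA_STRING; continue; }
        out[i] = pl_canonical(as<std::string>(kmers[i]));
    }
    return out;
}
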