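#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include "kmer_utils.h"

using namespace Rcpp;

// Shared membership oracle for the gap-filling / end-joining path search:
// either a Bloom filter (bits/m/h) or an exact canonical k-mer set (the
// KGraph external pointer), so tests can compare the two routes.
struct Oracle {
    bool use_bloom;
    const Rbyte *bits;
    uint64_t m, h;
    const std::unordered_map<std::string, int> *set;
};

static const uint64_t PL_S1 = 0xA24BAED4963EE407ULL;
static const uint64_t PL_S2 = 0x9FB21C651E98DF25ULL;

static inline bool oracle_has(const Oracle &o, const std::string &kmer,
                              std::string &rbuf) {
    if (!o.use_bloom) {
        const std::string &canon = pl_canonical_buf(kmer, rbuf);
        return o.set->find(canon) != o.set->end();
    }
    uint64_t fh, rh;
    pl_hash_pair(kmer.c_str(), (int)kmer.size(), fh, rh);
    uint64_t canon = pl_canon_hash(fh, rh);
    uint64_t h1 = pl_splitmix(canon ^ PL_S1);
    uint64_t h2 = pl_splitmix(canon ^ PL_S2) | 1ULL;
    for (uint64_t i = 0; i < o.h; ++i) {
        uint64_t pos = (h1 + i * h2) % o.m;
        if (!(o.bits[pos >> 3] & (Rbyte)(1u << (pos & 7u)))) return false;
    }
    return true;
}

static Oracle make_oracle(SEXP oracle, RawVector &keep_bits) {
    Oracle o;
    if (TYPEOF(oracle) == EXTPTRSXP) {
        XPtr<KGraph> g(oracle);
        o.use_bloom = false;
        o.set = &g->counts;
        o.bits = nullptr;
        o.m = o.h = 0;
    } else {
        List bl(oracle);
        keep_bits = as<RawVector>(bl["bits"]);
        o.use_bloom = true;
        o.bits = keep_bits.begin();
        o.m = (uint64_t)as<double>(bl["m"]);
        o.h = (uint64_t)as<double>(bl["h"]);
        o.set = nullptr;
    }
    return o;
}

// Depth-first bounded path search, extending rightward one base at a time
// through oracle membership. The goal test is literal (same orientation as
// the walk): a spliced fill must end with the goal k-mer as spelled in the
// scaffold, and a strand-insensitive test would let walks that reflect off
// an inverted repeat terminate on the goal's reverse complement. Branch
// events are counted as the extra extensions beyond the first at any node;
// exceeding B aborts with "branch_limit". Finding more than P start->goal
// paths aborts with "path_limit". Paths are returned spelled from the start
// k-mer through the goal k-mer inclusive.
// [[Rcpp::export]]
List cpp_path_search(std::string start, std::string goal, SEXP oracle,
                     int B, int P, int max_steps) {
    RawVector keep_bits;
    Oracle o = make_oracle(oracle, keep_bits);
    const int k = (int)start.size();

    std::vector<std::string> paths;
    std::string status = "no_path";
    long branch_events = 0;

    if (start == goal) {
        paths.push_back(start);
        return List::create(_["status"] = "ok", _["paths"] = wrap(paths),
                            _["branch_events"] = (double)branch_events);
    }

    // agenda of (extension depth, base); the path string is shared and
    // truncated on backtrack
    std::vector<std::pair<int, char>> agenda;
    std::string path = start;
    std::string t, rbuf;
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    bool aborted = false;

    auto expand = [&](int depth) -> bool {
        // returns false on branch-limit abort
        char found[4];
        int nf = 0;
        t.assign(path, path.size() - k + 1, k - 1);
        t.push_back('A');
        for (char b : bases) {
            t[t.size() - 1] = b;
            if (oracle_has(o, t, rbuf)) found[nf++] = b;
        }
        if (nf > 1) {
            branch_events += nf - 1;
            if (branch_events > B) return false;
        }
        for (int i = nf - 1; i >= 0; --i) agenda.push_back({depth + 1, found[i]});
        return true;
    };

    if (!expand(0)) {
        return List::create(_["status"] = "branch_limit", _["paths"] = CharacterVector(0),
                            _["branch_events"] = (double)branch_events);
    }

    while (!agenda.empty()) {
        auto item = agenda.back();
        agenda.pop_back();
        path.resize((size_t)k + (size_t)item.first - 1);
        path.push_back(item.second);
        if (path.compare(path.size() - k, k, goal) == 0) {
            paths.push_back(path);
            if ((int)paths.size() > P) { status = "path_limit"; aborted = true; break; }
            continue; // do not extend past the goal
        }
        if (item.first >= max_steps) continue;
        if (!expand(item.first)) { status = "branch_limit"; aborted = true; break; }
    }

    if (!aborted) status = paths.empty() ? "no_path" : "ok";
    if (aborted) paths.clear();
    return List::create(_["status"] = status, _["paths"] = wrap(paths),
                        _["branch_events"] = (double)branch_events);
}
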