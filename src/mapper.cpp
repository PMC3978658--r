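#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// 2-bit base codes; anything non-ACGT (N) gets 4 and never matches an
// index key, so an N inside a seed partition simply disables that seed.
static inline int base_code(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4;
    }
}

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

static std::string revcomp(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
    return r;
}

// Sorted (key, position) index over all k-mers of the concatenated genome.
// Positions are global offsets; k-mers never cross a chromosome boundary.
struct KmerIndex {
    int k;
    std::vector<uint64_t> keys;
    std::vector<uint32_t> pos;

    void build(const std::string& genome,
               const std::vector<uint32_t>& chrom_off,
               const std::vector<uint32_t>& chrom_len) {
        std::vector<std::pair<uint64_t, uint32_t>> tmp;
        tmp.reserve(genome.size());
        const uint64_t mask =
            (k >= 32) ? ~uint64_t(0) : ((uint64_t(1) << (2 * k)) - 1);
        for (size_t c = 0; c < chrom_off.size(); ++c) {
            if (chrom_len[c] < (uint32_t)k) continue;
            uint32_t off = chrom_off[c];
            uint64_t key = 0;
            int run = 0; // valid bases accumulated
            for (uint32_t i = 0; i < chrom_len[c]; ++i) {
                int b = base_code(genome[off + i]);
                if (b > 3) { run = 0; key = 0; continue; }
                key = ((key << 2) | (uint64_t)b) & mask;
                if (++run >= k)
                    tmp.push_back({key, off + i - (uint32_t)k + 1});
            }
        }
        std::sort(tmp.begin(), tmp.end());
        keys.resize(tmp.size());
        pos.resize(tmp.size());
        for (size_t i = 0; i < tmp.size(); ++i) {
            keys[i] = tmp[i].first;
            pos[i] = tmp[i].second;
        }
    }

    // indices [lo, hi) of positions matching key
    std::pair<size_t, size_t> lookup(uint64_t key) const {
        auto lo = std::lower_bound(keys.begin(), keys.end(), key);
        auto hi = std::upper_bound(lo, keys.end(), key);
        return {(size_t)(lo - keys.begin()), (size_t)(hi - keys.begin())};
    }
};

struct Hit {
    uint32_t gpos;  // global 0-based start on forward genome
    uint8_t strand; // 0 = +, 1 = -
    uint8_t mm;
};

// Pigeonhole seed partition of a read of length L into (max_mm + 1)
// non-overlapping pieces: any placement with <= max_mm mismatches has at
// least one error-free piece, so exact seed lookup is complete.
static void partition_lengths(int L, int parts, std::vector<int>& lens,
                              std::vector<int>& offs) {
    lens.assign(parts, L / parts);
    for (int i = 0; i < L % parts; ++i) lens[i] += 1;
    offs.assign(parts, 0);
    for (int i = 1; i < parts; ++i) offs[i] = offs[i - 1] + lens[i - 1];
}

class Mapper {
  public:
    std::string genome;
    std::vector<uint32_t> chrom_off, chrom_len;
    int read_len, max_mm, parts;
    std::vector<int> plens, poffs;
    std::vector<KmerIndex> idx; // one per partition length actually used

    Mapper(const CharacterVector& chrom_seqs, int read_len_, int max_mm_)
        : read_len(read_len_), max_mm(max_mm_) {
        parts = max_mm + 1;
        partition_lengths(read_len, parts, plens, poffs);
        size_t total = 0;
        for (R_xlen_t i = 0; i < chrom_seqs.size(); ++i)
            total += LENGTH(STRING_ELT(chrom_seqs, i));
        genome.reserve(total);
        for (R_xlen_t i = 0; i < chrom_seqs.size(); ++i) {
            std::string s = as<std::string>(chrom_seqs[i]);
            chrom_off.push_back((uint32_t)genome.size());
            chrom_len.push_back((uint32_t)s.size());
            genome += s;
        }
        std::vector<int> klens(plens);
        std::sort(klens.begin(), klens.end());
        klens.erase(std::unique(klens.begin(), klens.end()), klens.end());
        for (int k : klens) {
            KmerIndex ki;
            ki.k = k;
            ki.build(genome, chrom_off, chrom_len);
            idx.push_back(ki);
        }
    }

    const KmerIndex& index_for(int k) const {
        for (const auto& ki : idx)
            if (ki.k == k) return ki;
        stop("internal: no index for k");
    }

    int chrom_of(uint32_t gpos) const {
        // last chromosome whose offset is <= gpos
        size_t lo = 0, hi = chrom_off.size();
        while (hi - lo > 1) {
            size_t mid = (lo + hi) / 2;
            if (chrom_off[mid] <= gpos) lo = mid; else hi = mid;
        }
        return (int)lo;
    }

    // all best-stratum hits of one read (both strands)
    void best_hits(const std::string& read, std::vector<Hit>& out) const {
        out.clear();
        std::string rc = revcomp(read);
        std::vector<std::pair<uint32_t, uint8_t>> cand;
        for (int strand = 0; strand < 2; ++strand) {
            const std::string& seq = strand == 0 ? read : rc;
            for (int p = 0; p < parts; ++p) {
                int k = plens[p], off = poffs[p];
                uint64_t key = 0;
                bool ok = true;
                for (int i = 0; i < k; ++i) {
                    int b = base_code(seq[off + i]);
                    if (b > 3) { ok = false; break; }
                    key = (key << 2) | (uint64_t)b;
                }
                if (!ok) continue;
                const KmerIndex& ki = index_for(k);
                auto rng = ki.lookup(key);
                for (size_t j = rng.first; j < rng.second; ++j) {
                    int64_t start = (int64_t)ki.pos[j] - off;
                    if (start < 0) continue;
                    cand.push_back({(uint32_t)start, (uint8_t)strand});
                }
            }
        }
        std::sort(cand.begin(), cand.end());
        cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
        int best = max_mm + 1;
        for (auto& cs : cand) {
            int c = chrom_of(cs.first);
            if (cs.first + (uint32_t)read_len >
                chrom_off[c] + chrom_len[c]) continue;
            const std::string& seq = cs.second == 0 ? read : rc;
            int mm = 0;
            for (int i = 0; i < read_len && mm <= max_mm; ++i)
                if (seq[i] != genome[cs.first + i]) ++mm;
            if (mm > max_mm) continue;
            if (mm < best) { best = mm; out.clear(); }
            if (mm == best)
                out.push_back({cs.first, cs.second, (uint8_t)mm});
        }
    }
};

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector chrom_seqs, CharacterVector reads,
                   int read_len, int max_mm, bool collect_hits) {
    Mapper m(chrom_seqs, read_len, max_mm);
    int n = (int)reads.size();
    IntegerVector chrom(n, NA_INTEGER), pos(n, NA_INTEGER),
        strand(n, NA_INTEGER), mism(n, NA_INTEGER), mult(n, 0);
    List hits_out = collect_hits ? List(n) : List(0);
    std::vector<Hit> hits;
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string read = as<std::string>(reads[i]);
        if ((int)read.size() != read_len)
            stop("read %d has length %d, expected %d", (int)(i + 1),
                 (int)read.size(), read_len);
        m.best_hits(read, hits);
        if (collect_hits) {
            IntegerMatrix hm(hits.size(), 4);
            for (size_t j = 0; j < hits.size(); ++j) {
                int c = m.chrom_of(hits[j].gpos);
                hm(j, 0) = c + 1;
                hm(j, 1) = (int)(hits[j].gpos - m.chrom_off[c]);
                hm(j, 2) = hits[j].strand;
                hm(j, 3) = hits[j].mm;
            }
            hits_out[i] = hm;
        }
        if (hits.empty()) continue;
        size_t pick = hits.size() == 1
            ? 0
            : (size_t)(unif_rand() * hits.size());
        if (pick >= hits.size()) pick = hits.size() - 1;
        int c = m.chrom_of(hits[pick].gpos);
        chrom[i] = c + 1;
        pos[i] = (int)(hits[pick].gpos - m.chrom_off[c]);
        strand[i] = hits[pick].strand;
        mism[i] = hits[pick].mm;
        mult[i] = (int)hits.size();
    }
    return List::create(_["chrom"] = chrom, _["pos"] = pos,
                        _["strand"] = strand, _["mismatches"] = mism,
                        _["multiplicity"] = mult, _["hits"] = hits_out);
}

// [[Rcpp::export]]
CharacterVector cpp_extract_reads(std::string chrom_seq, IntegerVector starts,
                                  IntegerVector strands, int read_len) {
    R_xlen_t n = starts.size();
    CharacterVector out(n);
    int L = (int)chrom_seq.size();
    for (R_xlen_t i = 0; i < n; ++i) {
        int s = starts[i];
        if (s < 0 || s + read_len > L)
            stop("read interval [%d,%d) outside chromosome of length %d",
                 s, s + read_len, L);
        std::string r = chrom_seq.substr(s, read_len);
        if (strands[i] == 1) r = revcomp(r);
        out[i] = r;
    }
    return out;
}

// [[Rcpp::export]]
List cpp_inject_errors(CharacterVector seqs, double rate) {
    static const char* bases = "ACGT";
    R_xlen_t n = seqs.size();
    CharacterVector out(n);
    IntegerVector nerr(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        int e = 0;
        for (size_t j = 0; j < s.size(); ++j) {
            if (rate > 0 && unif_rand() < rate) {
                int cur = base_code(s[j]);
                if (cur > 3) continue;
                int sub = (int)(unif_rand() * 3);
                if (sub > 2) sub = 2;
                // pick uniformly among the three other bases
                int b = (cur + 1 + sub) % 4;
                s[j] = bases[b];
                ++e;
            }
        }
        out[i] = s;
        nerr[i] = e;
    }
    return List::create(_["seq"] = out, _["n_errors"] = nerr);
}

// Best ungapped identity of any `window`-length chunk of `a` against `b`,
// evaluated only at alignments sharing an exact k-mer (seed-and-verify).
// A chunk at >= (1 - (k's pigeonhole bound)) identity always shares a
// k-mer with its counterpart, so high-identity hits are never missed.
// Returns -1 when no seed exists.
// [[Rcpp::export]]
double cpp_seeded_window_identity(std::string a, std::string b,
                                  int window = 150, int k = 16) {
    int la = (int)a.size(), lb = (int)b.size();
    if (la == 0 || lb == 0) stop("empty sequence");
    if (window > la) window = la;
    if (window > lb) window = lb;
    if (k > window) k = window;
    // index b's k-mers
    std::vector<std::pair<uint64_t, uint32_t>> idx;
    idx.reserve(lb);
    uint64_t mask = (k >= 32) ? ~uint64_t(0) : ((uint64_t(1) << (2 * k)) - 1);
    {
        uint64_t key = 0;
        int run = 0;
        for (int i = 0; i < lb; ++i) {
            int c = base_code(b[i]);
            if (c > 3) { run = 0; key = 0; continue; }
            key = ((key << 2) | (uint64_t)c) & mask;
            if (++run >= k) idx.push_back({key, (uint32_t)(i - k + 1)});
        }
    }
    std::sort(idx.begin(), idx.end());
    double best = -1.0;
    std::vector<std::pair<int, int>> seen; // (window start, offset in b)
    for (int wo = 0; wo < la; wo += window) {
        int wlen = std::min(window, la - wo);
        if (wlen < k) break;
        uint64_t key = 0;
        int run = 0;
        for (int j = wo; j < wo + wlen; ++j) {
            int c = base_code(a[j]);
            if (c > 3) { run = 0; key = 0; continue; }
            key = ((key << 2) | (uint64_t)c) & mask;
            if (++run < k) continue;
            int apos = j - k + 1;
            auto lo = std::lower_bound(idx.begin(), idx.end(),
                                       std::make_pair(key, (uint32_t)0));
            for (auto it = lo; it != idx.end() && it->first == key; ++it) {
                int boff = (int)it->second - (apos - wo);
                if (boff < 0 || boff + wlen > lb) continue;
                std::pair<int, int> tag(wo, boff);
                bool dup = false;
                for (auto& s : seen)
                    if (s == tag) { dup = true; break; }
                if (dup) continue;
                seen.push_back(tag);
                int match = 0;
                for (int t = 0; t < wlen; ++t)
                    if (a[wo + t] == b[boff + t]) ++match;
                double id = 100.0 * match / wlen;
                if (id > best) best = id;
            }
        }
        seen.clear();
    }
    return best;
}
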