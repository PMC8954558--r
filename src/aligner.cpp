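// Seed-and-extend gapless short-read aligner.
//
// Index: exact k-mer hash over the reference sequences as given (+ strand).
// Query: every overlapping k-mer of the read (and of its reverse complement)
// is looked up, so any alignment with <= max_mismatch mismatches that leaves
// at least one clean k-length window is found.  For m mismatches this is
// guaranteed for reads of length >= (m+1)(k-1) + m + 1 (36 at k=12, m=2);
// shorter reads carrying the full budget may be missed (documented
// limitation).  N mismatches everything and never seeds.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

struct SeedIndex {
    std::vector<std::string> names;  // sorted lexicographically by caller
    std::vector<std::string> seqs;
    int k;
    std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t> > > table;
};

static inline int base2bits(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
    }
}

static inline char complement(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
    }
}

static std::string revcomp(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) r[i] = complement(r[i]);
    return r;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs, int k) {
    SeedIndex* idx = new SeedIndex();
    idx->k = k;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
    for (int t = 0; t < names.size(); ++t) {
        idx->names.push_back(as<std::string>(names[t]));
        idx->seqs.push_back(as<std::string>(seqs[t]));
        const std::string& s = idx->seqs[t];
        uint64_t kmer = 0;
        int valid = 0;  // length of current run of ACGT ending here
        for (size_t i = 0; i < s.size(); ++i) {
            int b = base2bits(s[i]);
            if (b < 0) { valid = 0; kmer = 0; continue; }
            kmer = ((kmer << 2) | (uint64_t)b) & mask;
            if (++valid >= k) {
                idx->table[kmer].push_back(
                    std::make_pair((int32_t)t, (int32_t)(i + 1 - k)));
            }
        }
    }
    XPtr<SeedIndex> p(idx, true);
    return p;
}

// [[Rcpp::export]]
DataFrame cpp_index_lookup(SEXP ptr, std::string kmer) {
    XPtr<SeedIndex> idx(ptr);
    if ((int)kmer.size() != idx->k) stop("k-mer length must equal index k");
    uint64_t key = 0;
    for (size_t i = 0; i < kmer.size(); ++i) {
        int b = base2bits(kmer[i]);
        if (b < 0) return DataFrame::create(_["target"] = CharacterVector(0),
                                            _["pos"] = IntegerVector(0));
        key = (key << 2) | (uint64_t)b;
    }
    std::vector<std::string> tg;
    std::vector<int> pos;
    std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t> > >::iterator
        it = idx->table.find(key);
    if (it != idx->table.end()) {
        for (size_t j = 0; j < it->second.size(); ++j) {
            tg.push_back(idx->names[it->second[j].first]);
            pos.push_back(it->second[j].second);
        }
    }
    return DataFrame::create(_["target"] = wrap(tg), _["pos"] = wrap(pos),
                             _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
IntegerVector cpp_index_info(SEXP ptr) {
    XPtr<SeedIndex> idx(ptr);
    IntegerVector out = IntegerVector::create(
        _["k"] = idx->k, _["n_targets"] = (int)idx->names.size());
    return out;
}

// Hamming distance with early exit; 'N' on either side mismatches.
static inline int hamming_capped(const char* a, const char* b, int len, int cap) {
    int mm = 0;
    for (int i = 0; i < len; ++i) {
        char x = a[i], y = b[i];
        if (x != y || x == 'N' || y == 'N') {
            if (++mm > cap) return mm;
        }
    }
    return mm;
}

struct Hit {
    int32_t tid;
    int32_t start;
    int strand;  // 0 = '+', 1 = '-'
    int mm;
};

static void collect_candidates(const SeedIndex* idx, const std::string& q,
                               int strand, int max_mm, std::vector<Hit>& hits) {
    const int k = idx->k;
    const int L = (int)q.size();
    if (L < k) return;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
    // dedupe candidate loci across windows
    std::vector<uint64_t> seen;
    uint64_t kmer = 0;
    int valid = 0;
    for (int i = 0; i < L; ++i) {
        int b = base2bits(q[i]);
        if (b < 0) { valid = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t)b) & mask;
        if (++valid < k) continue;
        int off = i + 1 - k;  // window start within read
        std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t> > >::const_iterator
            it = idx->table.find(kmer);
        if (it == idx->table.end()) continue;
        for (size_t j = 0; j < it->second.size(); ++j) {
            int32_t tid = it->second[j].first;
            int64_t start = (int64_t)it->second[j].second - off;
            if (start < 0) continue;
            const std::string& ref = idx->seqs[tid];
            if (start + L > (int64_t)ref.size()) continue;
            uint64_t key = ((uint64_t)tid << 40) | (uint64_t)start;
            seen.push_back(key);
        }
    }
    std::sort(seen.begin(), seen.end());
    seen.erase(std::unique(seen.begin(), seen.end()), seen.end());
    for (size_t j = 0; j < seen.size(); ++j) {
        int32_t tid = (int32_t)(seen[j] >> 40);
        int32_t start = (int32_t)(seen[j] & ((1ULL << 40) - 1));
        const std::string& ref = idx->seqs[tid];
        int mm = hamming_capped(ref.c_str() + start, q.c_str(), L, max_mm);
        if (mm <= max_mm) {
            Hit h; h.tid = tid; h.start = start; h.strand = strand; h.mm = mm;
            hits.push_back(h);
        }
    }
}

// Align one read; returns (tid, start, strand, mm, multiplicity) or tid = -1.
static void align_one(const SeedIndex* idx, const std::string& seq, int max_mm,
                      int& tid, int& start, int& strand, int& mm, int& mult) {
    std::vector<Hit> hits;
    collect_candidates(idx, seq, 0, max_mm, hits);
    std::string rc = revcomp(seq);
    collect_candidates(idx, rc, 1, max_mm, hits);
    tid = -1;
    if (hits.empty()) return;
    int best = max_mm + 1;
    for (size_t i = 0; i < hits.size(); ++i)
        if (hits[i].mm < best) best = hits[i].mm;
    int count = 0;
    int b_tid = -1, b_start = 0, b_strand = 0;
    for (size_t i = 0; i < hits.size(); ++i) {
        if (hits[i].mm != best) continue;
        ++count;
        // tie-break: lowest (target name order, start), '+' before '-'
        if (b_tid < 0 || hits[i].tid < b_tid ||
            (hits[i].tid == b_tid && (hits[i].start < b_start ||
             (hits[i].start == b_start && hits[i].strand < b_strand)))) {
            b_tid = hits[i].tid; b_start = hits[i].start; b_strand = hits[i].strand;
        }
    }
    tid = b_tid; start = b_start; strand = b_strand; mm = best; mult = count;
}

// [[Rcpp::export]]
DataFrame cpp_align_reads(SEXP ptr, CharacterVector read_ids,
                          CharacterVector read_seqs, int max_mismatch,
                          bool keep_unaligned) {
    XPtr<SeedIndex> idx(ptr);
    int n = read_seqs.size();
    std::vector<std::string> o_id, o_tg, o_strand, o_seq;
    std::vector<int> o_start, o_end, o_mm, o_mult;
    for (int i = 0; i < n; ++i) {
        std::string seq = as<std::string>(read_seqs[i]);
        int tid, start, strand, mm, mult;
        align_one(idx, seq, max_mismatch, tid, start, strand, mm, mult);
        if (tid < 0) {
            if (keep_unaligned) {
                o_id.push_back(as<std::string>(read_ids[i]));
                o_tg.push_back("");
                o_strand.push_back("");
                o_seq.push_back(seq);
                o_start.push_back(NA_INTEGER); o_end.push_back(NA_INTEGER);
                o_mm.push_back(NA_INTEGER); o_mult.push_back(NA_INTEGER);
            }
            continue;
        }
        o_id.push_back(as<std::string>(read_ids[i]));
        o_tg.push_back(idx->names[tid]);
        o_strand.push_back(strand == 0 ? "+" : "-");
        o_seq.push_back(seq);
        o_start.push_back(start);
        o_end.push_back(start + (int)seq.size());
        o_mm.push_back(mm);
        o_mult.push_back(mult);
    }
    return DataFrame::create(
        _["read_id"] = wrap(o_id), _["target"] = wrap(o_tg),
        _["start"] = wrap(o_start), _["end"] = wrap(o_end),
        _["strand"] = wrap(o_strand), _["mismatches"] = wrap(o_mm),
        _["multiplicity"] = wrap(o_mult), _["sequence"] = wrap(o_seq),
        _["stringsAsFactors"] = false);
}
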