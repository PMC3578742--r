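#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Ungapped (Hamming) scanning of short reads against a small reference.
//
// Completeness: for max_mismatch m we use m+1 non-overlapping exact seeds per
// read; by pigeonhole every alignment with <= m mismatches contains at least
// one exact seed, so the seeded scan returns the same hit set as an
// exhaustive scan over every offset and strand. Reads whose seeds would be
// shorter than MIN_SEED (ambiguity explosion) fall back to the naive scan,
// as do seeds containing non-ACGT characters.

static const int MIN_SEED = 8;

static inline char comp(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'a': return 't';
    case 'c': return 'g';
    case 'g': return 'c';
    case 't': return 'a';
    default:  return 'N';
    }
}

static std::string revcomp(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
    return r;
}

// 2-bit encode a k-mer; returns false if any base is not ACGT
static bool encode_kmer(const char* s, int k, uint64_t& out) {
    uint64_t v = 0;
    for (int i = 0; i < k; ++i) {
        int b;
        switch (s[i]) {
        case 'A': case 'a': b = 0; break;
        case 'C': case 'c': b = 1; break;
        case 'G': case 'g': b = 2; break;
        case 'T': case 't': b = 3; break;
        default: return false;
        }
        v = (v << 2) | (uint64_t)b;
    }
    out = v;
    return true;
}

// mismatches between read and ref at offset pos, early exit above cap
static inline int hamming_at(const std::string& read, const std::string& ref,
                             int pos, int cap) {
    int mm = 0;
    const int n = (int)read.size();
    for (int i = 0; i < n; ++i) {
        char a = read[i], b = ref[pos + i];
        if (a >= 'a') a -= 32;
        if (b >= 'a') b -= 32;
        if (a != b || a == 'N') {
            if (++mm > cap) return mm;
        }
    }
    return mm;
}

struct Hit {
    int read;    // 1-based index into the input read vector
    int pos;     // 0-based reference offset
    int strand;  // 0 = forward, 1 = reverse
    int nm;      // mismatch count
};

class KmerIndex {
public:
    int k;
    std::unordered_map<uint64_t, std::vector<int> > map;
    KmerIndex(const std::string& ref, int k_) : k(k_) {
        const int n = (int)ref.size();
        map.reserve(n > k ? n - k + 1 : 1);
        for (int i = 0; i + k <= n; ++i) {
            uint64_t code;
            if (encode_kmer(ref.c_str() + i, k, code)) map[code].push_back(i);
        }
    }
    const std::vector<int>* lookup(uint64_t code) const {
        std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
            map.find(code);
        return it == map.end() ? 0 : &it->second;
    }
};

static void scan_one(const std::string& read, int strand,
                     const std::string& ref, const KmerIndex* idx,
                     int max_mm, int read_id, std::vector<Hit>& hits,
                     std::vector<int>& stamp, int tick) {
    const int n = (int)ref.size(), L = (int)read.size();
    if (L > n) return;
    const int nslots = n - L + 1;
    int nseeds = max_mm + 1;
    int slen = idx ? idx->k : 0;
    bool seeded = idx && L / nseeds >= slen && slen >= MIN_SEED;

    if (seeded) {
        bool all_seeds_ok = true;
        for (int s = 0; s < nseeds; ++s) {
            int off = s * (L / nseeds);
            uint64_t code;
            if (!encode_kmer(read.c_str() + off, slen, code)) {
                all_seeds_ok = false;
                continue;
            }
            const std::vector<int>* cand = idx->lookup(code);
            if (!cand) continue;
            for (size_t j = 0; j < cand->size(); ++j) {
                int pos = (*cand)[j] - off;
                if (pos < 0 || pos >= nslots) continue;
                if (stamp[pos] == tick) continue;  // already checked
                stamp[pos] = tick;
                int mm = hamming_at(read, ref, pos, max_mm);
                if (mm <= max_mm) {
                    Hit h; h.read = read_id; h.pos = pos; h.strand = strand; h.nm = mm;
                    hits.push_back(h);
                }
            }
        }
        if (all_seeds_ok) return;
        // some seed unusable (contains N): naive scan of unvisited offsets
        for (int pos = 0; pos < nslots; ++pos) {
            if (stamp[pos] == tick) continue;
            int mm = hamming_at(read, ref, pos, max_mm);
            if (mm <= max_mm) {
                Hit h; h.read = read_id; h.pos = pos; h.strand = strand; h.nm = mm;
                hits.push_back(h);
            }
        }
        return;
    }

    for (int pos = 0; pos < nslots; ++pos) {
        int mm = hamming_at(read, ref, pos, max_mm);
        if (mm <= max_mm) {
            Hit h; h.read = read_id; h.pos = pos; h.strand = strand; h.nm = mm;
            hits.push_back(h);
        }
    }
}

// [[Rcpp::export(name = ".hamming_scan")]]
DataFrame hamming_scan(CharacterVector reads, std::string reference,
                       int max_mismatch) {
    if (max_mismatch < 0) stop("max_mismatch must be >= 0");
    const int nreads = reads.size();
    int minL = 1 << 30;
    for (int i = 0; i < nreads; ++i) {
        int L = (int)strlen(CHAR(STRING_ELT(reads, i)));
        if (L < minL) minL = L;
    }
    int slen = nreads ? minL / (max_mismatch + 1) : 0;
    KmerIndex* idx = 0;
    if (slen >= MIN_SEED && (int)reference.size() >= slen && slen <= 31)
        idx = new KmerIndex(reference, slen);

    std::vector<Hit> hits;
    int nslots = (int)reference.size() + 1;
    std::vector<int> stamp(nslots, -1);
    int tick = 0;
    for (int i = 0; i < nreads; ++i) {
        std::string fwd = as<std::string>(reads[i]);
        std::string rev = revcomp(fwd);
        ++tick;
        scan_one(fwd, 0, reference, idx, max_mismatch, i + 1, hits, stamp, tick);
        ++tick;
        scan_one(rev, 1, reference, idx, max_mismatch, i + 1, hits, stamp, tick);
    }
    delete idx;

    const int n = (int)hits.size();
    IntegerVector read(n), pos(n), nm(n);
    CharacterVector strand(n);
    for (int i = 0; i < n; ++i) {
        read[i] = hits[i].read;
        pos[i] = hits[i].pos;
        strand[i] = hits[i].strand == 0 ? "+" : "-";
        nm[i] = hits[i].nm;
    }
    return DataFrame::create(_["read"] = read, _["pos0"] = pos,
                             _["strand"] = strand, _["nm"] = nm,
                             _["stringsAsFactors"] = false);
}

// Best qualifying local ungapped match of a read against one consensus,
// both strands. Each diagonal (relative offset of the read against the
// consensus, including partial overhangs) is scanned with a
// Kadane-style segment search (match +1, mismatch -9, so retained
// segments stay near 90% identity); a candidate segment qualifies with
// >= min_len aligned bases and identity >= min_identity. The best
// qualifying segment maximizes match count, ties broken by identity then
// first-found (leftmost) position. Returns c(cons_start, matches, alen,
// strand01) -- cons_start is the 0-based consensus coordinate where the
// matched segment begins -- or an empty vector if nothing qualifies.
// [[Rcpp::export(name = ".best_ungapped_match")]]
IntegerVector best_ungapped_match(std::string read, std::string consensus,
                                  int min_len, double min_identity) {
    const int L = (int)read.size(), C = (int)consensus.size();
    if (min_len < 1) stop("min_len must be >= 1");
    const int MISMATCH = 9;
    int best_match = -1, best_alen = 0, best_cons = 0, best_strand = 0;
    for (int strand = 0; strand < 2; ++strand) {
        std::string r = strand == 0 ? read : revcomp(read);
        for (int off = -(L - min_len); off <= C - min_len; ++off) {
            int lo = off < 0 ? -off : 0;            // first read base used
            int hi = (off + L > C ? C - off : L);   // one past last read base
            if (hi - lo < min_len) continue;
            int score = 0, seg_start = lo, seg_match = 0;
            for (int i = lo; i < hi; ++i) {
                char a = r[i], b = consensus[off + i];
                if (a >= 'a') a -= 32;
                if (b >= 'a') b -= 32;
                bool m = (a == b && a != 'N');
                if (m) { ++score; ++seg_match; } else { score -= MISMATCH; }
                if (score < 0) {
                    score = 0; seg_start = i + 1; seg_match = 0;
                    continue;
                }
                int alen = i - seg_start + 1;
                if (alen < min_len) continue;
                if ((double)seg_match + 1e-9 < min_identity * alen) continue;
                bool better = seg_match > best_match ||
                    (seg_match == best_match && alen < best_alen);
                if (better) {
                    best_match = seg_match; best_alen = alen;
                    best_cons = off + seg_start; best_strand = strand;
                }
            }
        }
    }
    if (best_match < 0) return IntegerVector(0);
    return IntegerVector::create(best_cons, best_match, best_alen,
                                 best_strand);
}
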