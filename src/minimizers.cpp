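#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include "ivh_util.h"

using namespace Rcpp;

// Canonical (w,k)-minimizer extraction.
//
// k-mer values: for k <= 32 the 2-bit encodings of the forward and
// reverse-complement k-mer are each passed through the splitmix64 finalizer
// (invertible, so distinct k-mers get distinct values); the canonical value is
// the smaller of the two and the strand is the one achieving it.  Values equal
// on both strands (palindromic k-mers) are skipped.  For k > 32 an
// ntHash-style rolling hash replaces the exact encoding (distinct k-mers may
// collide; rotation period 64 caps the mixing for k > 64).
//
// Positions are end-standardized: `pos` is the 0-based index of the k-mer's
// last base in original (uncompressed) coordinates; `span` is the number of
// original bases the k-mer covers (= k without homopolymer compression).

static inline int base2bit(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// ntHash base constants (published rolling-hash seeds).
static const uint64_t NT_SEED[4] = {
    0x3c8bfbb395c60474ULL,  // A
    0x3193c18562a02b4cULL,  // C
    0x20323ed082572324ULL,  // G
    0x295549f54be24456ULL   // T
};

static inline uint64_t rotr64(uint64_t x, unsigned s) {
    s &= 63u;
    if (s == 0) return x;
    return (x >> s) | (x << (64u - s));
}

struct KmerStream {
    std::vector<int> pos;        // index (in the scanned string) of last base
    std::vector<uint64_t> val;   // canonical value
    std::vector<char> strand;    // '+' or '-'
    std::vector<char> brk;       // 1 if a new valid run starts at this k-mer
};

// Scan all canonical k-mer values of `s`; windows containing non-ACGT bases
// are skipped and break the run (minimizer windows never span them).
static KmerStream scan_kmers(const std::string& s, int k) {
    KmerStream ks;
    const int n = (int)s.size();
    if (n < k) return ks;
    bool small_k = (k <= 32);
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t cf = 0, cr = 0;          // exact 2-bit codes (k <= 32)
    uint64_t hf = 0, hr = 0;          // rolling ntHash values (k > 32)
    int run = 0;                      // valid bases in current run
    bool new_run = true;
    for (int j = 0; j < n; ++j) {
        int b = base2bit(s[j]);
        if (b < 0) { run = 0; new_run = true; hf = hr = 0; cf = cr = 0; continue; }
        ++run;
        uint64_t vf, vr;
        if (small_k) {
            cf = ((cf << 2) | (uint64_t)b) & mask;
            cr = (cr >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
            if (run < k) continue;
            vf = ivh_mix64(cf);
            vr = ivh_mix64(cr);
        } else {
            if (run < k) {
                hf = ivh_rotl(hf, 1) ^ NT_SEED[b];
                hr = hr ^ ivh_rotl(NT_SEED[3 - b], (unsigned)(run - 1));
                continue;
            } else if (run == k) {
                hf = ivh_rotl(hf, 1) ^ NT_SEED[b];
                hr = hr ^ ivh_rotl(NT_SEED[3 - b], (unsigned)(k - 1));
            } else {
                int out = base2bit(s[j - k]);
                hf = ivh_rotl(hf, 1) ^ ivh_rotl(NT_SEED[out], (unsigned)k)
                     ^ NT_SEED[b];
                hr = rotr64(hr, 1) ^ rotr64(NT_SEED[3 - out], 1)
                     ^ ivh_rotl(NT_SEED[3 - b], (unsigned)(k - 1));
            }
            vf = hf;
            vr = hr;
        }
        if (vf == vr) continue;       // strand-symmetric: ambiguous, skip
        ks.pos.push_back(j);
        ks.val.push_back(vf < vr ? vf : vr);
        ks.strand.push_back(vf < vr ? '+' : '-');
        ks.brk.push_back(new_run ? 1 : 0);
        new_run = false;
    }
    return ks;
}

// Homopolymer compression with coordinate maps.  For compressed index i,
// map_start[i] / map_end[i] are the original indices of the first / last base
// of the run.
static void hpc_compress(const std::string& s, std::string& out,
                         std::vector<int>& map_start, std::vector<int>& map_end) {
    const int n = (int)s.size();
    out.clear(); map_start.clear(); map_end.clear();
    int i = 0;
    while (i < n) {
        int j = i;
        while (j + 1 < n && s[j + 1] == s[i]) ++j;
        out.push_back(s[i]);
        map_start.push_back(i);
        map_end.push_back(j);
        i = j + 1;
    }
}

// [[Rcpp::export(name = ".cpp_hpc")]]
List cpp_hpc(std::string seq) {
    if (seq.empty()) stop("sequence must be non-empty");
    std::string comp;
    std::vector<int> ms, me;
    hpc_compress(seq, comp, ms, me);
    return List::create(_["bases"] = comp,
                        _["map_start"] = IntegerVector(ms.begin(), ms.end()),
                        _["map_end"] = IntegerVector(me.begin(), me.end()));
}

// All canonical k-mer values (no window selection, no HPC).
// [[Rcpp::export(name = ".cpp_kmer_hashes")]]
List cpp_kmer_hashes(std::string seq, int k) {
    if (k <= 0) stop("k must be >= 1");
    KmerStream ks = scan_kmers(seq, k);
    const int n = (int)ks.pos.size();
    CharacterVector val(n), strand(n);
    for (int i = 0; i < n; ++i) {
        val[i] = ivh_to_hex(ks.val[i]);
        strand[i] = std::string(1, ks.strand[i]);
    }
    return List::create(_["pos"] = IntegerVector(ks.pos.begin(), ks.pos.end()),
                        _["strand"] = strand, _["value"] = val);
}

// (w,k)-minimizers with all-minimum tie emission; optional homopolymer
// compression (k-mers taken in compressed space, coordinates mapped back).
// [[Rcpp::export(name = ".cpp_minimizers")]]
List cpp_minimizers(std::string seq, int k, int w, bool hpc) {
    if (k <= 0 || w <= 0) stop("k and w must be >= 1");
    std::string scan = seq;
    std::vector<int> ms, me;
    if (hpc) hpc_compress(seq, scan, ms, me);
    KmerStream ks = scan_kmers(scan, k);
    const int n = (int)ks.pos.size();
    std::vector<char> emitted(n, 0);
    std::vector<int> out_idx;
    // slide windows of w consecutive k-mers within each unbroken run
    int run_start = 0;
    for (int i = 0; i <= n; ++i) {
        if (i == n || ks.brk[i]) {
            int run_end = i;  // exclusive
            for (int s0 = run_start; s0 + w <= run_end; ++s0) {
                uint64_t mn = ks.val[s0];
                for (int t = s0 + 1; t < s0 + w; ++t)
                    if (ks.val[t] < mn) mn = ks.val[t];
                for (int t = s0; t < s0 + w; ++t)
                    if (ks.val[t] == mn && !emitted[t]) {
                        emitted[t] = 1;
                        out_idx.push_back(t);
                    }
            }
            run_start = i;
        }
    }
    std::sort(out_idx.begin(), out_idx.end());
    const int m = (int)out_idx.size();
    IntegerVector pos(m), span(m);
    CharacterVector val(m), strand(m);
    for (int i = 0; i < m; ++i) {
        int t = out_idx[i];
        int j = ks.pos[t];  // last-base index in scanned string
        if (hpc) {
            pos[i] = me[j];
            span[i] = me[j] - ms[j - k + 1] + 1;
        } else {
            pos[i] = j;
            span[i] = k;
        }
        val[i] = ivh_to_hex(ks.val[t]);
        strand[i] = std::string(1, ks.strand[t]);
    }
    return List::create(_["pos"] = pos, _["strand"] = strand,
                        _["value"] = val, _["span"] = span);
}
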