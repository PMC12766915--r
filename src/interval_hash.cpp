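#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include "ivh_util.h"

using namespace Rcpp;

// Interval hashing: map a vector of N occurrence intervals to N+1 per-occurrence
// 64-bit context hashes.  Five steps per occurrence i:
//   1. slice the interval vector into a 2W window (intervals i-W .. i+W-1) and
//      a 4W window (i-2W .. i+2W-1), out-of-bounds entries = infinity;
//      both slices are reversed when the central k-mer came from the reverse
//      strand (strand canonicalization);
//   2. unit interval = min over the 4W slice (the local repeat period);
//   3. normalise the 2W slice by the unit interval;
//   4. quantize: round(normalised * resolution), half away from zero;
//      each quantized value -> partial hash (splitmix64 finalizer, 0 reserved
//      for the infinity sentinel);
//   5. combine partials: XOR of partial j rotated left by (2W-1-j) bits.
// An all-infinite context (N = 0, or a singleton segment) hashes to 0.

static const double IVH_INF = R_PosInf;

static uint64_t hash_one(const std::vector<double>& iv, R_xlen_t i, bool rev,
                         int W, double resolution) {
    const R_xlen_t N = (R_xlen_t)iv.size();
    const int L2 = 2 * W, L4 = 4 * W;
    std::vector<double> s2(L2), s4(L4);
    for (int j = 0; j < L4; ++j) {
        R_xlen_t idx = i - 2 * W + j;
        s4[j] = (idx >= 0 && idx < N) ? iv[idx] : IVH_INF;
    }
    for (int j = 0; j < L2; ++j) {
        R_xlen_t idx = i - W + j;
        s2[j] = (idx >= 0 && idx < N) ? iv[idx] : IVH_INF;
    }
    if (rev) {
        std::reverse(s2.begin(), s2.end());
        std::reverse(s4.begin(), s4.end());
    }
    double unit = IVH_INF;
    for (int j = 0; j < L4; ++j) unit = std::min(unit, s4[j]);
    uint64_t h = 0;
    if (!R_FINITE(unit)) return 0;  // empty context
    for (int j = 0; j < L2; ++j) {
        uint64_t p;
        if (!R_FINITE(s2[j])) {
            p = 0;
        } else {
            double q = std::floor(s2[j] / unit * resolution + 0.5);
            p = ivh_mix64_nz((uint64_t)q);
        }
        h ^= ivh_rotl(p, (unsigned)(L2 - 1 - j));
    }
    return h;
}

static bool strand_is_rev(const String& s) {
    const char* c = s.get_cstring();
    return c[0] == '-';
}

// Hash every occurrence of one interval vector (single segment, no splitting).
// strand is recycled if length 1.
// [[Rcpp::export(name = ".cpp_interval_hashes")]]
CharacterVector cpp_interval_hashes(NumericVector intervals,
                                    CharacterVector strand,
                                    int W, double resolution) {
    if (W < 0) stop("W must be >= 0");
    if (!(resolution > 0)) stop("resolution must be > 0");
    R_xlen_t N = intervals.size();
    for (R_xlen_t j = 0; j < N; ++j) {
        double d = intervals[j];
        if (ISNA(d) || ISNAN(d)) stop("intervals must not contain NA");
        if (R_FINITE(d) && d < 1) stop("finite intervals must be >= 1");
    }
    if (strand.size() != 1 && strand.size() != N + 1)
        stop("strand must have length 1 or N+1");
    std::vector<double> iv(intervals.begin(), intervals.end());
    CharacterVector out(N + 1);
    for (R_xlen_t i = 0; i <= N; ++i) {
        bool rev = strand_is_rev(strand.size() == 1 ? String(strand[0])
                                                    : String(strand[i]));
        out[i] = ivh_to_hex(hash_one(iv, i, rev, W, resolution));
    }
    return out;
}

// Partial hash of quantized values (Inf -> 0 sentinel).
// [[Rcpp::export(name = ".cpp_partial_hash")]]
CharacterVector cpp_partial_hash(NumericVector q) {
    R_xlen_t n = q.size();
    CharacterVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (!R_FINITE(q[i])) {
            out[i] = ivh_to_hex(0);
        } else {
            if (q[i] < 0) stop("quantized values must be non-negative");
            out[i] = ivh_to_hex(ivh_mix64_nz((uint64_t)q[i]));
        }
    }
    return out;
}

// Rolling combination of 2W partial hash values (hex strings).
// [[Rcpp::export(name = ".cpp_combine")]]
CharacterVector cpp_combine(CharacterVector partials) {
    int n = (int)partials.size();
    uint64_t h = 0;
    for (int j = 0; j < n; ++j)
        h ^= ivh_rotl(ivh_from_hex(String(partials[j]).get_cstring()),
                      (unsigned)(n - 1 - j));
    return CharacterVector::create(ivh_to_hex(h));
}

// splitmix64 finalizer on hex inputs (exposed for the hash contract tests).
// [[Rcpp::export(name = ".cpp_mix64")]]
CharacterVector cpp_mix64(CharacterVector x) {
    R_xlen_t n = x.size();
    CharacterVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = ivh_to_hex(ivh_mix64(ivh_from_hex(String(x[i]).get_cstring())));
    return out;
}

// Interval hashing over occurrence groups with vector splitting.
// positions must be sorted by group then position; group ids contiguous.
// Segments are cut where consecutive positions differ by more than max_sep;
// each segment is hashed independently.
// [[Rcpp::export(name = ".cpp_group_ivh")]]
CharacterVector cpp_group_ivh(NumericVector positions,
                              CharacterVector strand,
                              IntegerVector group,
                              double max_sep, int W, double resolution) {
    R_xlen_t n = positions.size();
    if (strand.size() != n || group.size() != n)
        stop("positions, strand and group must have equal length");
    CharacterVector out(n);
    R_xlen_t g0 = 0;
    while (g0 < n) {
        R_xlen_t g1 = g0;
        while (g1 + 1 < n && group[g1 + 1] == group[g0]) ++g1;
        // split [g0, g1] at gaps > max_sep
        R_xlen_t s0 = g0;
        while (s0 <= g1) {
            R_xlen_t s1 = s0;
            while (s1 + 1 <= g1 &&
                   positions[s1 + 1] - positions[s1] <= max_sep) {
                if (positions[s1 + 1] <= positions[s1])
                    stop("positions must be strictly increasing within a group");
                ++s1;
            }
            R_xlen_t m = s1 - s0 + 1;            // occurrences in segment
            std::vector<double> iv(m - 1);
            for (R_xlen_t j = 0; j < m - 1; ++j)
                iv[j] = positions[s0 + j + 1] - positions[s0 + j];
            for (R_xlen_t i = 0; i < m; ++i) {
                bool rev = strand_is_rev(String(strand[s0 + i]));
                out[s0 + i] = ivh_to_hex(hash_one(iv, i, rev, W, resolution));
            }
            s0 = s1 + 1;
        }
        g0 = g1 + 1;
    }
    return out;
}

// Combined seed key: minimizer value XOR f(ivh), with f(0) = 0 so singleton
// minimizers keep their plain value.
// [[Rcpp::export(name = ".cpp_seed_keys")]]
CharacterVector cpp_seed_keys(CharacterVector value, CharacterVector ivh) {
    R_xlen_t n = value.size();
    if (ivh.size() != n) stop("value and ivh must have equal length");
    CharacterVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        uint64_t v = ivh_from_hex(String(value[i]).get_cstring());
        uint64_t h = ivh_from_hex(String(ivh[i]).get_cstring());
        uint64_t f = (h == 0) ? 0 : ivh_mix64_nz(h);
        out[i] = ivh_to_hex(v ^ f);
    }
    return out;
}
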