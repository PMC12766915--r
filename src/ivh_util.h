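#ifndef IVHASH_UTIL_H
#define IVHASH_UTIL_H

#include <cstdint>
#include <string>
#include <cstdio>
#include <cstdlib>

// Golden-ratio constant: substituted whenever the avalanche mixer would map a
// finite input to 0, so that 0 stays reserved for "no interval information".
static const uint64_t IVH_GOLDEN = 0x9E3779B97F4A7C15ULL;

// splitmix64 finalizer: the fixed avalanche mixer used for partial interval
// hashes, minimizer values and seed-key mixing.  Stable part of the hash
// contract; changing any constant changes every hash the package emits.
static inline uint64_t ivh_mix64(uint64_t z) {
    z ^= z >> 30;
    z *= 0xBF58476D1CE4E5B9ULL;
    z ^= z >> 27;
    z *= 0x94D049BB133111EBULL;
    z ^= z >> 31;
    return z;
}

// Mixer with 0 excluded from the image (0 in -> IVH_GOLDEN out).
static inline uint64_t ivh_mix64_nz(uint64_t z) {
    uint64_t h = ivh_mix64(z);
    return h == 0 ? IVH_GOLDEN : h;
}

static inline uint64_t ivh_rotl(uint64_t x, unsigned s) {
    s &= 63u;
    if (s == 0) return x;
    return (x << s) | (x >> (64u - s));
}

static inline std::string ivh_to_hex(uint64_t x) {
    char buf[17];
    std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)x);
    return std::string(buf);
}

static inline uint64_t ivh_from_hex(const char* s) {
    uint64_t x = 0;
    for (; *s; ++s) {
        char c = *s;
        int d;
        if (c >= '0' && c <= '9') d = c - '0';
        else if (c >= 'a' && c <= 'f') d = c - 'a' + 10;
        else if (c >= 'A' && c <= 'F') d = c - 'A' + 10;
        else break;
        x = (x << 4) | (uint64_t)d;
    }
    return x;
}

#endif
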