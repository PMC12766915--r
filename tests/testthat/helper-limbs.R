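# Pure-R unsigned 64-bit arithmetic on 16-bit limbs (least-significant
# first), used by the independent interval-hash oracle. Shares no code with
# the package's compiled implementation.

u64_zero <- function() integer(4)

u64_from_num <- function(n) {
    # n: non-negative double < 2^53
    out <- integer(4)
    for (i in 1:4) {
        out[i] <- as.integer(n %% 65536)
        n <- n %/% 65536
    }
    out
}

u64_from_hex <- function(s) {
    s <- tolower(s)
    s <- paste0(strrep("0", 16L - nchar(s)), s)
    v <- strtoi(substring(s, c(13, 9, 5, 1), c(16, 12, 8, 4)), 16L)
    as.integer(v)
}

u64_to_hex <- function(x) {
    paste0(sprintf("%04x", x[4]), sprintf("%04x", x[3]),
           sprintf("%04x", x[2]), sprintf("%04x", x[1]))
}

u64_xor <- function(a, b) bitwXor(a, b)

u64_is_zero <- function(a) all(a == 0L)

u64_lt <- function(a, b) {
    for (i in 4:1) {
        if (a[i] < b[i]) return(TRUE)
        if (a[i] > b[i]) return(FALSE)
    }
    FALSE
}

u64_shl <- function(a, s) {
    s <- as.integer(s)
    if (s <= 0) return(a)
    if (s >= 64) return(integer(4))
    q <- s %/% 16L
    r <- s %% 16L
    v <- if (q > 0) c(integer(q), a)[1:4] else a
    if (r > 0) {
        prev <- c(0L, v[1:3])
        v <- as.integer((v * 2^r) %% 65536 + prev %/% 2^(16 - r))
    }
    v
}

u64_shr <- function(a, s) {
    s <- as.integer(s)
    if (s <= 0) return(a)
    if (s >= 64) return(integer(4))
    q <- s %/% 16L
    r <- s %% 16L
    v <- if (q > 0) c(a[(q + 1):4], integer(q)) else a
    if (r > 0) {
        nxt <- c(v[2:4], 0L)
        v <- as.integer(v %/% 2^r + (nxt %% 2^r) * 2^(16 - r))
    }
    v
}

u64_rotl <- function(a, s) {
    s <- as.integer(s) %% 64L
    if (s == 0) return(a)
    u64_xor(u64_shl(a, s), u64_shr(a, 64L - s))
}

u64_add <- function(a, b) {
    out <- integer(4)
    carry <- 0
    for (i in 1:4) {
        t <- a[i] + b[i] + carry
        out[i] <- as.integer(t %% 65536)
        carry <- t %/% 65536
    }
    out
}

u64_mul <- function(a, b) {
    acc <- numeric(4)
    for (i in 1:4)
        for (j in 1:4)
            if (i + j - 1 <= 4)
                acc[i + j - 1] <- acc[i + j - 1] + as.numeric(a[i]) * b[j]
    out <- integer(4)
    carry <- 0
    for (i in 1:4) {
        t <- acc[i] + carry
        out[i] <- as.integer(t %% 65536)
        carry <- t %/% 65536
    }
    out
}
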