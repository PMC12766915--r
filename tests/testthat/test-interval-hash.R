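ZERO <- strrep("0", 16)

test_that("slice extraction follows the interval indexing contract", {
    expect_equal(sliceAt(numeric(0), 0, 1),
                 list(slice2w = c(Inf, Inf), slice4w = rep(Inf, 4)))
    expect_equal(sliceAt(c(171, 342), 1, 1),
                 list(slice2w = c(171, 342), slice4w = c(Inf, 171, 342, Inf)))
    expect_equal(sliceAt(c(171, 342), 0, 1),
                 list(slice2w = c(Inf, 171), slice4w = c(Inf, Inf, 171, 342)))
    # central 2W span of the 4W slice equals the 2W slice, for any i, W
    v <- c(5, 9, 13, 171, 2, 88)
    for (W in 1:3)
        for (i in 0:length(v)) {
            s <- sliceAt(v, i, W)
            expect_equal(s$slice4w[(W + 1):(3 * W)], s$slice2w)
        }
    expect_error(sliceAt(c(1, 2), 3, 1), "out of range")
    expect_error(sliceAt(c(1, 2), -1, 1), "out of range")
})

test_that("unit interval is the 4W-slice minimum, Inf on empty context", {
    expect_equal(unitInterval(c(Inf, 171, 342, Inf)), 171)
    expect_equal(unitInterval(rep(Inf, 4)), Inf)
    expect_equal(unitInterval(c(340, 171, 171, 513)), 171)
})

test_that("quantization normalises by the unit and rounds half away from zero", {
    expect_equal(quantizeIntervals(c(171, 342), 171), c(4, 8))
    expect_equal(quantizeIntervals(c(Inf, 171), 171), c(Inf, 4))
    # round(171/150*4) = round(4.56) = 5
    expect_equal(quantizeIntervals(c(150, 171), 150), c(4, 5))
    expect_error(quantizeIntervals(c(1, 2), 0), "unit")
    expect_error(quantizeIntervals(c(1, Inf), Inf), "Inf")
    expect_equal(quantizeIntervals(rep(Inf, 4), Inf), rep(Inf, 4))
})

test_that("partial hashes: zero sentinel for Inf, nonzero avalanche otherwise", {
    expect_equal(partialHash(Inf), ZERO)
    # slot does not enter the partial hash (rotation happens in combine)
    expect_equal(partialHash(c(4, 4)), rep(partialHash(4), 2))
    expect_false(partialHash(4) == partialHash(8))
    # never zero for finite inputs (0 is reserved)
    expect_true(all(partialHash(0:500) != ZERO))
})

test_that("combination is XOR of slot-rotations: identity, order sensitivity", {
    expect_equal(combinePartials(rep(ZERO, 6)), ZERO)
    # single nonzero entry: result is its rotation, nonzero
    p <- partialHash(4)
    one <- combinePartials(c(ZERO, ZERO, p, ZERO, ZERO, ZERO))
    expect_false(one == ZERO)
    # in the last slot the rotation is by 0 bits: identity
    expect_equal(combinePartials(c(ZERO, ZERO, ZERO, ZERO, ZERO, p)), p)
    a <- partialHash(4); b <- partialHash(8)
    expect_false(combinePartials(c(a, b)) == combinePartials(c(b, a)))
})

test_that("empty interval vectors and singletons hash to exactly zero", {
    expect_equal(intervalHashes(numeric(0)), ZERO)
    for (W in 0:4)
        expect_equal(intervalHashes(numeric(0), W = W), ZERO)
    expect_equal(hashOccurrence(numeric(0), 0), ZERO)
})

test_that("perfectly periodic vectors give one hash at interior occurrences", {
    for (p in c(171, 2052)) {
        h <- intervalHashes(rep(p, 30), W = 3)
        interior <- h[(2 * 3 + 1):(30 - 2 * 3 + 1)]  # occurrences 2W..N-2W
        expect_length(unique(interior), 1)
        expect_false(unique(interior) == ZERO)
    }
})

test_that("strand canonicalization: hash(v, i, +) = hash(rev(v), N-i, -)", {
    set.seed(42)
    for (rep_i in 1:50) {
        n <- sample(0:8, 1)
        v <- sample(c(10, 171, 342, 2052, 30), n, replace = TRUE)
        W <- sample(1:3, 1)
        expect_equal(intervalHashes(v, "+", W = W),
                     rev(intervalHashes(rev(v), "-", W = W)))
    }
})

test_that("hashes are scale invariant in the intervals", {
    set.seed(7)
    for (rep_i in 1:40) {
        v <- sample(c(5, 9, 171, 513, 60), sample(1:10, 1), replace = TRUE)
        h <- intervalHashes(v)
        for (cc in c(2, 3, 10))
            expect_equal(intervalHashes(cc * v), h)
    }
})

test_that("hash of occurrence i depends only on intervals within 2W of it", {
    set.seed(13)
    W <- 2
    v <- sample(c(171, 342, 513, 60), 12, replace = TRUE)
    h0 <- intervalHashes(v, W = W)
    for (i in 0:12) {
        window <- seq(i - 2 * W, i + 2 * W - 1)  # 0-based interval indices
        outside <- setdiff(0:11, window)
        for (j in outside) {
            v2 <- v
            v2[j + 1] <- v2[j + 1] + 1000
            expect_equal(intervalHashes(v2, W = W)[i + 1], h0[i + 1])
        }
    }
})

test_that("hash is zero exactly when the whole 2W context is absent", {
    set.seed(3)
    for (rep_i in 1:30) {
        n <- sample(0:6, 1)
        v <- sample(c(9, 171, 342), n, replace = TRUE)
        W <- sample(1:3, 1)
        h <- intervalHashes(v, W = W)
        for (i in 0:n) {
            s <- sliceAt(v, i, W)
            expect_equal(h[i + 1] == ZERO, all(is.infinite(s$slice2w)))
        }
    }
})

test_that("production hashes agree with the literal pure-R five-step oracle", {
    set.seed(99)
    for (rep_i in 1:60) {
        n <- sample(0:10, 1)
        v <- sample(c(3, 9, 57, 171, 342, 2052, 19999), n, replace = TRUE)
        W <- sample(1:3, 1)
        strands <- sample(c("+", "-"), n + 1, replace = TRUE)
        expect_equal(intervalHashes(v, strands, W = W),
                     o_hash_vector(v, strands, W = W))
    }
})

test_that("interval vectors split at gaps above the separation threshold", {
    expect_equal(splitPositions(c(0, 5000, 30000), 20000),
                 list(c(0, 5000), 30000))
    expect_equal(splitPositions(c(0, 20000), 20000), list(c(0, 20000)))
    expect_equal(splitPositions(numeric(0)), list())
    expect_error(splitPositions(c(5, 3)), "increasing")
    # concatenation reproduces the input
    set.seed(5)
    pos <- cumsum(sample(c(100, 500, 25000), 30, replace = TRUE))
    segs <- splitPositions(pos, 20000)
    expect_equal(unlist(segs), pos)
    expect_true(all(vapply(segs, function(s) all(diff(s) <= 20000), TRUE)))
})

test_that("input validation rejects bad intervals and parameters", {
    expect_error(intervalHashes(c(171, NA)), "NA")
    expect_error(intervalHashes(c(171, 0.5)), ">= 1")
    expect_error(intervalHashes(171, W = -1), "W")
    expect_error(intervalHashes(171, resolution = 0), "resolution")
    expect_error(hashOccurrence(c(171), 2), "out of range")
})
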