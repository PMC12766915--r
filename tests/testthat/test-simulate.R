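test_that("monomer libraries have the configured pairwise divergence", {
    set.seed(40)
    expect_length(makeMonomerLibrary(1, 171, 0.1), 1)
    lib0 <- makeMonomerLibrary(6, 171, 0)
    expect_length(unique(lib0), 1)
    # divergence 0.1: Hamming distance to monomer 0 ~ Binomial(171, 0.1);
    # [8, 27] covers ~99% of that mass, so >= 95% of monomers fall inside
    hams <- replicate(40, {
        lib <- makeMonomerLibrary(2, 171, 0.1)
        sum(strsplit(lib[1], "")[[1]] != strsplit(lib[2], "")[[1]])
    })
    expect_gte(mean(hams >= 8 & hams <= 27), 0.95)
})

test_that("event-free arrays have exact length and per-event arithmetic holds", {
    set.seed(41)
    cfg0 <- horConfig(nUnits = 7, truncationProb = 0, insertionProb = 0,
                      unitMutationRate = 0)
    arr <- buildArray(cfg0)
    expect_equal(nchar(arr$seq), 7 * 12 * 171)
    expect_equal(nrow(arr$layout), 7 * 12)
    # layout tiles the array exactly
    expect_equal(arr$layout$start, c(0, head(cumsum(
        arr$layout$end - arr$layout$start), -1)))
    expect_equal(tail(arr$layout$end, 1), nchar(arr$seq))
    # truncating exactly one monomer per unit shrinks by nUnits * monomerLen
    cfgT <- horConfig(nUnits = 7, truncationProb = 1, truncationMonomers = 1,
                      insertionProb = 0, unitMutationRate = 0)
    arrT <- buildArray(cfgT)
    expect_equal(nchar(arrT$seq), 7 * (12 - 1) * 171)
    # insertions after every unit add nUnits * insertionLen
    cfgI <- horConfig(nUnits = 7, truncationProb = 0, insertionProb = 1,
                      insertionLen = 500, unitMutationRate = 0)
    arrI <- buildArray(cfgI)
    expect_equal(nchar(arrI$seq), 7 * 12 * 171 + 7 * 500)
    expect_equal(sum(arrI$layout$type == "insertion"), 7)
})

test_that("an event-free array is periodic: one interior hash per value", {
    set.seed(43)
    cfg <- horConfig(nUnits = 20, monomerDivergence = 0, unitMutationRate = 0,
                     truncationProb = 0, insertionProb = 0)
    arr <- buildArray(cfg)
    st <- seedTables(c(x = arr$seq), ivhParams())$x
    g <- groupByValue(st)
    W <- 3L
    checked <- 0
    for (gi in seq_len(nrow(g))) {
        n_occ <- g$n[gi]
        if (n_occ < 4 * W + 2) next
        rows <- st[st$value == g$value[gi], ]
        rows <- rows[order(rows$pos), ]
        interior <- rows$ivh[(2 * W + 1):(n_occ - 2 * W)]
        expect_length(unique(interior), 1)
        checked <- checked + 1
    }
    expect_gt(checked, 10)
})

test_that("haplotype pairs differ at exactly the drawn variants", {
    set.seed(44)
    arr <- rand_seq(5000)
    h0 <- makeHaplotypes(arr, 0)
    expect_equal(h0$hapA, h0$hapB)
    h <- makeHaplotypes(arr, 25)
    expect_equal(nrow(h$variants), 25)
    expect_false(anyDuplicated(h$variants$pos) > 0)
    expect_true(all(h$variants$pos >= 0 & h$variants$pos < 5000))
    a <- strsplit(h$hapA, "")[[1]]
    b <- strsplit(h$hapB, "")[[1]]
    expect_equal(sum(a != b), 25)
    expect_equal(which(a != b) - 1L, h$variants$pos)
    expect_equal(b[h$variants$pos + 1L], h$variants$alt)
})

test_that("error-free reads are exact substrings up to reverse complement", {
    set.seed(45)
    tmpl <- rand_seq(20000)
    cfg <- horConfig(readLenMean = 3000, readLenSd = 300, readErrorRate = 0,
                     readDepth = 3)
    sim <- simulateReads(tmpl, cfg)
    rc <- function(s) {
        m <- c(A = "T", C = "G", G = "C", T = "A")
        paste(rev(m[strsplit(s, "")[[1]]]), collapse = "")
    }
    for (i in seq_along(sim$reads)) {
        o <- sim$origins[i, ]
        want <- substr(tmpl, o$start + 1, o$end)
        if (o$strand == "-") want <- rc(want)
        expect_equal(unname(sim$reads[i]), want)
    }
    # coverage within 10% of requested depth
    total <- sum(sim$origins$end - sim$origins$start)
    expect_lt(abs(total / nchar(tmpl) - 3) / 3, 0.1)
})

test_that("read errors match the configured substitution rate", {
    set.seed(46)
    tmpl <- rand_seq(30000)
    cfg <- horConfig(readLenMean = 5000, readLenSd = 0, readErrorRate = 0.01,
                     readDepth = 2)
    sim <- simulateReads(tmpl, cfg)
    rc <- function(s) {
        m <- c(A = "T", C = "G", G = "C", T = "A")
        paste(rev(m[strsplit(s, "")[[1]]]), collapse = "")
    }
    rates <- vapply(seq_along(sim$reads), function(i) {
        o <- sim$origins[i, ]
        want <- substr(tmpl, o$start + 1, o$end)
        if (o$strand == "-") want <- rc(want)
        mean(strsplit(want, "")[[1]] != strsplit(sim$reads[[i]], "")[[1]])
    }, numeric(1))
    # per-read binomial(5000, 0.01): 99.9% bounds ~ [0.0055, 0.0145]
    expect_true(all(rates > 0.004 & rates < 0.016))
    expect_equal(mean(rates), 0.01, tolerance = 0.15)
})

test_that("identical config and seed give byte-identical simulations", {
    cfg <- horConfig(nUnits = 8, readDepth = 2, readLenMean = 4000,
                     readLenSd = 400, rngSeed = 99)
    s1 <- simulateHOR(cfg)
    s2 <- simulateHOR(cfg)
    expect_identical(as.character(horArray(s1)), as.character(horArray(s2)))
    expect_identical(as.character(horReads(s1)), as.character(horReads(s2)))
    expect_identical(horOrigins(s1), horOrigins(s2))
    expect_identical(horLayout(s1), horLayout(s2))
    expect_identical(horVariants(s1), horVariants(s2))
})

test_that("simulation accessors and validity hold together", {
    sim <- fx_small_sim()
    cfg <- sim@config
    expect_s4_class(sim, "HORSimulation")
    expect_equal(length(horHaplotypes(sim)), 2)
    expect_equal(nrow(horOrigins(sim)), length(horReads(sim)))
    expect_equal(nrow(horVariants(sim)), cfg@nHapVariants)
    lay <- horLayout(sim)
    expect_equal(tail(lay$end, 1), length(horArray(sim)))
    # read origins stay within haplotype bounds
    org <- horOrigins(sim)
    hl <- Biostrings::width(horHaplotypes(sim))[
        match(org$hap, names(horHaplotypes(sim)))]
    expect_true(all(org$start >= 0 & org$end <= hl))
    expect_output(show(sim), "HORSimulation")
    # invalid configs are rejected
    expect_error(horConfig(monomerDivergence = 1.5), "must be in")
    expect_error(horConfig(nUnits = 0), ">= 1")
})
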