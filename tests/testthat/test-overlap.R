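revcomp <- function(s) {
    m <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(m[strsplit(s, "")[[1]]]), collapse = "")
}

test_that("anchors between identical sequences lie on the diagonal", {
    set.seed(20)
    s <- rand_seq(4000)
    st <- seedTables(c(a = s, b = s), ivhParams(k = 15, w = 10))
    anc <- matchAnchors(st$a, st$b)
    expect_gt(nrow(anc), 100)
    expect_true(all(anc$qpos == anc$tpos))
    expect_true(all(anc$rel_strand == "+"))
})

test_that("anchors against the reverse complement are all minus strand", {
    set.seed(22)
    s <- rand_seq(4000)
    st <- seedTables(c(a = s, b = revcomp(s)), ivhParams(k = 15, w = 10))
    anc <- matchAnchors(st$a, st$b)
    expect_gt(nrow(anc), 100)
    expect_true(all(anc$rel_strand == "-"))
})

test_that("chain score matches exhaustive subset enumeration on toy anchors", {
    p <- ivhParams(chainMinScore = 0, chainGap = 100)
    cases <- list(
        list(q = c(10, 30, 50), t = c(110, 130, 150), s = c(15, 15, 15)),
        list(q = c(10, 35, 50), t = c(110, 120, 160), s = c(15, 15, 15)),
        list(q = c(10, 20, 200), t = c(110, 120, 150), s = c(15, 10, 15)),
        list(q = c(5, 5, 60, 80), t = c(100, 150, 160, 170),
             s = c(10, 10, 10, 10)))
    for (cs in cases) {
        anc <- data.frame(qpos = cs$q, tpos = cs$t, rel_strand = "+",
                          span = cs$s)
        rec <- chainAnchors(anc, "q", 1000, "t", 1000, p)
        want <- o_best_chain_score(cs$q, cs$t, cs$s, p@chainGap, p@chainGamma)
        expect_equal(max(rec$score), want, tolerance = 1e-9)
    }
})

test_that("anchor clusters separated beyond the gap bound form two chains", {
    # two colinear clusters 20 kb apart on both axes (gap bound 10 kb)
    q <- c(100, 200, 300, 20300, 20400, 20500)
    t <- q + 50
    anc <- data.frame(qpos = q, tpos = t, rel_strand = "+", span = 19)
    rec <- chainAnchors(anc, "q", 30000, "t", 30000,
                        ivhParams(chainMinScore = 10))
    expect_equal(nrow(rec), 2)
    # equally spaced colinear anchors chain into one
    anc1 <- data.frame(qpos = seq(100, 2000, by = 100),
                       tpos = seq(600, 2500, by = 100),
                       rel_strand = "+", span = 19)
    rec1 <- chainAnchors(anc1, "q", 3000, "t", 3000,
                         ivhParams(chainMinScore = 10))
    expect_equal(nrow(rec1), 1)
    expect_equal(rec1$n_anchors, nrow(anc1))
})

test_that("reverse-strand chains report forward-query PAF coordinates", {
    set.seed(23)
    s <- rand_seq(6000)
    seqs <- c(a = s, b = revcomp(s))
    paf <- detectOverlaps(seqs, ivhParams(k = 15, w = 10, chainMinScore = 100))
    expect_gt(nrow(paf), 0)
    top <- paf[which.max(paf$score), ]
    expect_equal(top$strand, "-")
    expect_true(top$qstart >= 0 && top$qend <= 6000 && top$qstart < top$qend)
    expect_gt(top$qend - top$qstart, 5000)  # spans most of the pair
})

test_that("PAF records satisfy coordinate and match-count invariants", {
    sim <- fx_small_sim()
    paf <- detectOverlaps(horReads(sim)[1:8], ivhParams(hpc = TRUE))
    expect_gt(nrow(paf), 5)
    expect_true(all(paf$qstart >= 0 & paf$qstart < paf$qend &
                    paf$qend <= paf$qlen))
    expect_true(all(paf$tstart >= 0 & paf$tstart < paf$tend &
                    paf$tend <= paf$tlen))
    expect_true(all(paf$residue_matches <= paf$block_len))
    expect_true(all(paf$strand %in% c("+", "-")))
    expect_true(all(paf$qname < paf$tname))  # unordered pairs emitted once
})

test_that("overlap detection is symmetric under swapping the pair", {
    sim <- fx_small_sim()
    reads <- horReads(sim)[3:4]
    p <- ivhParams(hpc = TRUE)
    ab <- detectOverlaps(stats::setNames(reads, c("a", "b")), p)
    ba <- detectOverlaps(stats::setNames(reads, c("b", "a")), p)
    # the same interval pairs are reported with query/target roles swapped
    expect_equal(nrow(ab), nrow(ba))
    expect_equal(sort(ab$strand), sort(ba$strand))
    sig_ab <- sort(paste(ab$qstart, ab$qend, ab$tstart, ab$tend))
    sig_ba <- sort(paste(ba$tstart, ba$tend, ba$qstart, ba$qend))
    expect_equal(sig_ab, sig_ba)
})

test_that("the match-rate filter is strict at the boundary", {
    rec <- data.frame(residue_matches = c(300L, 150L, 200L, 10L),
                      block_len = c(1000L, 1000L, 1000L, 0L))
    expect_warning(out <- filterMatchRate(rec, 0.2), "zero block length")
    expect_equal(out$residue_matches, 300L)  # 0.3 kept; 0.15 and 0.2 dropped
})

test_that("overhang classification separates dovetail, contained, internal", {
    mk <- function(qlen, qs, qe, tlen, ts, te, strand = "+")
        data.frame(qlen = qlen, qstart = qs, qend = qe, strand = strand,
                   tlen = tlen, tstart = ts, tend = te)
    # full-length identical pair: zero flanks everywhere -> contained
    expect_equal(classifyOverhang(mk(5000, 0, 5000, 5000, 0, 5000)),
                 "contained")
    # suffix-prefix join with zero flanks at the joined ends -> dovetail
    expect_equal(classifyOverhang(mk(40000, 0, 10000, 40000, 30000, 40000)),
                 "dovetail")
    # mid-read repeat match with 30 kb flanks -> internal
    expect_equal(classifyOverhang(mk(70000, 30000, 40000, 70000, 30000,
                                     40000)), "internal")
    # one read inside the other within tolerance -> contained
    expect_equal(classifyOverhang(mk(10000, 100, 9900, 50000, 20000, 29800)),
                 "contained")
    # minus-strand dovetail: flip query coordinates before judging
    expect_equal(classifyOverhang(mk(40000, 30000, 40000, 40000, 30000,
                                     40000, strand = "-")), "dovetail")
})

test_that("augmented dotplot points are a subset of plain points", {
    sim <- fx_small_sim()
    reads <- as.character(horReads(sim))
    p <- ivhParams(hpc = TRUE)
    a <- dotplotMatches(reads[1], reads[2], mode = "augmented", params = p)
    b <- dotplotMatches(reads[1], reads[2], mode = "plain", params = p)
    expect_gt(nrow(a), 0)
    expect_lte(nrow(a), nrow(b))
    keyA <- paste(a$posA, a$posB, a$rel_strand)
    keyB <- paste(b$posA, b$posB, b$rel_strand)
    expect_true(all(keyA %in% keyB))
    # identity dotplot keeps the main diagonal in augmented mode
    aa <- dotplotMatches(reads[1], reads[1], mode = "augmented", params = p)
    diag_pts <- sum(aa$posA == aa$posB & aa$rel_strand == "+")
    expect_gt(diag_pts, 100)
})

test_that("the key-frequency ceiling thins repetitive dotplot points", {
    sim <- fx_small_sim()
    arr <- as.character(horArray(sim))
    half <- substr(arr, 1, 30000)
    p <- ivhParams(hpc = TRUE)
    all_pts <- dotplotMatches(half, half, mode = "plain", params = p)
    rare <- dotplotMatches(half, half, mode = "plain", params = p,
                           maxKeyFreq = 10)
    expect_lt(nrow(rare), nrow(all_pts))
    aug_rare <- dotplotMatches(half, half, mode = "augmented", params = p,
                               maxKeyFreq = 10)
    expect_lte(nrow(aug_rare), nrow(rare) + nrow(all_pts))  # sanity
    expect_gt(nrow(aug_rare), 0)
})

test_that("simulated neighbour reads are recovered by augmented-mode chains", {
    sim <- fx_small_sim()
    org <- horOrigins(sim)
    p <- ivhParams(hpc = TRUE)
    # same-haplotype pairs with >= 4 kb true overlap (8 kb reads)
    idx <- which(org$hap == "hapA")[1:12]
    pairs <- list()
    for (a in idx) for (b in idx) if (a < b &&
        fx_true_overlap(org, a, b) >= 4000) pairs[[length(pairs) + 1]] <- c(a, b)
    expect_gt(length(pairs), 5)
    reads <- horReads(sim)
    found <- 0
    for (pr in pairs) {
        pafs <- detectOverlaps(reads[pr], p)
        if (nrow(pafs) > 0 && max(pafs$score) >= p@chainMinScore)
            found <- found + 1
    }
    expect_equal(found, length(pairs))
})

test_that("anchor offset statistics flag off-diagonal repeat matches", {
    sim <- fx_small_sim()
    seeds <- fx("offdiag_seeds", function()
        seedTables(horReads(sim)[1:6], ivhParams(hpc = TRUE, mode = "plain")))
    st <- anchorOffsetStats(seeds, cbind(1, 2), band = 2052)
    expect_equal(nrow(st), 1)
    expect_gt(st$total, 0)
    expect_gte(st$offdiag, 0)
    expect_lte(st$offdiag, st$total)
    # identical unique-sequence reads: anchors sit on the zero-offset diagonal
    set.seed(33)
    rs <- rand_seq(20000)
    rseeds <- seedTables(c(x = rs, y = rs), ivhParams())
    st2 <- anchorOffsetStats(rseeds, cbind(1, 2), band = 1000)
    expect_lt(st2$offdiag / st2$total, 0.02)
})
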