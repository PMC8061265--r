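test_that("DepthTrack validates its window grid", {
    expect_s4_class(DepthTrack("c", c(0, 1000), c(1000, 2000), c(1, 2)),
                    "DepthTrack")
    # terminal short window accepted
    expect_s4_class(DepthTrack("c", c(0, 1000), c(1000, 1400), c(1, 2)),
                    "DepthTrack")
    # overlap, gap, unsorted, negative depth all rejected
    expect_error(DepthTrack("c", c(0, 500), c(1000, 1500), c(1, 2)), "tile")
    expect_error(DepthTrack("c", c(0, 1500), c(1000, 2500), c(1, 2)), "tile")
    expect_error(DepthTrack("c", c(1000, 0), c(2000, 1000), c(1, 2)), "sorted")
    expect_error(DepthTrack("c", 0, 1000, -1), "depth")
})

test_that("depth normalisation divides by the baseline contig mean", {
    bl <- DepthTrack("chr1", c(0, 1000), c(1000, 2000), c(40, 40))
    tr <- DepthTrack("chr2", c(0, 1000, 2000), c(1000, 2000, 3000),
                     c(40, 2000, 0))
    nn <- normalizeDepth(tr, bl)
    expect_equal(depth(nn), c(1, 50, 0))
    zero <- DepthTrack("chr1", 0, 1000, 0)
    expect_error(normalizeDepth(tr, zero), "zero mean")
})

test_that("ratio track masks low-control windows instead of dividing", {
    mk <- function(d) DepthTrack("c", (seq_along(d) - 1) * 1000,
                                 seq_along(d) * 1000, d)
    rt <- ratioTrack(mk(c(1, 1, 12.5, 0.2)), mk(c(1, 0, 0.25, 1)))
    expect_equal(ratio(rt), c(1, NA, 50, 0.2))       # inclusive floor at 0.25
    expect_equal(masked(rt), c(FALSE, TRUE, FALSE, FALSE))
    # identical tracks give ratio 1 everywhere
    expect_equal(ratio(ratioTrack(mk(c(2, 3)), mk(c(2, 3)))), c(1, 1))
    expect_error(ratioTrack(mk(1:3), mk(1:2)), "grid")
})

test_that("region calling merges short masked gaps and drops short runs", {
    # all-background track calls nothing
    none <- makeRatioTrack(rep(1, 50), rep(FALSE, 50))
    expect_length(callAmplifiedRegions(none), 0)

    # two 10-window runs at ratio 50 split by 4 masked windows merge
    r <- c(rep(1, 10), rep(50, 10), rep(NA, 4), rep(50, 10), rep(1, 10))
    m <- is.na(r)
    rt <- makeRatioTrack(ifelse(m, 0, r), m)
    reg <- callAmplifiedRegions(rt, foldMin = 5, minWindows = 5,
                                maxMaskGap = 10)
    expect_length(reg, 1)
    expect_equal(start(reg) - 1L, 10000)
    expect_equal(end(reg), 34000)
    expect_equal(S4Vectors::mcols(reg)$n_windows, 20)
    expect_equal(S4Vectors::mcols(reg)$n_masked_internal, 4)
    expect_equal(S4Vectors::mcols(reg)$fold, 50)

    # a gap longer than maxMaskGap splits the run
    reg2 <- callAmplifiedRegions(rt, maxMaskGap = 3)
    expect_length(reg2, 2)

    # runs below minWindows are discarded
    short <- makeRatioTrack(c(rep(1, 5), rep(50, 3), rep(1, 5)),
                            rep(FALSE, 13))
    expect_length(callAmplifiedRegions(short, minWindows = 5), 0)

    # an unmasked sub-threshold window always breaks a run
    r3 <- c(rep(50, 6), 1, rep(50, 6))
    reg3 <- callAmplifiedRegions(makeRatioTrack(r3, rep(FALSE, 13)))
    expect_length(reg3, 2)
})

test_that("region calling matches a brute-force oracle on random tracks", {
    set.seed(7)
    for (i in 1:30) {
        n <- sample(30:200, 1)
        ratioVals <- exp(rnorm(n, 0, 1)) *
            sample(c(1, 50), n, replace = TRUE, prob = c(0.8, 0.2))
        maskVals <- runif(n) < 0.15
        foldMin <- runif(1, 2, 10)
        minWindows <- sample(1:6, 1)
        maxMaskGap <- sample(0:10, 1)
        got <- callAmplifiedRegions(makeRatioTrack(ratioVals, maskVals),
                                    foldMin, minWindows, maxMaskGap)
        want <- oracleRegions(ifelse(maskVals, NA, ratioVals), maskVals,
                              foldMin, minWindows, maxMaskGap)
        expect_equal(length(got), length(want), info = paste("case", i))
        if (length(want)) {
            expect_equal(as.numeric(start(got) - 1L),
                         vapply(want, function(w) (w$first - 1) * 1000, 0))
            expect_equal(as.numeric(end(got)),
                         vapply(want, function(w) w$last * 1000, 0))
            expect_equal(S4Vectors::mcols(got)$fold,
                         vapply(want, `[[`, 0, "fold"))
            expect_equal(as.numeric(S4Vectors::mcols(got)$n_windows),
                         vapply(want, function(w) as.numeric(w$n), 0))
        }
        # called regions never overlap
        if (length(got) > 1)
            expect_true(all(start(got)[-1] > end(got)[-length(got)]))
    }
})

test_that("the pipeline is invariant to library sequencing depth", {
    d <- simulateDepth(simPreset("nakh_like", seed = 31L))
    scale <- function(tr, c) DepthTrack(as.character(seqnames(tr))[1],
                                        start(tr) - 1L, end(tr),
                                        depth(tr) * c)
    run <- function(case, caseBl, ctrl, ctrlBl)
        callAmplifiedRegions(ratioTrack(normalizeDepth(case, caseBl),
                                        normalizeDepth(ctrl, ctrlBl)))
    base <- run(d$case, d$caseBaseline, d$control, d$controlBaseline)
    scaled <- run(scale(d$case, 3.7), scale(d$caseBaseline, 3.7),
                  scale(d$control, 0.4), scale(d$controlBaseline, 0.4))
    expect_equal(start(base), start(scaled))
    expect_equal(end(base), end(scaled))
    expect_equal(S4Vectors::mcols(base)$fold, S4Vectors::mcols(scaled)$fold)
})

test_that("planted segment midpoint is recovered across seeds", {
    hits <- 0L
    for (s in 1:20) {
        d <- simulateDepth(simPreset("nakh_like", seed = 5000L + s))
        rt <- ratioTrack(normalizeDepth(d$case, d$caseBaseline),
                         normalizeDepth(d$control, d$controlBaseline))
        reg <- callAmplifiedRegions(rt)
        if (length(reg) >= 1) {
            top <- reg[which.max(S4Vectors::mcols(reg)$n_windows)]
            mid <- (start(top) - 1 + end(top)) / 2
            if (abs(mid - 500000) < 2000) hits <- hits + 1L
        }
    }
    expect_gte(hits, 19L)
})

test_that("regions annotate to the genes they span under half-open rules", {
    genes <- GenomicRanges::GRanges(
        "chr2", IRanges::IRanges(start = c(1, 1001, 2001, 3001, 4001, 5001),
                                 end = c(800, 1800, 2800, 3800, 4800, 5800)),
        name = paste0("g", 1:6))
    region <- GenomicRanges::GRanges("chr2", IRanges::IRanges(1001, 4800))
    expect_equal(annotateRegion(region, genes), paste0("g", 2:5))
    far <- GenomicRanges::GRanges("chr2", IRanges::IRanges(9001, 9900))
    expect_equal(annotateRegion(far, genes), character(0))
    # 0-based half-open: gene ending where the region starts does not overlap
    gBed <- GenomicRanges::GRanges("chr2", IRanges::IRanges(1, 1000),
                                   name = "edge")  # 0-based [0, 1000)
    reg2 <- GenomicRanges::GRanges("chr2", IRanges::IRanges(1001, 2000))
    expect_equal(annotateRegion(reg2, gBed), character(0))
})
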