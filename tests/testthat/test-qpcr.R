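test_that("standard-curve fit recovers amplification efficiency", {
    # perfect doubling: Cq rises log2(10) cycles per decade of dilution
    fit <- fitStandardCurve(c(0, -1, -2), c(20, 23.3219281, 26.6438562))
    expect_equal(efficiency(fit), 2, tolerance = 1e-6)
    expect_equal(fit@slope, -3.3219281, tolerance = 1e-6)
    expect_equal(fit@rSquared, 1, tolerance = 1e-9)

    # closed form at slope -3.45
    dil <- c(0, -1, -2, -3)
    fit2 <- fitStandardCurve(dil, 20 - 3.45 * dil)
    expect_equal(efficiency(fit2), 1.9491940296, tolerance = 1e-8)

    # noiseless generated curves for a range of true efficiencies
    for (e in c(1.8, 1.9, 2.0)) {
        cq <- 25 - log(10^dil) / log(e)
        fit3 <- fitStandardCurve(dil, cq)
        expect_equal(efficiency(fit3), e, tolerance = 1e-9)
    }

    expect_error(fitStandardCurve(c(0, -1), c(20, 23)), "insufficient")
    expect_error(fitStandardCurve(c(0, -1, -2), c(20, 18, 16)), "inverted")
})

test_that("Pfaffl fold matches closed form and classic delta-delta-Cq", {
    expect_equal(pfafflFold(2, 5, 2, 0), 32)
    expect_equal(pfafflFold(2, 0, 2, 0), 1)
    expect_equal(pfafflFold(1.9, 3, 2, 1), 3.4295, tolerance = 1e-10)

    # E = 2 on both sides reduces to 2^(dCq_t - dCq_r)
    set.seed(42)
    for (i in 1:25) {
        a <- runif(1, -8, 8); b <- runif(1, -8, 8)
        expect_equal(pfafflFold(2, a, 2, b), 2^(a - b))
    }

    # strictly increasing in target shift, decreasing in reference shift
    expect_true(pfafflFold(1.9, 2.1, 1.95, 1) > pfafflFold(1.9, 2.0, 1.95, 1))
    expect_true(pfafflFold(1.9, 2, 1.95, 1.1) < pfafflFold(1.9, 2, 1.95, 1))

    expect_error(pfafflFold(1.0, 1, 2, 1), "efficiency")
    expect_error(pfafflFold(2, 1, 2.3, 1), "efficiency")
})

test_that("reference combination is a geometric mean with its invariances", {
    expect_equal(combineReferences(c(4, 9)), 6)
    expect_equal(combineReferences(7.3), 7.3)
    expect_equal(combineReferences(c(2, 4, 8)), 4)

    set.seed(1)
    x <- runif(5, 0.1, 50)
    expect_equal(combineReferences(x), combineReferences(rev(x)))
    expect_equal(combineReferences(3 * x), 3 * combineReferences(x))

    expect_error(combineReferences(numeric()), "no reference")
    expect_error(combineReferences(c(2, 0)), "positive")
})

test_that("quantification recovers generating truths at zero cycle noise", {
    truths <- rbind("s1" = c(CCE1 = 32, CCE2 = 8, REF1 = 1, REF2 = 1),
                    "s2" = c(CCE1 = 2.5, CCE2 = 1, REF1 = 1, REF2 = 1))
    for (e in c(1.8, 2.0)) {
        eff <- setNames(rep(e, 4), colnames(truths))
        spec <- qpcrSimSpec(truths, references = c("REF1", "REF2"),
                            calibrators = "cal", efficiencies = eff,
                            sigmaCq = 0, replicates = 2L, seed = 11L)
        suppressMessages(
            q <- quantifyCnv(simulateQpcr(spec), eff, "cal",
                             c("CCE1", "CCE2"), c("REF1", "REF2")))
        for (s in rownames(truths)) for (g in c("CCE1", "CCE2"))
            expect_equal(q$fold[q$sample_id == s & q$gene_id == g],
                         unname(truths[s, g]), tolerance = 1e-12)
        # calibrator self-quantifies at fold 1
        expect_equal(q$fold[q$sample_id == "cal"], c(1, 1), tolerance = 1e-12)
    }
})

test_that("quantification reproduces the hand-built delta-delta-Cq example", {
    # target 5 cycles below calibrator, references equal to calibrator: 2^5
    m <- data.frame(
        sample_id = rep(c("cal", "s"), each = 3),
        gene_id = rep(c("T", "R1", "R2"), 2),
        replicate = 1L,
        cq = c(30, 28, 27, 25, 28, 27))
    suppressMessages(
        q <- quantifyCnv(m, NULL, "cal", "T", c("R1", "R2")))
    expect_equal(q$fold[q$sample_id == "s"], 32)
})

test_that("undetermined wells are handled per the assay semantics", {
    m <- data.frame(
        sample_id = c("cal", "cal", "s", "s", "x"),
        gene_id = c("T", "R1", "T", "R1", "T"),
        replicate = 1L,
        cq = c(30, 28, NA, 28, 25))
    # target undetermined in a non-calibrator sample: fold 0, flagged;
    # sample with no reference at all is skipped with a warning
    q <- NULL
    expect_warning(suppressMessages(
        q <- quantifyCnv(m, NULL, "cal", "T", "R1")), "x")
    srow <- q[q$sample_id == "s", ]
    expect_equal(srow$fold, 0)
    expect_equal(srow$flag, "no-target-amplification")
    expect_false("x" %in% q$sample_id)
})

test_that("replicates are averaged on the Cq scale before the fold", {
    m <- data.frame(
        sample_id = c("cal", "cal", "s", "s", "s", "s"),
        gene_id = c("T", "R1", "T", "T", "R1", "R1"),
        replicate = c(1L, 1L, 1L, 2L, 1L, 2L),
        cq = c(30, 28, 26, 24, 28, 28))
    suppressMessages(q <- quantifyCnv(m, NULL, "cal", "T", "R1"))
    # mean target Cq 25 -> dCq 5 -> 32 (not the mean of 2^4 and 2^6)
    expect_equal(q$fold[q$sample_id == "s"], 32)
    expect_equal(q$n_replicates[q$sample_id == "s"], 2L)
    expect_gt(q$cv[q$sample_id == "s"], 0)
})

test_that("duplex TaqMan wells quantify against FAM/HEX calibrator Cq", {
    expect_equal(duplexQuantify(25, 30, 2, 2, 30, 30)$fold, 32)
    expect_equal(duplexQuantify(30, 30, 2, 2, 30, 30)$fold, 1)
    expect_equal(duplexQuantify(27, 29, 1.95, 1.95, 30, 30)$fold,
                 3.8025, tolerance = 1e-10)
    noAmp <- duplexQuantify(NA, 29, 2, 2, 30, 30)
    expect_equal(noAmp$fold, 0)
    expect_equal(noAmp$flag, "no-target-amplification")
    expect_error(duplexQuantify(25, NA, 2, 2, 30, 30), "failed well")
})

test_that("Cq calling interpolates the first upward threshold crossing", {
    tr <- c(rep(0.01, 23), 0.6, 1.6, rep(2.5, 15))
    expect_equal(callCq(tr, threshold = 1.0), 24.4)
    expect_equal(callCq(tr, threshold = 1.0), oracleCq(tr, 1.0))

    # sigmoid against the scan oracle under the auto threshold
    cyc <- 1:40
    sig <- 3 / (1 + exp(-(cyc - 26) / 1.3)) + 0.005 * sin(cyc)
    auto <- mean(sig[3:15]) + 10 * sd(sig[3:15])
    expect_equal(callCq(sig), oracleCq(sig, auto), tolerance = 1e-9)

    expect_true(is.na(callCq(rep(0.01, 40))))
    expect_error(callCq(tr, threshold = 0), "threshold")
    expect_error(callCq(sig[1:30]), "40 cycles")
})
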