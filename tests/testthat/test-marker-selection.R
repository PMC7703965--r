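test_that("minor allele frequency counts alleles over called genotypes", {
    expect_equal(minorAlleleFreq(c(0L, 0L, 0L)), 0)        # monomorphic
    expect_equal(minorAlleleFreq(c(0L, 2L)), 0.5)          # balanced
    # hand count: hom X + two hets + one missing -> 2 Y of 6 alleles
    expect_equal(minorAlleleFreq(c(0L, 1L, 1L, NA)), 2 / 6)
    expect_error(minorAlleleFreq(c(NA_integer_, NA_integer_)), "undefined")

    gm <- makeGM(rbind(c(0L, 0L), c(0L, 2L)))
    expect_equal(unname(minorAlleleFreq(gm)), c(0, 0.5))
})

test_that("discriminated pairs require two called, different states", {
    expect_identical(nrow(discriminatedPairs(c(0L, 0L, 0L))), 0L)
    expect_equal(unname(discriminatedPairs(c(0L, 1L))), rbind(c(1L, 2L)))
    # a missing call never discriminates
    expect_equal(unname(discriminatedPairs(c(0L, NA, 2L))), rbind(c(1L, 3L)))
})

test_that("greedy selection seeds on MAF then maximizes pair gain", {
    # the only informative marker has the top MAF and resolves the pair
    gm <- makeGM(rbind(c(0L, 0L), c(0L, 1L)))
    sel <- greedySelect(gm)
    expect_identical(selectedMarkers(sel), "m02")
    expect_identical(nrow(residualPairs(sel)), 0L)
    expect_identical(selectionGains(sel), 1L)

    # clones cannot be split: the pair stays in the residual
    clones <- makeGM(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L)))
    sel2 <- greedySelect(clones)
    expect_identical(nrow(residualPairs(sel2)), 1L)
    expect_true(sel2@complete)

    expect_error(greedySelect(makeGM(matrix(0L, 1, 3))), "two samples")
})

test_that("greedy gains match a per-iteration brute-force recount", {
    set.seed(42)
    for (rep in 1:20) {
        gm <- randomInstance(sample(4:10, 1), sample(3:8, 1))
        cl <- genotypeCalls(gm)
        sel <- greedySelect(gm)
        expect_identical(selectionGains(sel),
                         oracleStepGains(cl, selectedMarkers(sel)))
        # residual pairs are exactly the pairs no marker splits
        resolvable <- oracleResolvablePairs(cl)
        ids <- sampleIds(gm)
        want <- setdiff(
            apply(t(utils::combn(ids, 2)), 1, paste, collapse = "|"),
            apply(matrix(ids[resolvable], ncol = 2), 1, paste,
                  collapse = "|"))
        got <- apply(residualPairs(sel), 1, paste, collapse = "|")
        expect_setequal(got, want)
        # monotone: every gain after the first is strictly positive
        if (length(selectionGains(sel)) > 1L)
            expect_true(all(selectionGains(sel)[-1L] > 0L))
    }
})

test_that("selection is deterministic for identical inputs", {
    set.seed(5)
    gm <- randomInstance(10, 8)
    s1 <- greedySelect(gm)
    s2 <- greedySelect(gm)
    expect_identical(selectedMarkers(s1), selectedMarkers(s2))
    expect_identical(selectionGains(s1), selectionGains(s2))
    expect_identical(residualPairs(s1), residualPairs(s2))
})

test_that("exhaustive search finds provably minimal panels", {
    # one marker alone splits every pair
    gm1 <- makeGM(rbind(c(0L, 0L), c(1L, 0L), c(2L, 0L)))
    bf1 <- bruteForceMinimumPanel(gm1)
    expect_identical(bf1$markers, "m01")

    # no single marker works, but markers 1+2 jointly split all 10 pairs
    gm2 <- makeGM(cbind(m1 = c(0L, 0L, 1L, 1L, 2L),
                        m2 = c(0L, 1L, 0L, 1L, 2L),
                        m3 = c(0L, 0L, 0L, 0L, 1L),
                        m4 = c(1L, 1L, 1L, 1L, 1L)))
    bf2 <- bruteForceMinimumPanel(gm2)
    expect_identical(bf2$size, 2L)
    expect_identical(bf2$markers, c("m1", "m2"))

    # identical samples: nothing resolves them
    gm3 <- makeGM(rbind(c(0L, 1L), c(0L, 1L)))
    bf3 <- bruteForceMinimumPanel(gm3)
    expect_identical(bf3$markers, character())
    expect_identical(nrow(bf3$unresolvablePairs), 1L)

    expect_error(bruteForceMinimumPanel(randomInstance(4, 30),
                                        maxSubsets = 10), "guard")
})

test_that("greedy panels are never smaller than the exhaustive minimum", {
    set.seed(12)
    for (rep in 1:10) {
        gm <- randomInstance(sample(4:8, 1), sample(3:6, 1),
                             missingProb = 0.05)
        sel <- greedySelect(gm)
        bf <- bruteForceMinimumPanel(gm)
        if (!is.null(bf$markers) && length(bf$markers))
            expect_gte(length(selectedMarkers(sel)), bf$size)
    }
})

test_that("ranking and augmentation cover missing chromosomes", {
    # samples constructed so m1 resolves everything; m2..m4 sit on chr2
    codes <- cbind(m1 = c(0L, 1L, 2L), m2 = c(0L, 0L, 1L),
                   m3 = c(0L, 1L, 1L), m4 = c(0L, 0L, 0L))
    gm <- makeGM(codes, chromosomes = c("chr1", "chr2", "chr2", "chr2"))
    sel <- greedySelect(gm)
    expect_identical(selectedMarkers(sel), "m1")
    ra <- rankAndAugment(gm, sel)
    # chr2 uncovered: the candidate with the higher differentiation
    # score is appended; with all pairs resolved scores tie at zero and
    # the higher-MAF candidate wins (m3: MAF 2/6 vs m2: 1/6 vs m4: 0)
    expect_identical(ra$augmented, c("m1", "m3"))
    expect_identical(length(ra$augmented), 2L)

    # all chromosomes already covered: selection unchanged
    gm2 <- makeGM(codes[, 1, drop = FALSE], chromosomes = "chr1")
    sel2 <- greedySelect(gm2)
    expect_identical(rankAndAugment(gm2, sel2)$augmented,
                     selectedMarkers(sel2))

    expect_error(rankAndAugment(makeGM(codes), sel), "chromosome")
})
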