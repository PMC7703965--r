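test_that("noise-free simulation observes the true genotypes exactly", {
    cfg <- simConfig(nFounders = 15, miscallRate = 0, missingRate = 0,
                     sportMutationRate = 0, seed = 2)
    sim <- simulateCollection(cfg)
    expect_identical(genotypeCalls(sim$observed),
                     genotypeCalls(sim$truth$trueGenotypes))
    expect_identical(nrow(sim$truth$injectedErrors), 0L)
    expect_identical(nrow(sim$truth$injectedMissing), 0L)
    # clones really are copies of their founder
    cm <- sim$truth$cloneMembership
    cl <- genotypeCalls(sim$observed)
    for (v in unique(cm)) {
        ids <- names(cm)[cm == v]
        if (length(ids) > 1L)
            expect_true(all(cl[, ids] == cl[, ids[1L]]))
    }
})

test_that("every observed-vs-true discrepancy is logged exactly once", {
    sim <- simulateCollection(simConfig(nFounders = 60,
                                        cloneGroupSizes = 2L,
                                        miscallRate = 0.01,
                                        missingRate = 0.02, seed = 13))
    obs <- genotypeCalls(sim$observed)
    tru <- genotypeCalls(sim$truth$trueGenotypes)
    errs <- sim$truth$injectedErrors
    miss <- sim$truth$injectedMissing
    # recount mismatches directly
    flips <- which(!is.na(obs) & !is.na(tru) & obs != tru, arr.ind = TRUE)
    expect_identical(nrow(flips), nrow(errs))
    expect_setequal(paste(colnames(obs)[flips[, 2]],
                          rownames(obs)[flips[, 1]]),
                    paste(errs$sample, errs$marker))
    gone <- which(is.na(obs) & !is.na(tru), arr.ind = TRUE)
    expect_identical(nrow(gone), nrow(miss))
    # no discrepancy appears in both logs
    expect_length(intersect(paste(errs$sample, errs$marker),
                            paste(miss$sample, miss$marker)), 0L)
})

test_that("simulation is reproducible from its seed", {
    cfg <- simConfig(nFounders = 25, miscallRate = 0.01,
                     missingRate = 0.03, mislabelRate = 0.1, seed = 7)
    a <- simulateCollection(cfg)
    b <- simulateCollection(cfg)
    expect_identical(genotypeCalls(a$observed), genotypeCalls(b$observed))
    expect_identical(a$truth$injectedErrors, b$truth$injectedErrors)
    expect_identical(a$truth$mislabeled, b$truth$mislabeled)
})

test_that("marker MAFs track the configured range", {
    sim <- simulateCollection(simConfig(nFounders = 400, nMarkers = 10,
                                        mafRange = c(0.5, 0.5),
                                        triploidFraction = 0,
                                        miscallRate = 0, missingRate = 0,
                                        sportMutationRate = 0,
                                        cloneGroupSizes = 1L, seed = 21))
    maf <- minorAlleleFreq(sim$observed)
    # folded binomial bound on 800 alleles per marker, family-wise over
    # the 10 markers (per-marker tail 1e-4)
    lo <- qbinom(1e-4, 800, 0.5) / 800
    expect_true(all(maf >= lo))
    expect_true(all(maf <= 0.5))
})

test_that("injected error counts follow the configured rates", {
    gm <- makeGM(matrix(0L, 100, 100))
    flipAll <- injectErrors(gm, miscallRate = 1, missingRate = 0, seed = 5)
    expect_true(all(genotypeCalls(flipAll$matrix) != 0L))
    expect_false(anyNA(genotypeCalls(flipAll$matrix)))

    ident <- injectErrors(gm, 0, 0, seed = 5)
    expect_identical(genotypeCalls(ident$matrix), genotypeCalls(gm))

    some <- injectErrors(gm, miscallRate = 0.05, missingRate = 0, seed = 11)
    n <- nrow(some$errors)
    # 99% binomial interval around 500 of 10,000
    expect_gte(n, qbinom(0.005, 1e4, 0.05))
    expect_lte(n, qbinom(0.995, 1e4, 0.05))
})

test_that("invalid configurations are rejected with the violations listed", {
    expect_error(simConfig(nFounders = 1), "nFounders")
    expect_error(simConfig(mafRange = c(0, 0.6)), "mafRange")
    expect_error(simConfig(miscallRate = 1.5), "miscallRate")
    err <- tryCatch(simConfig(nFounders = 1, missingRate = -1),
                    error = conditionMessage)
    expect_match(err, "nFounders")
    expect_match(err, "missingRate")
})

test_that("triploid-like samples show elevated heterozygosity downstream", {
    sim <- simulateCollection(simConfig(nFounders = 300,
                                        triploidFraction = 0.3,
                                        hetInflation = 0.32,
                                        miscallRate = 0, missingRate = 0,
                                        cloneGroupSizes = 1L, seed = 17))
    het <- sampleHeterozygosity(sim$observed)
    pl <- setNames(sampleInfo(sim$observed)$ploidy,
                   sampleIds(sim$observed))
    s <- as.data.frame(summarizeByPloidy(het, pl, tail = 50L)$byPloidy)
    expect_gt(s$mean_het[s$ploidy == "3"], s$mean_het[s$ploidy == "2"])
})

test_that("a generous simulated panel resolves every non-clone pair", {
    sim <- simulateCollection(simConfig(nFounders = 12, nMarkers = 40,
                                        mafRange = c(0.3, 0.5),
                                        cloneGroupSizes = c(1L, 2L),
                                        miscallRate = 0, missingRate = 0,
                                        sportMutationRate = 0, seed = 19))
    sel <- greedySelect(sim$observed)
    res <- residualPairs(sel)
    cm <- sim$truth$cloneMembership
    if (nrow(res))
        expect_true(all(cm[res[, 1]] == cm[res[, 2]]))
})
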