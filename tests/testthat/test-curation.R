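test_that("strict grouping partitions samples by exact profile", {
    codes <- rbind(a = c(0L, 1L, 2L), b = c(0L, 1L, 2L), c = c(0L, 1L, 0L))
    gps <- groupProfiles(makeGM(codes))
    expect_identical(vapply(gps, function(g) length(groupMembers(g)), 0L),
                     c(2L, 1L))
    expect_setequal(groupMembers(gps[[1]]), c("a", "b"))
    # a partition: every sample in exactly one group
    expect_setequal(unlist(lapply(gps, groupMembers)), rownames(codes))
})

test_that("missing is its own state strictly but matches anything compatibly", {
    codes <- rbind(a = c(0L, 1L, 2L), b = c(0L, NA, 2L))
    gm <- makeGM(codes)
    expect_length(groupProfiles(gm, "strict"), 2L)
    expect_warning(gps <- groupProfiles(gm, "compatible"), "over-merge")
    expect_length(gps, 1L)
    expect_setequal(groupMembers(gps[[1]]), c("a", "b"))
})

test_that("replicate-labelled groups merge only under the difference cap", {
    ref <- refProfile()
    codes <- rbind(bv1 = shiftAt(ref, 3), bv2 = ref, bv3 = ref,
                   far = shiftAt(ref, 1:12))
    gm <- makeGM(codes)
    gps <- groupProfiles(gm)

    # one of three same-label samples differs by a single call: merge
    lab <- c(bv1 = "BlackVallis", bv2 = "BlackVallis", bv3 = "BlackVallis")
    merged <- mergeReplicateGroups(gps, lab, maxDiff = 1L)
    sizes <- vapply(merged$groups, function(g) length(groupMembers(g)), 0L)
    expect_identical(max(sizes), 3L)
    expect_identical(nrow(merged$log), 1L)
    expect_identical(merged$log$differences, 1L)

    # same label but 12 differences: not replicate noise, no merge
    lab2 <- c(bv2 = "Pair", far = "Pair")
    m2 <- mergeReplicateGroups(gps, lab2, maxDiff = 2L)
    expect_identical(length(m2$groups), length(gps))

    # maxDiff = 0 merges only already-identical profiles
    m0 <- mergeReplicateGroups(gps, lab, maxDiff = 0L)
    expect_identical(length(m0$groups), length(gps))

    expect_warning(mergeReplicateGroups(gps, c(ghost = "X", bv1 = "X")),
                   "unknown")
})

test_that("systematic nulls are markers missing in every group member", {
    codes <- rbind(j1 = c(NA, 0L, 1L), j2 = c(NA, 0L, NA),
                   j3 = c(NA, 0L, 1L))
    gm <- makeGM(codes)
    grp <- groupProfiles(gm, "compatible") |> suppressWarnings()
    expect_identical(findSystematicNulls(grp[[1]], gm), "m01")

    solo <- new("ProfileGroup", members = "j1",
                representative = genotypeCalls(gm)[, "j1"],
                systematicNulls = character())
    expect_message(out <- findSystematicNulls(solo, gm), "singleton")
    expect_identical(out, character())

    full <- makeGM(rbind(x = c(0L, 1L), y = c(0L, 1L)))
    g2 <- groupProfiles(full)[[1]]
    expect_identical(findSystematicNulls(g2, full), character())
})

test_that("strand harmonization complements calls and refuses palindromes", {
    # A/G assay read on the other strand is C/T: hom A -> hom T,
    # hom G -> hom C, het stays het, missing stays missing
    calls <- c(0L, 1L, 2L, NA)
    out <- harmonizeStrand(calls, c("A", "G"), c("C", "T"))
    expect_identical(out, c(2L, 1L, 0L, NA))   # A:A->T:T, G:G->C:C, A:G->C:T
    expect_true(is.na(out[4]))

    # involution: mapping back restores the original exactly
    back <- harmonizeStrand(out, c("C", "T"), c("A", "G"))
    expect_identical(back, calls)

    expect_error(harmonizeStrand(calls, c("A", "T"), c("A", "T")),
                 "palindromic")
    ok <- harmonizeStrand(calls, c("A", "T"), c("A", "T"),
                          mapping = c(A = "T", T = "A"))
    expect_identical(ok, c(2L, 1L, 0L, NA))
    expect_error(harmonizeStrand(calls, c("A", "G"), c("A", "G")),
                 "do not map")
})

test_that("concordance counts agreements and categorized disagreements", {
    a <- makeGM(rbind(s1 = c(0L, 1L), s2 = c(2L, 1L)))
    expect_equal(concordanceStats(a, a)@overallPercent, 100)
    expect_true(all(concordanceStats(a, a)@perMarker$het_to_hom == 0))

    # hand count: one disagreement among four compared cells -> 75%
    b <- makeGM(rbind(s1 = c(0L, 1L), s2 = c(2L, 0L)))
    rep_ <- concordanceStats(a, b)
    expect_equal(rep_@overallPercent, 75)
    expect_identical(sum(rep_@perMarker$het_to_hom), 1L)

    # missing on either side drops the cell from the comparison
    c_ <- makeGM(rbind(s1 = c(NA, 1L), s2 = c(2L, 1L)))
    expect_identical(sum(concordanceStats(a, c_)@perMarker$compared), 3L)

    # disagreement totals are symmetric with categories swapped
    expect_identical(sum(rep_@perMarker$het_to_hom),
                     sum(concordanceStats(b, a)@perMarker$hom_to_het))

    expect_error(concordanceStats(a, makeGM(matrix(0L, 2, 3))), "mismatch")
})

test_that("heterozygosity is the het fraction of called loci", {
    expect_equal(sampleHeterozygosity(rep(1L, 5)), 1)
    expect_equal(sampleHeterozygosity(c(0L, 2L, 0L)), 0)
    # 21 calls, 1 missing, 10 het of the 20 called
    p <- c(rep(1L, 10), rep(0L, 10), NA)
    expect_equal(sampleHeterozygosity(p), 0.5)
    expect_error(sampleHeterozygosity(c(NA_integer_, NA_integer_)),
                 "undefined")
    # invariant under strand harmonization
    q <- c(0L, 1L, 2L, 1L, NA)
    expect_equal(sampleHeterozygosity(
        harmonizeStrand(q, c("A", "G"), c("C", "T"))),
        sampleHeterozygosity(q))
})

test_that("ploidy summaries expose the triploid heterozygosity excess", {
    het <- c(a = 0.2, b = 0.3, c = 0.8, d = 0.7, e = 0.4)
    pl <- c(a = 2, b = 2, c = 3, d = 3, e = NA)
    s <- summarizeByPloidy(het, pl, tail = 2L)
    by <- as.data.frame(s$byPloidy)
    expect_equal(by$mean_het[by$ploidy == "2"], 0.25)
    expect_equal(by$mean_het[by$ploidy == "3"], 0.75)
    tails <- as.data.frame(s$tails)
    expect_identical(tails$n_top[tails$ploidy == "3"], 2L)
    expect_identical(tails$n_bottom[tails$ploidy == "2"], 2L)

    one <- summarizeByPloidy(het, c(a = 2, b = 2, c = 2, d = 2, e = 2))
    expect_equal(as.data.frame(one$byPloidy)$mean_het, mean(het))

    empty <- summarizeByPloidy(setNames(numeric(), character()), pl)
    expect_identical(nrow(empty$byPloidy), 0L)
})
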