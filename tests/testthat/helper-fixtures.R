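# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately naive (nested loops, full re-enumeration) so
# they share no code path with the implementation they check.

# GenotypeMatrix from a samples-in-rows integer code matrix
# (0 = hom X, 1 = het, 2 = hom Y, NA = missing).
makeGM <- function(codes, chromosomes = NULL) {
    codes <- as.matrix(codes)
    if (is.null(rownames(codes)))
        rownames(codes) <- sprintf("s%02d", seq_len(nrow(codes)))
    if (is.null(colnames(codes)))
        colnames(codes) <- sprintf("m%02d", seq_len(ncol(codes)))
    mi <- S4Vectors::DataFrame(marker_id = colnames(codes),
                               allele_x = "A", allele_y = "G")
    if (!is.null(chromosomes))
        mi$chromosome <- chromosomes
    GenotypeMatrix(t(codes), markerInfo = mi)
}

# a complete 21-marker reference profile and a state-shift helper
refProfile <- function() rep(0:2, 7)
shiftAt <- function(p, at) { p[at] <- (p[at] + 1L) %% 3L; p }

# replicate group in the list layout of replicateGroups()
makeGroup <- function(label, ...) {
    prof <- rbind(...)
    rownames(prof) <- paste0(label, "_", seq_len(nrow(prof)))
    colnames(prof) <- sprintf("m%02d", seq_len(ncol(prof)))
    list(label = label, sample_ids = rownames(prof), profiles = prof)
}

# The four worked replicate groups: an identical pair, a pair differing
# at 12 calls, a trio with one deviant call and one missing call, and a
# trio with one member 9 calls from the consensus.
workedReplicateGroups <- function() {
    ref <- refProfile()
    kimDev <- shiftAt(ref, 1:12)
    abMiss <- ref; abMiss[5] <- NA
    abDev <- shiftAt(ref, 10)
    gavDev <- shiftAt(ref, 1:9)
    list(pair_identical = makeGroup("pair_identical", ref, ref),
         pair_divergent = makeGroup("pair_divergent", ref, kimDev),
         trio_one_miss = makeGroup("trio_one_miss", ref, abMiss, abDev),
         trio_deviant = makeGroup("trio_deviant", ref, ref, gavDev))
}

# ORACLE: all sample pairs split by at least one marker, by direct scan.
oracleResolvablePairs <- function(cl) {
    n <- ncol(cl)
    out <- NULL
    if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        hit <- FALSE
        for (k in seq_len(nrow(cl))) {
            a <- cl[k, i]; b <- cl[k, j]
            if (!is.na(a) && !is.na(b) && a != b) { hit <- TRUE; break }
        }
        if (hit) out <- rbind(out, c(i, j))
    }
    if (is.null(out)) matrix(integer(), 0L, 2L) else out
}

# ORACLE: given the selected marker sequence, rebuild the pairwise
# discrimination state from scratch at every iteration and recount the
# newly resolved pairs per step.
oracleStepGains <- function(cl, selected) {
    n <- ncol(cl)
    resolved <- matrix(FALSE, n, n)
    gains <- integer()
    for (mk in selected) {
        gain <- 0L
        if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
            if (resolved[i, j]) next
            a <- cl[mk, i]; b <- cl[mk, j]
            if (!is.na(a) && !is.na(b) && a != b) {
                resolved[i, j] <- TRUE
                gain <- gain + 1L
            }
        }
        gains <- c(gains, gain)
    }
    gains
}

# random small instance for property tests
randomInstance <- function(nSamples, nMarkers, missingProb = 0.1) {
    codes <- matrix(sample(c(0:2, NA), nSamples * nMarkers, replace = TRUE,
                           prob = c((1 - missingProb) / 3,
                                    (1 - missingProb) / 3,
                                    (1 - missingProb) / 3, missingProb)),
                    nSamples, nMarkers)
    makeGM(codes)
}
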