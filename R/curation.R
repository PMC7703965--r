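# Union-find over 1..n, used for compatibility grouping and replicate
# merging.
.ufNew <- function(n) seq_len(n)
.ufFind <- function(parent, i) {
    while (parent[i] != i) i <- parent[i]
    i
}
.ufUnion <- function(parent, i, j) {
    ri <- .ufFind(parent, i)
    rj <- .ufFind(parent, j)
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    parent
}
.ufComponents <- function(parent) {
    roots <- vapply(seq_along(parent), function(i) .ufFind(parent, i), 0L)
    split(seq_along(parent), roots)
}

#' Group samples with identical SNP profiles
#'
#' In \code{strict} mode two samples share a profile iff every marker
#' state matches, missing being its own state: this is the
#' distinct-profile count a curator reports.  In \code{compatible} mode
#' a missing call matches anything and groups are formed by transitive
#' compatibility; this can over-merge (a warning is issued), because two
#' samples that are both compatible with a third need not be compatible
#' with each other, and is offered only for exploratory screening.
#'
#' @param x a non-empty \linkS4class{GenotypeMatrix}.
#' @param missingMode \code{"strict"} (default) or \code{"compatible"}.
#' @return list of \linkS4class{ProfileGroup}; the groups partition the
#'   samples.  Groups are ordered by decreasing size, then first member.
#' @export
groupProfiles <- function(x, missingMode = c("strict", "compatible")) {
    missingMode <- match.arg(missingMode)
    cl <- genotypeCalls(x)
    if (ncol(cl) == 0L)
        stop("empty genotype matrix")
    ids <- sampleIds(x)
    if (missingMode == "strict") {
        key <- apply(cl, 2L, function(g)
            paste(ifelse(is.na(g), ".", g), collapse = ""))
        comp <- split(seq_along(ids), key)
    } else {
        warning("compatible matching can over-merge profiles across missing calls")
        n <- ncol(cl)
        parent <- .ufNew(n)
        for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
            d <- cl[, i] != cl[, j]
            if (!any(d, na.rm = TRUE))
                parent <- .ufUnion(parent, i, j)
        }
        comp <- .ufComponents(parent)
    }
    groups <- lapply(unname(comp), function(members) {
        prof <- if (length(members) == 1L) cl[, members]
        else apply(cl[, members, drop = FALSE], 1L, .majorityState)
        new("ProfileGroup",
            members = ids[members],
            representative = setNames(as.integer(prof), rownames(cl)),
            systematicNulls = character())
    })
    first <- vapply(groups, function(g) g@members[1L], "")
    sizes <- vapply(groups, function(g) length(g@members), 0L)
    groups[order(-sizes, match(first, ids))]
}

# Strict-majority non-missing state; NA when no state has > half of the
# non-missing calls.
.majorityState <- function(states) {
    states <- states[!is.na(states)]
    if (!length(states))
        return(NA_integer_)
    tab <- tabulate(states + 1L, 3L)
    if (max(tab) * 2L > length(states))
        which.max(tab) - 1L
    else NA_integer_
}

# Differences between two profiles ignoring positions where either is
# missing.
.calledDiff <- function(a, b) sum(a != b, na.rm = TRUE)

#' Merge profile groups that are declared replicates
#'
#' Adjusts a strict profile grouping for genotyping errors using
#' declared replicate structure: two groups are merged iff they share a
#' replicate label and their representative profiles differ at no more
#' than \code{maxDiff} markers (missing-vs-called positions are not
#' counted as differences).  Merging is never attempted across samples
#' without a shared label — unlabelled near-identical profiles are left
#' apart, since a miscall cannot be told from a genuine 1-SNP sport
#' without replicate evidence.
#'
#' @param groups list of \linkS4class{ProfileGroup} (from
#'   \code{\link{groupProfiles}}).
#' @param replicateLabels named character vector, sample id to label
#'   (e.g. a variety name or registry code); samples absent from it are
#'   unlabelled.  Names not present in any group produce a warning only.
#' @param maxDiff maximum representative-profile differences allowed for
#'   a merge (default 1, the single-miscall case).
#' @return list with \code{groups} (merged \linkS4class{ProfileGroup}
#'   list) and \code{log} (DataFrame of performed merges with their
#'   difference counts).
#' @export
mergeReplicateGroups <- function(groups, replicateLabels, maxDiff = 1L) {
    if (maxDiff < 0L)
        stop("maxDiff must be >= 0")
    allMembers <- unlist(lapply(groups, groupMembers))
    unknown <- setdiff(names(replicateLabels), allMembers)
    if (length(unknown))
        warning("replicate labels for unknown samples ignored: ",
                paste(utils::head(unknown, 5L), collapse = ", "))
    ng <- length(groups)
    labelsOf <- lapply(groups, function(g)
        unique(stats::na.omit(unname(replicateLabels[g@members]))))
    parent <- .ufNew(ng)
    logs <- list()
    if (ng > 1L) for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) {
        shared <- intersect(labelsOf[[i]], labelsOf[[j]])
        if (!length(shared))
            next
        d <- .calledDiff(groups[[i]]@representative,
                         groups[[j]]@representative)
        if (d <= maxDiff) {
            parent <- .ufUnion(parent, i, j)
            logs[[length(logs) + 1L]] <-
                data.frame(label = shared[1L],
                           group_1 = groups[[i]]@members[1L],
                           group_2 = groups[[j]]@members[1L],
                           differences = d)
        }
    }
    comp <- .ufComponents(parent)
    merged <- lapply(unname(comp), function(idx) {
        mem <- unlist(lapply(groups[idx], groupMembers))
        reps <- do.call(cbind, lapply(groups[idx], representativeProfile))
        new("ProfileGroup",
            members = mem,
            representative = setNames(
                as.integer(apply(reps, 1L, .majorityState)),
                names(groups[[idx[1L]]]@representative)),
            systematicNulls = character())
    })
    sizes <- vapply(merged, function(g) length(g@members), 0L)
    log <- if (length(logs)) do.call(rbind, logs)
        else data.frame(label = character(), group_1 = character(),
                        group_2 = character(), differences = integer())
    list(groups = merged[order(-sizes)], log = DataFrame(log))
}

#' Markers systematically missing within a clonal group
#'
#' A marker that fails in every member of a clonal group is unlikely to
#' fail at random; such reproducible no-calls behave as null alleles
#' (primer-site variation) and are a genuine part of the group's SNP
#' profile.
#'
#' @param group a \linkS4class{ProfileGroup} with at least two members.
#' @param x the \linkS4class{GenotypeMatrix} the group came from.
#' @return character vector of marker ids missing in every member.  A
#'   singleton group returns an empty vector with a message, since a
#'   single failure carries no evidence of reproducibility.
#' @export
findSystematicNulls <- function(group, x) {
    cl <- genotypeCalls(x)[, groupMembers(group), drop = FALSE]
    if (ncol(cl) < 2L) {
        message("singleton group: systematic nulls need >= 2 members")
        return(character())
    }
    rownames(cl)[rowSums(!is.na(cl)) == 0L]
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Harmonize calls across assay strands
#'
#' Maps calls reported on one DNA strand onto the allele pair of the
#' other: homozygotes map to complement homozygotes, heterozygotes stay
#' heterozygous, missing stays missing (e.g. an A/G assay read as C/T:
#' A:A becomes T:T, G:G becomes C:C, A:G becomes C:T).  For palindromic
#' SNPs (A/T, C/G) the strand cannot be inferred from the alleles, so an
#' explicit allele mapping is required.
#'
#' @param calls integer code vector/matrix relative to
#'   \code{sourceAlleles}.
#' @param sourceAlleles length-2 character, alphabetical (X, Y) of the
#'   source assay.
#' @param targetAlleles length-2 character, alphabetical (X, Y) of the
#'   target assay; must be the base complements of the source pair
#'   unless \code{mapping} is given.
#' @param mapping optional named character vector mapping each source
#'   allele to a target allele (e.g. \code{c(A = "T", T = "A")}),
#'   required for palindromic pairs.
#' @return calls re-coded relative to \code{targetAlleles}; applying the
#'   inverse mapping restores the input exactly.
#' @export
harmonizeStrand <- function(calls, sourceAlleles, targetAlleles,
                            mapping = NULL) {
    sourceAlleles <- sort(toupper(sourceAlleles))
    targetAlleles <- sort(toupper(targetAlleles))
    stopifnot(length(sourceAlleles) == 2L, length(targetAlleles) == 2L)
    if (is.null(mapping)) {
        if (sourceAlleles[1L] == .COMPLEMENT[sourceAlleles[2L]])
            stop(sprintf(
                "palindromic SNP %s/%s: strand orientation is ambiguous; supply an explicit allele mapping",
                sourceAlleles[1L], sourceAlleles[2L]))
        mapping <- setNames(unname(.COMPLEMENT[sourceAlleles]),
                            sourceAlleles)
    } else {
        mapping <- setNames(toupper(mapping), toupper(names(mapping)))
        if (!setequal(names(mapping), sourceAlleles))
            stop("mapping must be named by the two source alleles")
    }
    if (!setequal(unname(mapping), targetAlleles))
        stop(sprintf("source alleles %s/%s do not map onto target pair %s/%s",
                     sourceAlleles[1L], sourceAlleles[2L],
                     targetAlleles[1L], targetAlleles[2L]))
    # X maps to the target's Y iff the order reverses; then hom codes swap
    flip <- mapping[sourceAlleles[1L]] == targetAlleles[2L]
    if (flip) {
        out <- calls
        out[calls == 0L] <- 2L
        out[calls == 2L] <- 0L
        out
    } else calls
}

#' Concordance between two call sets
#'
#' Compares genotype calls for the same samples and markers from two
#' platforms (after any strand harmonization).  Cells where either side
#' is missing are excluded from the comparison.  Disagreements are
#' split into heterozygote-called-homozygote (het on the first platform,
#' hom on the second), the converse, and opposite homozygotes.
#'
#' @param a,b \linkS4class{GenotypeMatrix} objects or integer code
#'   matrices (markers x samples) with identical marker and sample sets.
#' @return a \linkS4class{ConcordanceReport}.
#' @export
concordanceStats <- function(a, b) {
    ca <- if (is(a, "GenotypeMatrix")) genotypeCalls(a) else a
    cb <- if (is(b, "GenotypeMatrix")) genotypeCalls(b) else b
    if (!identical(dim(ca), dim(cb)))
        stop(sprintf("shape mismatch: %dx%d vs %dx%d",
                     nrow(ca), ncol(ca), nrow(cb), ncol(cb)))
    if (!is.null(rownames(ca)) && !is.null(rownames(cb))) {
        um <- c(setdiff(rownames(ca), rownames(cb)),
                setdiff(colnames(ca), colnames(cb)))
        if (length(um))
            stop("unmatched ids between the two call sets: ",
                 paste(utils::head(um, 5L), collapse = ", "))
        cb <- cb[rownames(ca), colnames(ca), drop = FALSE]
    }
    both <- !is.na(ca) & !is.na(cb)
    agree <- both & ca == cb
    hetHom <- both & ca == 1L & cb != 1L
    homHet <- both & ca != 1L & cb == 1L
    other <- both & !agree & !hetHom & !homHet
    per <- DataFrame(
        marker_id = if (is.null(rownames(ca)))
            sprintf("M%02d", seq_len(nrow(ca))) else rownames(ca),
        compared = as.integer(rowSums(both)),
        agree = as.integer(rowSums(agree)),
        het_to_hom = as.integer(rowSums(hetHom)),
        hom_to_het = as.integer(rowSums(homHet)),
        other_disagree = as.integer(rowSums(other)))
    total <- sum(per$compared)
    new("ConcordanceReport",
        perMarker = per,
        overallPercent = if (total) 100 * sum(per$agree) / total else
            NA_real_)
}

#' Per-sample heterozygosity
#'
#' Number of heterozygous calls divided by the number of non-missing
#' calls for the sample.
#'
#' @param x a \linkS4class{GenotypeMatrix} (returns a named vector) or a
#'   single integer profile.
#' @return fraction(s) in [0, 1]; a sample with no calls at all is an
#'   error (single profile) or \code{NA} with a warning (matrix).
#' @export
sampleHeterozygosity <- function(x) {
    if (is(x, "GenotypeMatrix")) {
        cl <- genotypeCalls(x)
        called <- colSums(!is.na(cl))
        het <- colSums(cl == 1L, na.rm = TRUE)
        out <- het / called
        if (anyNA(out))
            warning("samples with no calls have undefined heterozygosity")
        return(out)
    }
    g <- x[!is.na(x)]
    if (!length(g))
        stop("heterozygosity is undefined when every call is missing")
    sum(g == 1L) / length(g)
}

#' Heterozygosity summarized by reported ploidy
#'
#' Group means of per-sample heterozygosity by ploidy, plus the ploidy
#' composition of the extreme tails: among the \code{tail} samples with
#' the highest (and lowest) heterozygosity, how many belong to each
#' ploidy class.  Elevated heterozygosity flags candidate triploids for
#' cytological confirmation.
#'
#' @param het named numeric vector of heterozygosity fractions (e.g.
#'   from \code{\link{sampleHeterozygosity}}).
#' @param ploidy named vector of reported ploidy (NA = unknown).
#' @param tail size of each extreme tail (default 200; truncated to the
#'   sample count).
#' @return list with \code{byPloidy} (DataFrame: ploidy, n, mean_het)
#'   and \code{tails} (DataFrame: ploidy, n_top, n_bottom).  Empty input
#'   gives empty tables.
#' @export
summarizeByPloidy <- function(het, ploidy, tail = 200L) {
    ids <- names(het)
    pl <- ploidy[ids]
    if (!length(het))
        return(list(byPloidy = DataFrame(ploidy = character(), n = integer(),
                                         mean_het = numeric()),
                    tails = DataFrame(ploidy = character(), n_top = integer(),
                                      n_bottom = integer())))
    plc <- ifelse(is.na(pl), "unknown", as.character(pl))
    agg <- aggregate(list(mean_het = het), list(ploidy = plc), mean)
    cnt <- table(plc)
    byPloidy <- DataFrame(ploidy = agg$ploidy,
                          n = as.integer(cnt[agg$ploidy]),
                          mean_het = agg$mean_het)
    k <- min(as.integer(tail), length(het))
    ord <- order(het, decreasing = TRUE)
    lev <- sort(unique(plc))
    top <- table(factor(plc[ord[seq_len(k)]], levels = lev))
    bot <- table(factor(plc[rev(ord)[seq_len(k)]], levels = lev))
    list(byPloidy = byPloidy,
         tails = DataFrame(ploidy = lev,
                           n_top = as.integer(top),
                           n_bottom = as.integer(bot)))
}
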