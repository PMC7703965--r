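#' Build replicate groups from labels
#'
#' Collects the samples sharing each replicate label (variety name or
#' registry code) into groups for error estimation.  Samples without a
#' label, and labels with a single sample, are dropped: error estimation
#' needs at least two nominal replicates.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param labels named character vector (sample id to label); defaults
#'   to the \code{replicate_label} column of the sample metadata.
#' @return named list of groups; each group is a list with \code{label},
#'   \code{sample_ids} and \code{profiles} (integer matrix, members in
#'   rows, markers in columns).
#' @export
replicateGroups <- function(x, labels = NULL) {
    if (is.null(labels)) {
        lab <- sampleInfo(x)$replicate_label
        if (is.null(lab))
            stop("no replicate labels: supply 'labels' or a replicate_label sample-metadata column")
        labels <- setNames(as.character(lab), sampleIds(x))
    }
    labels <- labels[!is.na(labels) & labels != ""]
    labels <- labels[names(labels) %in% sampleIds(x)]
    cl <- genotypeCalls(x)
    byLab <- split(names(labels), unname(labels))
    byLab <- byLab[vapply(byLab, length, 0L) >= 2L]
    lapply(byLab, function(ids)
        list(label = unname(labels[ids[1L]]),
             sample_ids = ids,
             profiles = t(cl[, ids, drop = FALSE])))
}

#' Differences between two SNP profiles
#'
#' @param a,b integer code vectors of equal length.
#' @return named integer vector: \code{differences} (positions where
#'   both calls are present and the states differ) and \code{comparable}
#'   (positions where both are present).
#' @export
pairwiseDifferences <- function(a, b) {
    if (length(a) != length(b))
        stop("profiles differ in length")
    both <- !is.na(a) & !is.na(b)
    c(differences = sum(a[both] != b[both]),
      comparable = sum(both))
}

#' Consensus profile of a replicate group
#'
#' Per marker, the strict-majority non-missing state across members;
#' markers with no strict majority (including exact ties) get a missing
#' consensus and are excluded from downstream error counting.
#'
#' @param profiles integer matrix, members in rows, markers in columns;
#'   at least 3 members (for pairs, use \code{\link{pairwiseDifferences}}
#'   — with two members a disagreement has no majority to arbitrate).
#' @return named integer vector of consensus codes.
#' @export
consensusProfile <- function(profiles) {
    if (nrow(profiles) < 3L)
        stop("consensus needs >= 3 members; compare pairs with pairwiseDifferences()")
    setNames(as.integer(apply(profiles, 2L, .majorityState)),
             colnames(profiles))
}

#' Error arithmetic for one replicate group
#'
#' For two members, the errors are their pairwise call differences and
#' the denominator is the number of non-missing calls summed over both
#' profiles (42 for two complete 21-marker profiles).  For three or more
#' members, each member is compared with the strict-majority consensus;
#' the errors are the mismatches at markers where both the member and
#' the consensus are called, and the denominator is the non-missing
#' calls summed over all members (63 for three complete profiles, 62
#' when one call is missing).
#'
#' @param profiles integer matrix, members in rows, markers in columns
#'   (>= 2 rows).
#' @return named numeric vector: \code{errors}, \code{total_calls},
#'   \code{rate}.
#' @export
groupError <- function(profiles) {
    k <- nrow(profiles)
    if (k < 2L)
        stop("error estimation needs >= 2 members")
    totalCalls <- sum(!is.na(profiles))
    if (k == 2L) {
        errors <- unname(pairwiseDifferences(profiles[1L, ],
                                             profiles[2L, ])["differences"])
    } else {
        cons <- consensusProfile(profiles)
        errors <- sum(vapply(seq_len(k), function(i) {
            p <- profiles[i, ]
            both <- !is.na(p) & !is.na(cons)
            sum(p[both] != cons[both])
        }, 0L))
    }
    c(errors = as.numeric(errors), total_calls = totalCalls,
      rate = if (totalCalls) errors / totalCalls else NA_real_)
}

#' Overall error rate across replicate groups
#'
#' Aggregates \code{\link{groupError}} over replicate groups under one
#' of two assumptions about label fidelity.  Under \code{all_genuine}
#' every nominal replicate is taken to be a true biological replicate,
#' so every call difference is counted as a genotyping error — an upper
#' bound that is inflated by mislabelled samples.  Under
#' \code{diff_threshold} a member whose profile differs from its group
#' consensus (or, for pairs, from its partner) at more than
#' \code{threshold} markers is presumed not to be a true replicate and
#' is excluded; both members of a discordant pair are excluded, since
#' neither can be presumed correct.  Groups reduced below two members
#' drop out.  Surviving groups are re-evaluated after exclusion.
#'
#' @param groups list of replicate groups (see
#'   \code{\link{replicateGroups}}).
#' @param assumption \code{"all_genuine"} or \code{"diff_threshold"}.
#' @param threshold maximum SNP differences still treated as replicate
#'   noise (default 2, i.e. fewer than 3 differences).
#' @return an \linkS4class{ErrorEstimate}.
#' @export
overallErrorRate <- function(groups,
                             assumption = c("all_genuine", "diff_threshold"),
                             threshold = 2L) {
    assumption <- match.arg(assumption)
    if (!length(groups))
        stop("no replicate groups supplied")
    excluded <- list()
    perGroup <- list()
    errors <- 0L
    totalCalls <- 0L
    for (g in groups) {
        prof <- g$profiles
        if (nrow(prof) < 2L)
            next
        if (assumption == "diff_threshold") {
            if (nrow(prof) == 2L) {
                d <- pairwiseDifferences(prof[1L, ], prof[2L, ])["differences"]
                if (d > threshold) {
                    for (sid in g$sample_ids)
                        excluded[[length(excluded) + 1L]] <- data.frame(
                            sample_id = sid, label = g$label,
                            differences = as.integer(d),
                            reason = "discordant pair; neither member can be presumed correct")
                    next
                }
            } else {
                cons <- consensusProfile(prof)
                dv <- apply(prof, 1L, function(p) {
                    both <- !is.na(p) & !is.na(cons)
                    sum(p[both] != cons[both])
                })
                drop <- dv > threshold
                if (any(drop)) {
                    for (i in which(drop))
                        excluded[[length(excluded) + 1L]] <- data.frame(
                            sample_id = g$sample_ids[i], label = g$label,
                            differences = as.integer(dv[i]),
                            reason = sprintf("differs from consensus at %d markers (> %d)",
                                             dv[i], threshold))
                    prof <- prof[!drop, , drop = FALSE]
                    if (nrow(prof) < 2L) {
                        for (i in seq_len(nrow(prof)))
                            excluded[[length(excluded) + 1L]] <- data.frame(
                                sample_id = rownames(prof)[i], label = g$label,
                                differences = NA_integer_,
                                reason = "group reduced below two members")
                        next
                    }
                }
            }
        }
        ge <- groupError(prof)
        errors <- errors + as.integer(ge["errors"])
        totalCalls <- totalCalls + as.integer(ge["total_calls"])
        perGroup[[length(perGroup) + 1L]] <- data.frame(
            label = g$label, n_members = nrow(prof),
            errors = as.integer(ge["errors"]),
            total_calls = as.integer(ge["total_calls"]),
            rate = unname(ge["rate"]))
    }
    if (!length(perGroup))
        stop("no replicate group of two or more members survives; error rate is undefined")
    excl <- if (length(excluded)) do.call(rbind, excluded)
        else data.frame(sample_id = character(), label = character(),
                        differences = integer(), reason = character())
    new("ErrorEstimate",
        errors = errors,
        totalCalls = totalCalls,
        rate = errors / totalCalls,
        assumption = assumption,
        threshold = as.integer(threshold),
        excluded = DataFrame(excl),
        perGroup = DataFrame(do.call(rbind, perGroup)))
}
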