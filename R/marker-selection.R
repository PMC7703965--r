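# All C(n,2) unordered sample index pairs, i < j, in lexicographic order.
.pairIndices <- function(n) {
    if (n < 2L)
        return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("i", "j"))))
    i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
    j <- sequence((n - 1L):1L) + i
    cbind(i = i, j = j)
}

# Logical vector over the given pairs: does this marker column split them?
# A pair is split iff both calls are present and the genotype states
# differ (het vs either homozygote counts as different); a missing call
# never discriminates.
.splitsPair <- function(column, pairs) {
    d <- column[pairs[, 1L]] != column[pairs[, 2L]]
    d & !is.na(d)
}

#' Minor allele frequency per marker
#'
#' Allele counting over non-missing calls: a homozygote contributes two
#' copies of one allele, a heterozygote one of each.  The MAF is the
#' frequency of the rarer allele, in [0, 0.5]; markers with no calls at
#' all get \code{NA} with a warning.
#'
#' @param x a \linkS4class{GenotypeMatrix}, or an integer code vector
#'   for a single marker.
#' @return named numeric vector of MAFs (or a single value).
#' @export
minorAlleleFreq <- function(x) {
    if (is(x, "GenotypeMatrix")) {
        cl <- genotypeCalls(x)
        maf <- apply(cl, 1L, .mafColumn)
        if (anyNA(maf))
            warning("markers with no non-missing calls have undefined MAF: ",
                    paste(rownames(cl)[is.na(maf)], collapse = ", "))
        return(maf)
    }
    v <- .mafColumn(as.integer(x))
    if (is.na(v))
        stop("minor allele frequency is undefined when every call is missing")
    v
}

.mafColumn <- function(g) {
    g <- g[!is.na(g)]
    if (!length(g))
        return(NA_real_)
    y <- sum(g)                       # copies of allele Y
    total <- 2L * length(g)
    min(y, total - y) / total
}

#' Sample pairs discriminated by one marker
#'
#' @param x a \linkS4class{GenotypeMatrix} or an integer code vector.
#' @param marker marker id (when \code{x} is a matrix).
#' @return two-column integer matrix of sample index pairs (i < j) whose
#'   states at the marker are both called and different.
#' @export
discriminatedPairs <- function(x, marker = NULL) {
    g <- if (is(x, "GenotypeMatrix")) {
        stopifnot(!is.null(marker))
        genotypeCalls(x)[marker, ]
    } else as.integer(x)
    p <- .pairIndices(length(g))
    p[.splitsPair(g, p), , drop = FALSE]
}

#' Greedy minimal-panel selection
#'
#' Iterative pairwise-discrimination panel construction: the first
#' marker selected is the one with the highest minor allele frequency;
#' each subsequent step selects the marker that discriminates the most
#' still-unresolved sample pairs.  Selection stops when every pair is
#' resolved, when no remaining marker adds a split, or when
#' \code{maxPanel} markers have been chosen.  Ties are broken towards
#' higher MAF, then towards the lexicographically smaller marker id, so
#' results are deterministic.
#'
#' @param x a \linkS4class{GenotypeMatrix} with at least two samples.
#' @param maxPanel optional cap on panel size.
#' @return a \linkS4class{SelectionResult}.  When selection ran to
#'   completion, the residual pairs are exactly the pairs (clones, or
#'   samples masked by missing data) that no marker in the matrix can
#'   split.
#' @export
greedySelect <- function(x, maxPanel = NULL) {
    cl <- genotypeCalls(x)
    n <- ncol(cl)
    if (n < 2L)
        stop("need at least two samples to discriminate")
    if (nrow(cl) < 1L)
        stop("need at least one marker")
    if (is.null(maxPanel))
        maxPanel <- nrow(cl)
    pairs <- .pairIndices(n)
    unresolved <- rep(TRUE, nrow(pairs))
    maf <- apply(cl, 1L, .mafColumn)
    maf[is.na(maf)] <- -Inf
    remaining <- rownames(cl)
    selected <- character()
    gains <- integer()
    capped <- FALSE
    repeat {
        if (!any(unresolved) || !length(remaining))
            break
        if (length(selected) >= maxPanel) {
            capped <- TRUE
            break
        }
        live <- pairs[unresolved, , drop = FALSE]
        if (length(selected) == 0L) {
            # seeding step: highest MAF, not pair gain
            ord <- order(-maf[remaining], remaining)
            pick <- remaining[ord[1L]]
        } else {
            g <- vapply(remaining, function(mk)
                sum(.splitsPair(cl[mk, ], live)), 0L)
            if (max(g) == 0L)
                break
            ord <- order(-g, -maf[remaining], remaining)
            pick <- remaining[ord[1L]]
        }
        hit <- .splitsPair(cl[pick, ], live)
        selected <- c(selected, pick)
        gains <- c(gains, sum(hit))
        unresolved[which(unresolved)[hit]] <- FALSE
        remaining <- setdiff(remaining, pick)
    }
    res <- pairs[unresolved, , drop = FALSE]
    new("SelectionResult",
        selected = selected,
        gains = as.integer(gains),
        residualPairs = matrix(sampleIds(x)[res], ncol = 2L,
                               dimnames = list(NULL, c("sample_1", "sample_2"))),
        nPairs = nrow(pairs),
        complete = !capped)
}

#' Rank remaining markers and augment a panel for chromosome coverage
#'
#' Ranks the markers not yet in a panel by their differentiation score
#' (the number of still-unresolved pairs each would split, with MAF and
#' marker id as tie-breaks), then greedily appends top-ranked markers
#' from chromosomes not yet represented in the panel until every
#' chromosome present in the marker metadata is covered or no candidate
#' remains.
#'
#' @param x the \linkS4class{GenotypeMatrix} the selection was made from.
#' @param selection a \linkS4class{SelectionResult} from
#'   \code{\link{greedySelect}}.
#' @return list with \code{ranking} (DataFrame: \code{marker_id},
#'   \code{differentiation_score}, \code{maf}, \code{chromosome}) and
#'   \code{augmented} (character vector: selected panel plus appended
#'   coverage markers, in order).
#' @export
rankAndAugment <- function(x, selection) {
    cl <- genotypeCalls(x)
    chrom <- markerInfo(x)$chromosome
    if (is.null(chrom) || all(is.na(chrom)))
        stop("chromosome-coverage augmentation needs a 'chromosome' column in the marker metadata")
    chrom <- setNames(as.character(chrom), rownames(cl))
    panel <- selection@selected
    remaining <- setdiff(rownames(cl), panel)
    ids <- sampleIds(x)
    res <- selection@residualPairs
    live <- cbind(match(res[, 1L], ids), match(res[, 2L], ids))
    score <- vapply(remaining, function(mk)
        sum(.splitsPair(cl[mk, ], live)), 0L)
    maf <- vapply(remaining, function(mk) .mafColumn(cl[mk, ]), 0)
    ord <- order(-score, -maf, remaining)
    ranking <- DataFrame(marker_id = remaining[ord],
                         differentiation_score = as.integer(score[ord]),
                         maf = maf[ord],
                         chromosome = unname(chrom[remaining[ord]]))
    augmented <- panel
    repeat {
        uncovered <- setdiff(unique(chrom[!is.na(chrom)]),
                             chrom[augmented])
        cand <- ranking$marker_id[!is.na(ranking$chromosome) &
                                  ranking$chromosome %in% uncovered &
                                  !(ranking$marker_id %in% augmented)]
        if (!length(uncovered) || !length(cand))
            break
        augmented <- c(augmented, cand[1L])
    }
    list(ranking = ranking, augmented = augmented)
}

#' Exhaustive minimum discriminating panel
#'
#' Reference search enumerating marker subsets by increasing size and
#' returning the first (lexicographically smallest) subset that splits
#' every resolvable sample pair — every pair discriminated by at least
#' one marker in the full matrix.  Intended as a ground-truth check for
#' \code{\link{greedySelect}} on small instances; the enumeration is
#' guarded and refuses instances beyond \code{maxSubsets}.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param maxSize largest subset size to try.
#' @param maxSubsets enumeration guard (default 1e6 subsets).
#' @return list with \code{markers} (character vector; empty when the
#'   resolvable set is empty), \code{size}, \code{resolvable} (number of
#'   resolvable pairs) and \code{unresolvablePairs} (two-column
#'   character matrix of pairs no marker splits).
#' @export
bruteForceMinimumPanel <- function(x, maxSize = NULL, maxSubsets = 1e6) {
    cl <- genotypeCalls(x)
    n <- ncol(cl)
    m <- nrow(cl)
    if (is.null(maxSize))
        maxSize <- m
    maxSize <- min(maxSize, m)
    pairs <- .pairIndices(n)
    split <- matrix(FALSE, m, nrow(pairs))
    for (k in seq_len(m))
        split[k, ] <- .splitsPair(cl[k, ], pairs)
    resolvable <- colSums(split) > 0L
    unres <- pairs[!resolvable, , drop = FALSE]
    unresolvable <- matrix(sampleIds(x)[unres], ncol = 2L,
                           dimnames = list(NULL, c("sample_1", "sample_2")))
    if (!any(resolvable))
        return(list(markers = character(), size = 0L,
                    resolvable = 0L, unresolvablePairs = unresolvable))
    target <- split[, resolvable, drop = FALSE]
    total <- cumsum(choose(m, seq_len(maxSize)))
    if (any(total > maxSubsets))
        maxSize <- max(0L, which(total <= maxSubsets))
    if (maxSize == 0L)
        stop("subset enumeration would exceed the guard; use greedySelect() instead")
    for (size in seq_len(maxSize)) {
        combos <- combn(m, size)
        for (ci in seq_len(ncol(combos))) {
            sel <- combos[, ci]
            if (all(colSums(target[sel, , drop = FALSE]) > 0L))
                return(list(markers = rownames(cl)[sel],
                            size = as.integer(size),
                            resolvable = sum(resolvable),
                            unresolvablePairs = unresolvable))
        }
    }
    list(markers = NULL, size = NA_integer_,
         resolvable = sum(resolvable), unresolvablePairs = unresolvable)
}
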