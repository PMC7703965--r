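#' Shared-call similarity between SNP profiles
#'
#' Similarity of two samples is the number of markers with identical
#' calls divided by the number of markers called in both; markers
#' missing in either sample are not used.  With no shared called marker
#' the similarity is undefined (\code{NA}).
#'
#' @param a,b integer code vectors of equal length.
#' @return fraction in [0, 1], or \code{NA} when undefined.
#' @export
profileSimilarity <- function(a, b) {
    d <- pairwiseDifferences(a, b)
    if (d["comparable"] == 0L)
        return(NA_real_)
    unname((d["comparable"] - d["differences"]) / d["comparable"])
}

#' Pairwise similarity and distance matrices
#'
#' \code{similarityMatrix} applies \code{\link{profileSimilarity}} to
#' every sample pair; \code{genotypeDistance} returns its complement
#' (1 - similarity).  For complete profiles of \eqn{m} markers the
#' distance can only take the values \eqn{k/m}: one SNP difference on a
#' 21-marker panel is a distance of 1/21 (about 0.05).  Pairs with no
#' shared called marker are \code{NA} and must be resolved by the caller
#' before clustering.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @return symmetric numeric matrix with unit (zero) diagonal.
#' @name similarityMatrix
#' @rdname similarityMatrix
#' @export
similarityMatrix <- function(x) {
    cl <- genotypeCalls(x)
    called <- !is.na(cl)
    comparable <- crossprod(called)
    matches <- matrix(0, ncol(cl), ncol(cl))
    for (s in 0:2) {
        ind <- called & !is.na(cl) & cl == s
        ind[is.na(cl)] <- FALSE
        matches <- matches + crossprod(ind)
    }
    sim <- matches / comparable
    sim[comparable == 0] <- NA_real_
    dg <- diag(sim)
    dg[colSums(called) > 0] <- 1
    diag(sim) <- dg
    dimnames(sim) <- list(sampleIds(x), sampleIds(x))
    sim
}

#' @rdname similarityMatrix
#' @export
genotypeDistance <- function(x) 1 - similarityMatrix(x)

#' Agglomerative clustering of a distance matrix
#'
#' Standard hierarchical clustering (\code{stats::hclust}) of the
#' shared-call distance matrix.  Undefined distances (pairs with no
#' shared called marker) are refused, naming the offending pairs:
#' imputing them would fabricate relatedness.  \code{hclust} resolves
#' merge-height ties by the order of the input rows, so identical inputs
#' give identical trees.
#'
#' @param d symmetric distance matrix (e.g. from
#'   \code{\link{genotypeDistance}}) or a \code{dist}.
#' @param linkage \code{"average"} (UPGMA, default), \code{"complete"}
#'   or \code{"single"}.
#' @return an \code{hclust} tree.
#' @export
hierarchicalCluster <- function(d, linkage = c("average", "complete",
                                               "single")) {
    linkage <- match.arg(linkage)
    if (is.matrix(d)) {
        if (anyNA(d)) {
            bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
            stop("undefined distances (no shared called markers) for pairs: ",
                 paste(utils::head(
                     paste(rownames(d)[bad[, 1L]], colnames(d)[bad[, 2L]],
                           sep = " / "), 5L), collapse = "; "))
        }
        d <- as.dist(d)
    }
    hclust(d, method = linkage)
}

# Clade keys (sorted member labels) for every internal node of an
# hclust tree, in merge order.
.hclustClades <- function(hc) {
    n <- length(hc$labels)
    sets <- vector("list", nrow(hc$merge))
    for (k in seq_len(nrow(hc$merge))) {
        pick <- function(v) if (v < 0L) hc$labels[-v] else sets[[v]]
        sets[[k]] <- sort(c(pick(hc$merge[k, 1L]), pick(hc$merge[k, 2L])))
    }
    sets
}

.cladeKey <- function(members) paste(members, collapse = "\r")

#' Marker-bootstrap support for a cluster tree
#'
#' Felsenstein-style bootstrap over markers: in each replicate the
#' markers are resampled with replacement, the distance matrix and tree
#' are rebuilt, and each internal node of the reference tree is scored
#' present when a replicate tree contains a clade with exactly the same
#' leaf set.  Clades of pairwise-identical profiles always reappear, so
#' they earn 100\% support; clusters held together by many-SNP
#' differences do not.
#'
#' @param x the \linkS4class{GenotypeMatrix} the tree was built from
#'   (needs >= 2 markers; with one marker the bootstrap is degenerate
#'   and refused).
#' @param tree the reference \code{hclust} tree.
#' @param replicates number of bootstrap replicates (>= 1; 1000 typical).
#' @param seed integer seed for reproducibility.
#' @param linkage linkage used to rebuild replicate trees (use the one
#'   the reference tree was built with).
#' @return numeric vector of support percentages, one per internal node
#'   in merge order, with the clade member lists attached as the
#'   \code{"clades"} attribute.  Replicates in which some pair loses all
#'   shared called markers are skipped (counted in the
#'   \code{"skipped"} attribute).
#' @export
bootstrapSupport <- function(x, tree, replicates = 1000L, seed = 1L,
                             linkage = c("average", "complete", "single")) {
    linkage <- match.arg(linkage)
    cl <- genotypeCalls(x)
    if (nrow(cl) < 2L)
        stop("bootstrap over a single marker is degenerate")
    if (replicates < 1L)
        stop("replicates must be >= 1")
    refClades <- .hclustClades(tree)
    keys <- vapply(refClades, .cladeKey, "")
    hits <- numeric(length(keys))
    used <- 0L
    skipped <- 0L
    set.seed(seed)
    for (r in seq_len(replicates)) {
        idx <- sample.int(nrow(cl), replace = TRUE)
        xb <- GenotypeMatrix(
            structure(cl[idx, , drop = FALSE],
                      dimnames = list(sprintf("B%03d", seq_along(idx)),
                                      colnames(cl))))
        db <- genotypeDistance(xb)
        if (anyNA(db[upper.tri(db)])) {
            skipped <- skipped + 1L
            next
        }
        hb <- hclust(as.dist(db), method = linkage)
        bkeys <- vapply(.hclustClades(hb), .cladeKey, "")
        hits <- hits + (keys %in% bkeys)
        used <- used + 1L
    }
    if (used == 0L)
        stop("every bootstrap replicate produced undefined distances")
    structure(100 * hits / used, clades = refClades, skipped = skipped)
}

#' Export a cluster tree as newick (or NEXUS)
#'
#' Converts an \code{hclust} tree to a phylogram (\code{ape::as.phylo},
#' ultrametric: leaf depths are half the merge heights), writes bootstrap
#' supports as internal node labels when given, and serializes with
#' \code{ape::write.tree}.  Re-parsing the string recovers the topology
#' exactly.  \code{exportNexus} wraps the same tree in a NEXUS file with
#' a taxa block.
#'
#' @param tree an \code{hclust} (or \code{phylo}) tree.
#' @param supports optional numeric vector from
#'   \code{\link{bootstrapSupport}} (per internal node in merge order).
#' @param file optional path; when omitted the newick string is
#'   returned.
#' @param digits support label digits.
#' @return the newick string (invisibly when written to a file).
#' @name exportNewick
#' @rdname exportNewick
#' @export
exportNewick <- function(tree, supports = NULL, file = NULL, digits = 0L) {
    phy <- .toPhylo(tree, supports, digits)
    if (is.null(file))
        return(ape::write.tree(phy))
    ape::write.tree(phy, file = file)
    invisible(ape::write.tree(phy))
}

#' @rdname exportNewick
#' @export
exportNexus <- function(tree, supports = NULL, file, digits = 0L) {
    phy <- .toPhylo(tree, supports, digits)
    ape::write.nexus(phy, file = file)
    invisible(file)
}

.toPhylo <- function(tree, supports, digits) {
    if (inherits(tree, "phylo")) {
        phy <- tree
        if (!is.null(supports))
            stop("supports can only be attached when converting an hclust tree")
        return(phy)
    }
    phy <- ape::as.phylo(tree)
    if (!is.null(supports)) {
        clades <- attr(supports, "clades")
        if (is.null(clades))
            clades <- .hclustClades(tree)
        keys <- vapply(clades, .cladeKey, "")
        parts <- ape::prop.part(phy)
        labs <- attr(parts, "labels")
        nodeKeys <- vapply(parts, function(tips)
            .cladeKey(sort(labs[tips])), "")
        phy$node.label <- ifelse(
            is.na(match(nodeKeys, keys)), "",
            formatC(supports[match(nodeKeys, keys)],
                    format = "f", digits = digits))
    }
    phy
}

#' Cut a tree into flat clusters at a height
#'
#' Convenience wrapper around \code{stats::cutree}: no default height is
#' asserted, since a dendrogram over a small marker panel is a
#' description, not a phylogeny, and any cut is a user decision.
#'
#' @param tree an \code{hclust} tree.
#' @param h cut height (distance).
#' @return named integer vector of cluster memberships.
#' @export
cutClusters <- function(tree, h) stats::cutree(tree, h = h)
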