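#' @import methods
#' @importFrom stats as.dist hclust runif rbinom qbinom setNames aggregate
#' @importFrom utils combn read.table write.table
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

# Integer encoding of a biallelic call relative to the marker's
# alphabetically ordered allele pair (X < Y):
#   0 = homozygous X, 1 = heterozygous, 2 = homozygous Y, NA = missing.
.CALL_LEVELS <- c(HOM_X = 0L, HET = 1L, HOM_Y = 2L)

#' GenotypeMatrix: biallelic SNP calls for a germplasm collection
#'
#' An S4 container for a dense table of biallelic genotype calls
#' (samples by markers), stored as a \linkS4class{SummarizedExperiment}
#' with markers as rows and samples as columns.  The single assay,
#' \code{"calls"}, holds integer codes: 0 = homozygous for the
#' alphabetically first allele (X), 1 = heterozygous, 2 = homozygous for
#' the second allele (Y), \code{NA} = missing / no-call.  Marker
#' metadata (\code{marker_id}, \code{chromosome}, \code{allele_x},
#' \code{allele_y}, optional primer sequences) lives in \code{rowData};
#' sample metadata (\code{sample_id}, \code{variety_name},
#' \code{replicate_label}, \code{ploidy}) in \code{colData}.
#'
#' Genotypes are canonicalized internally to alphabetical allele order,
#' so an unordered KASP call "GA" at an A/G marker is stored identically
#' to "AG".  Ploidy is metadata only: calls are diploid-style categories
#' even for triploids, matching the three-cluster KASP readout.
#'
#' @seealso \code{\link{GenotypeMatrix}} (constructor),
#'   \code{\link{readGenotypeTable}}, \code{\link{genotypeCalls}}
#' @name GenotypeMatrix-class
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

.validGenotypeMatrix <- function(object) {
    msg <- character()
    if (!"calls" %in% SummarizedExperiment::assayNames(object))
        return("assay 'calls' is required")
    cl <- assay(object, "calls")
    if (!is.integer(cl))
        msg <- c(msg, "assay 'calls' must be an integer matrix")
    bad <- cl[!is.na(cl)]
    if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
        msg <- c(msg, "calls must be 0 (hom X), 1 (het), 2 (hom Y) or NA")
    rd <- rowData(object)
    for (f in c("marker_id", "allele_x", "allele_y"))
        if (!f %in% colnames(rd))
            msg <- c(msg, sprintf("rowData column '%s' is required", f))
    if (all(c("marker_id", "allele_x", "allele_y") %in% colnames(rd))) {
        if (anyDuplicated(rd$marker_id))
            msg <- c(msg, "duplicate marker_id")
        same <- !is.na(rd$allele_x) & !is.na(rd$allele_y) &
            rd$allele_x == rd$allele_y
        if (any(same))
            msg <- c(msg, "allele_x and allele_y must differ for every marker")
        swapped <- !is.na(rd$allele_x) & !is.na(rd$allele_y) &
            as.character(rd$allele_x) > as.character(rd$allele_y)
        if (any(swapped))
            msg <- c(msg, "alleles must be stored in alphabetical order (X < Y)")
    }
    cd <- colData(object)
    if (!"sample_id" %in% colnames(cd))
        msg <- c(msg, "colData column 'sample_id' is required")
    else if (anyDuplicated(cd$sample_id))
        msg <- c(msg, "duplicate sample_id")
    if ("ploidy" %in% colnames(cd)) {
        pl <- cd$ploidy[!is.na(cd$ploidy)]
        if (length(pl) && !all(pl %in% 2:4))
            msg <- c(msg, "ploidy must be 2, 3 or 4 when present")
    }
    if (length(msg)) msg else TRUE
}
setValidity("GenotypeMatrix", .validGenotypeMatrix)

#' Result of greedy minimal-panel selection
#'
#' Ordered markers chosen by \code{\link{greedySelect}}, the number of
#' newly discriminated sample pairs contributed at each step, and the
#' sample pairs left unresolved at termination.
#'
#' @slot selected ordered character vector of selected marker ids.
#' @slot gains integer vector, per-step count of newly resolved pairs
#'   (parallel to \code{selected}).
#' @slot residualPairs two-column character matrix of sample-id pairs
#'   still unresolved when selection stopped.
#' @slot nPairs total number of sample pairs, \eqn{\binom{n}{2}}.
#' @slot complete logical: \code{TRUE} if selection ran until no marker
#'   added discrimination (so residual pairs are unsplittable by any
#'   marker in the matrix), \code{FALSE} if a panel-size cap stopped it.
#' @name SelectionResult-class
#' @aliases SelectionResult-class
#' @exportClass SelectionResult
setClass("SelectionResult", representation(
    selected = "character",
    gains = "integer",
    residualPairs = "matrix",
    nPairs = "integer",
    complete = "logical"
))

#' Replicate-based genotyping error-rate estimate
#'
#' @slot errors integer, total discordant calls counted as errors.
#' @slot totalCalls integer, non-missing calls among included samples.
#' @slot rate numeric, \code{errors / totalCalls}.
#' @slot assumption \code{"all_genuine"} (every nominal replicate is a
#'   true biological replicate) or \code{"diff_threshold"} (members too
#'   divergent from their group are presumed mislabelled and excluded).
#' @slot threshold integer, maximum tolerated SNP differences under
#'   \code{"diff_threshold"}.
#' @slot excluded DataFrame logging excluded samples and reasons.
#' @slot perGroup DataFrame with per-group errors, calls and rate.
#' @name ErrorEstimate-class
#' @aliases ErrorEstimate-class
#' @exportClass ErrorEstimate
setClass("ErrorEstimate", representation(
    errors = "integer",
    totalCalls = "integer",
    rate = "numeric",
    assumption = "character",
    threshold = "integer",
    excluded = "DataFrame",
    perGroup = "DataFrame"
))

#' A group of samples sharing one SNP profile
#'
#' @slot members character vector of sample ids.
#' @slot representative named integer vector of call codes (the shared
#'   profile; for compatibility-merged groups, the consensus of called
#'   states).
#' @slot systematicNulls character vector of markers missing in every
#'   member (candidate null alleles), filled by
#'   \code{\link{findSystematicNulls}}.
#' @name ProfileGroup-class
#' @aliases ProfileGroup-class
#' @exportClass ProfileGroup
setClass("ProfileGroup", representation(
    members = "character",
    representative = "integer",
    systematicNulls = "character"
))

#' Cross-platform concordance report
#'
#' @slot perMarker DataFrame with columns \code{marker_id},
#'   \code{compared}, \code{agree}, \code{het_to_hom}, \code{hom_to_het},
#'   \code{other_disagree}.
#' @slot overallPercent numeric in [0, 100].
#' @name ConcordanceReport-class
#' @aliases ConcordanceReport-class
#' @exportClass ConcordanceReport
setClass("ConcordanceReport", representation(
    perMarker = "DataFrame",
    overallPercent = "numeric"
))
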