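#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix of call codes (markers in rows, samples in
#'   columns; 0/1/2/NA) or a character matrix of two-letter genotypes
#'   (samples in rows or markers in rows, see \code{samplesInRows}).
#'   Dimnames are required: marker ids and sample ids.
#' @param markerInfo optional \code{DataFrame}/\code{data.frame} with
#'   columns \code{marker_id}, \code{allele_x}, \code{allele_y} and
#'   optionally \code{chromosome} and primer columns.  When absent,
#'   allele pairs are inferred from the observed letters of a character
#'   \code{calls} matrix, or set to the placeholder pair A/B for coded
#'   input.
#' @param sampleInfo optional \code{DataFrame}/\code{data.frame} with
#'   column \code{sample_id} and optionally \code{variety_name},
#'   \code{replicate_label}, \code{ploidy}.
#' @param samplesInRows logical; for character \code{calls}, whether rows
#'   are samples (the spreadsheet layout).  Coded integer input is always
#'   markers x samples.
#' @param missingTokens character vector of strings treated as no-calls
#'   in character input.
#' @return a \linkS4class{GenotypeMatrix}.
#' @examples
#' tab <- rbind(s1 = c(m1 = "AA", m2 = "CT"),
#'              s2 = c(m1 = "GA", m2 = "--"))
#' gm <- GenotypeMatrix(tab, samplesInRows = TRUE)
#' genotypeCalls(gm)
#' @export
GenotypeMatrix <- function(calls, markerInfo = NULL, sampleInfo = NULL,
                           samplesInRows = FALSE,
                           missingTokens = c("", "NA", "--", "NN")) {
    if (is.character(calls)) {
        if (samplesInRows)
            calls <- t(calls)
        if (is.null(rownames(calls)) || is.null(colnames(calls)))
            stop("character call matrices need marker and sample dimnames")
        enc <- .encodeCalls(calls, markerInfo, missingTokens)
        calls <- enc$codes
        markerInfo <- enc$markerInfo
    } else {
        storage.mode(calls) <- "integer"
        if (is.null(rownames(calls)))
            rownames(calls) <- sprintf("M%02d", seq_len(nrow(calls)))
        if (is.null(colnames(calls)))
            colnames(calls) <- sprintf("S%03d", seq_len(ncol(calls)))
        if (is.null(markerInfo))
            markerInfo <- DataFrame(marker_id = rownames(calls),
                                    allele_x = "A", allele_y = "B")
    }
    markerInfo <- .alignMeta(DataFrame(markerInfo), "marker_id",
                             rownames(calls))
    if (is.null(sampleInfo))
        sampleInfo <- DataFrame(sample_id = as.character(colnames(calls)))
    sampleInfo <- .alignMeta(DataFrame(sampleInfo), "sample_id",
                             colnames(calls))
    se <- SummarizedExperiment(assays = list(calls = calls),
                               rowData = markerInfo, colData = sampleInfo)
    new("GenotypeMatrix", se)
}

# Reorder a metadata table to match the matrix dimnames, or create rows
# for ids it lacks.
.alignMeta <- function(df, key, ids) {
    if (!key %in% colnames(df))
        stop(sprintf("metadata must contain a '%s' column", key))
    df[[key]] <- as.character(df[[key]])
    if (anyDuplicated(df[[key]]))
        stop(sprintf("duplicate %s in metadata", key))
    miss <- setdiff(ids, df[[key]])
    if (length(miss))
        stop(sprintf("metadata missing %s: %s", key,
                     paste(utils::head(miss, 5L), collapse = ", ")))
    df <- df[match(ids, df[[key]]), , drop = FALSE]
    rownames(df) <- ids
    df
}

# Turn a character matrix (markers x samples) of two-letter genotypes
# into integer codes, inferring or checking the allele pair per marker.
.encodeCalls <- function(chr, markerInfo, missingTokens) {
    chr <- trimws(chr)
    chr[chr %in% missingTokens] <- NA_character_
    ok <- is.na(chr) | grepl("^[ACGTacgt]{2}$", chr)
    if (!all(ok)) {
        bad <- which(!ok, arr.ind = TRUE)[1L, ]
        stop(sprintf("malformed genotype '%s' at sample '%s', marker '%s'",
                     chr[bad[1L], bad[2L]],
                     colnames(chr)[bad[2L]], rownames(chr)[bad[1L]]))
    }
    chr <- toupper(chr)
    a1 <- substr(chr, 1L, 1L)
    a2 <- substr(chr, 2L, 2L)
    if (is.null(markerInfo)) {
        pairs <- lapply(seq_len(nrow(chr)), function(i) {
            letters <- sort(unique(stats::na.omit(c(a1[i, ], a2[i, ]))))
            if (length(letters) > 2L)
                stop(sprintf(
                    "marker '%s' shows %d distinct alleles (%s); markers must be biallelic",
                    rownames(chr)[i], length(letters),
                    paste(letters, collapse = "/")))
            if (length(letters) == 0L) letters <- c("A", "B")
            if (length(letters) == 1L)
                letters <- c(letters, setdiff(c("A", "C", "G", "T"),
                                              letters)[1L])
            letters
        })
        markerInfo <- DataFrame(
            marker_id = rownames(chr),
            allele_x = vapply(pairs, `[`, "", 1L),
            allele_y = vapply(pairs, `[`, "", 2L))
    }
    mi <- .alignMeta(DataFrame(markerInfo), "marker_id", rownames(chr))
    ax <- as.character(mi$allele_x)
    ay <- as.character(mi$allele_y)
    codes <- matrix(NA_integer_, nrow(chr), ncol(chr),
                    dimnames = dimnames(chr))
    for (i in seq_len(nrow(chr))) {
        known <- c(ax[i], ay[i])
        called <- !is.na(chr[i, ])
        outside <- called & (!(a1[i, ] %in% known) | !(a2[i, ] %in% known))
        if (any(outside)) {
            j <- which(outside)[1L]
            stop(sprintf(
                "call '%s' for sample '%s' at marker '%s' uses an allele outside the %s/%s pair",
                chr[i, j], colnames(chr)[j], rownames(chr)[i], ax[i], ay[i]))
        }
        # unordered call: code = number of Y alleles
        codes[i, called] <- (a1[i, called] == ay[i]) + (a2[i, called] == ay[i])
    }
    list(codes = codes, markerInfo = mi)
}

#' Accessors for GenotypeMatrix
#'
#' \code{genotypeCalls} returns the integer call matrix (markers x
#' samples; 0 = hom X, 1 = het, 2 = hom Y, NA = missing).
#' \code{markerInfo} and \code{sampleInfo} return the marker and sample
#' metadata tables; \code{markerIds} and \code{sampleIds} their ids.
#' \code{genotypeStrings} renders calls as two-letter genotypes in the
#' marker's X/Y orientation.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @return see individual descriptions.
#' @aliases genotypeCalls markerInfo sampleInfo markerIds sampleIds
#'   genotypeStrings
#' @name genotypeCalls
#' @rdname genotypeCalls
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname genotypeCalls
setMethod("genotypeCalls", "GenotypeMatrix", function(x)
    assay(x, "calls"))

#' @rdname genotypeCalls
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname genotypeCalls
setMethod("markerInfo", "GenotypeMatrix", function(x) rowData(x))

#' @rdname genotypeCalls
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname genotypeCalls
setMethod("sampleInfo", "GenotypeMatrix", function(x) colData(x))

#' @rdname genotypeCalls
#' @export
markerIds <- function(x) rownames(x)

#' @rdname genotypeCalls
#' @export
sampleIds <- function(x) colnames(x)

#' @param missingToken string used to render missing calls.
#' @rdname genotypeCalls
#' @export
genotypeStrings <- function(x, missingToken = "--") {
    cl <- genotypeCalls(x)
    ax <- as.character(markerInfo(x)$allele_x)
    ay <- as.character(markerInfo(x)$allele_y)
    out <- matrix(missingToken, nrow(cl), ncol(cl), dimnames = dimnames(cl))
    gl <- cbind(paste0(ax, ax), paste0(ax, ay), paste0(ay, ay))
    for (i in seq_len(nrow(cl))) {
        called <- !is.na(cl[i, ])
        out[i, called] <- gl[i, cl[i, called] + 1L]
    }
    out
}

setMethod("show", "GenotypeMatrix", function(object) {
    cl <- assay(object, "calls")
    miss <- sum(is.na(cl))
    cat(sprintf("GenotypeMatrix: %d samples x %d markers\n",
                ncol(cl), nrow(cl)))
    cat(sprintf("  missing calls: %d of %d (%.1f%%)\n",
                miss, length(cl),
                if (length(cl)) 100 * miss / length(cl) else 0))
    chrom <- rowData(object)$chromosome
    if (!is.null(chrom))
        cat(sprintf("  chromosomes: %d\n",
                    length(unique(chrom[!is.na(chrom)]))))
    invisible(NULL)
})

setMethod("show", "SelectionResult", function(object) {
    cat(sprintf("SelectionResult: %d markers, %d/%d pairs resolved\n",
                length(object@selected),
                object@nPairs - nrow(object@residualPairs), object@nPairs))
    if (length(object@selected)) {
        cat("  order: ", paste(object@selected, collapse = " > "), "\n")
        cat("  gains: ", paste(object@gains, collapse = ", "), "\n")
    }
    cat(sprintf("  residual unresolved pairs: %d%s\n",
                nrow(object@residualPairs),
                if (object@complete) " (unsplittable by any marker)" else
                    " (panel size cap reached)"))
    invisible(NULL)
})

setMethod("show", "ErrorEstimate", function(object) {
    cat(sprintf("ErrorEstimate (%s): %d errors / %d calls = %.2f%%\n",
                object@assumption, object@errors, object@totalCalls,
                100 * object@rate))
    if (nrow(object@excluded))
        cat(sprintf("  excluded samples: %d\n", nrow(object@excluded)))
    invisible(NULL)
})

setMethod("show", "ProfileGroup", function(object) {
    cat(sprintf("ProfileGroup: %d sample(s)", length(object@members)))
    if (length(object@systematicNulls))
        cat(sprintf(", systematic nulls: %s",
                    paste(object@systematicNulls, collapse = ", ")))
    cat("\n  ", paste(utils::head(object@members, 8L), collapse = ", "))
    if (length(object@members) > 8L) cat(", ...")
    cat("\n")
    invisible(NULL)
})

setMethod("show", "ConcordanceReport", function(object) {
    cat(sprintf("ConcordanceReport: %.1f%% overall (%d markers)\n",
                object@overallPercent, nrow(object@perMarker)))
    invisible(NULL)
})

#' Group membership, gains and residual pairs of a selection
#'
#' @param x a \linkS4class{SelectionResult}.
#' @return \code{selectedMarkers}: character vector; \code{selectionGains}:
#'   integer vector; \code{residualPairs}: two-column character matrix of
#'   unresolved sample pairs.
#' @name selectedMarkers
#' @rdname selectedMarkers
#' @export
selectedMarkers <- function(x) x@selected

#' @rdname selectedMarkers
#' @export
selectionGains <- function(x) x@gains

#' @rdname selectedMarkers
#' @export
residualPairs <- function(x) x@residualPairs

#' Members and representative profile of a profile group
#'
#' @param x a \linkS4class{ProfileGroup}.
#' @return \code{groupMembers}: character vector of sample ids;
#'   \code{representativeProfile}: named integer vector of call codes.
#' @name groupMembers
#' @rdname groupMembers
#' @export
groupMembers <- function(x) x@members

#' @rdname groupMembers
#' @export
representativeProfile <- function(x) x@representative

#' Error-estimate accessors
#'
#' @param x an \linkS4class{ErrorEstimate}.
#' @return \code{errorRate}: numeric rate; \code{errorCounts}: named
#'   integer vector (errors, total_calls); \code{excludedSamples}:
#'   DataFrame of exclusions.
#' @name errorRate
#' @rdname errorRate
#' @export
errorRate <- function(x) x@rate

#' @rdname errorRate
#' @export
errorCounts <- function(x)
    c(errors = x@errors, total_calls = x@totalCalls)

#' @rdname errorRate
#' @export
excludedSamples <- function(x) x@excluded
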