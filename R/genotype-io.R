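#' Read a genotype table
#'
#' Reads a CSV/TSV genotype table in the spreadsheet layout: header row
#' of marker ids, first column of sample ids, each cell a two-letter
#' genotype (unordered; "GA" and "AG" are the same call) or a missing
#' token.  Calls are canonicalized to the marker's alphabetical X/Y
#' allele orientation.  When marker metadata with declared allele pairs
#' is supplied, any call using an allele outside the marker's pair is an
#' error naming the offending cell; without metadata the pair is
#' inferred from the observed letters (more than two letters at one
#' marker is an error).
#'
#' @param file path or connection.
#' @param missingTokens strings read as no-calls; the empty cell,
#'   \code{"NA"}, \code{"--"} and \code{"NN"} by default.
#' @param sep field separator; \code{NULL} picks "\\t" for .tsv/.txt
#'   files and "," otherwise.
#' @param markerInfo optional marker metadata (see
#'   \code{\link{GenotypeMatrix}}).
#' @param sampleInfo optional sample metadata.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
readGenotypeTable <- function(file, missingTokens = c("", "NA", "--", "NN"),
                              sep = NULL, markerInfo = NULL,
                              sampleInfo = NULL) {
    if (is.null(sep))
        sep <- if (is.character(file) && grepl("\\.(tsv|txt)$", file,
                                               ignore.case = TRUE))
            "\t" else ","
    raw <- read.table(file, sep = sep, header = FALSE,
                      colClasses = "character", check.names = FALSE,
                      stringsAsFactors = FALSE, na.strings = NULL,
                      quote = "\"", comment.char = "", fill = FALSE)
    if (nrow(raw) < 2L || ncol(raw) < 2L)
        stop("genotype table needs a header row of marker ids and at least one sample row")
    mk <- trimws(as.character(raw[1L, -1L]))
    ids <- trimws(as.character(raw[-1L, 1L]))
    if (anyDuplicated(mk))
        stop("duplicate marker ids in header: ",
             paste(unique(mk[duplicated(mk)]), collapse = ", "))
    if (anyDuplicated(ids))
        stop("duplicate sample ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    body <- as.matrix(raw[-1L, -1L, drop = FALSE])
    dimnames(body) <- list(ids, mk)
    GenotypeMatrix(body, markerInfo = markerInfo, sampleInfo = sampleInfo,
                   samplesInRows = TRUE, missingTokens = missingTokens)
}

#' Write a genotype table
#'
#' Inverse of \code{\link{readGenotypeTable}}: samples in rows, markers
#' in columns, calls rendered in the marker's X/Y orientation.  A
#' write-then-read round trip reproduces calls and ordering exactly.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param file path or connection.
#' @param missingToken string written for missing calls.
#' @param sep field separator.
#' @return invisibly, \code{file}.
#' @export
writeGenotypeTable <- function(x, file, missingToken = "--", sep = ",") {
    gs <- t(genotypeStrings(x, missingToken = missingToken))
    out <- cbind(sample_id = rownames(gs), as.data.frame(gs))
    write.table(out, file, sep = sep, row.names = FALSE, quote = FALSE)
    invisible(file)
}

#' Read marker or sample metadata
#'
#' Small CSV readers for the companion metadata tables: markers
#' (\code{marker_id}, \code{chromosome}, \code{allele_x}, \code{allele_y},
#' optional primer columns) and samples (\code{sample_id},
#' \code{variety_name}, \code{replicate_label}, \code{ploidy}).
#'
#' @param file path or connection.
#' @param sep field separator.
#' @return a \code{DataFrame}.
#' @name readMarkerInfo
#' @rdname readMarkerInfo
#' @export
readMarkerInfo <- function(file, sep = ",") {
    df <- read.table(file, sep = sep, header = TRUE,
                     stringsAsFactors = FALSE, check.names = FALSE,
                     quote = "\"", comment.char = "")
    if (!all(c("marker_id", "allele_x", "allele_y") %in% colnames(df)))
        stop("marker metadata needs columns marker_id, allele_x, allele_y")
    DataFrame(df)
}

#' @rdname readMarkerInfo
#' @export
readSampleInfo <- function(file, sep = ",") {
    df <- read.table(file, sep = sep, header = TRUE,
                     stringsAsFactors = FALSE, check.names = FALSE,
                     quote = "\"", comment.char = "")
    if (!"sample_id" %in% colnames(df))
        stop("sample metadata needs a sample_id column")
    DataFrame(df)
}

#' Per-marker and overall fail rates
#'
#' The fail rate of a marker is the fraction of samples with a missing
#' call at that marker; the overall rate is total missing calls over all
#' cells of the matrix.
#'
#' @param x a non-empty \linkS4class{GenotypeMatrix}.
#' @return a list with \code{perMarker} (DataFrame: \code{marker_id},
#'   \code{n_missing}, \code{fail_rate}) and \code{overall} (list:
#'   \code{n_missing}, \code{n_calls}, \code{fail_rate}).
#' @export
markerFailRates <- function(x) {
    cl <- genotypeCalls(x)
    if (length(cl) == 0L)
        stop("empty genotype matrix")
    nm <- as.integer(rowSums(is.na(cl)))
    list(
        perMarker = DataFrame(marker_id = rownames(cl),
                              n_missing = nm,
                              fail_rate = nm / ncol(cl)),
        overall = list(n_missing = sum(nm), n_calls = length(cl),
                       fail_rate = sum(nm) / length(cl))
    )
}

#' Per-sample counts of non-missing calls
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @return named integer vector of non-missing call counts per sample.
#' @export
sampleCallCounts <- function(x) {
    cl <- genotypeCalls(x)
    colSums(!is.na(cl))
}

#' Retain samples with enough successful calls
#'
#' Keeps the samples with at least \code{minCalls} non-missing calls,
#' the retention rule used before any profile analysis (e.g. at least
#' 19 of 21 markers called), and reports those removed.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param minCalls integer in [0, number of markers].
#' @return list with \code{retained} (a \linkS4class{GenotypeMatrix},
#'   sample order preserved) and \code{removed} (character vector of
#'   sample ids).
#' @export
filterByMinCalls <- function(x, minCalls) {
    m <- nrow(genotypeCalls(x))
    if (!is.numeric(minCalls) || length(minCalls) != 1L ||
        minCalls < 0 || minCalls > m)
        stop(sprintf("minCalls must be a single integer in [0, %d]", m))
    keep <- sampleCallCounts(x) >= minCalls
    list(retained = x[, keep], removed = sampleIds(x)[!keep])
}
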