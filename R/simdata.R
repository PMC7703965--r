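#' Configuration for a synthetic germplasm collection
#'
#' Bundles and validates the generating parameters of
#' \code{\link{simulateCollection}}.  The defaults emulate a curated
#' clonal fruit collection genotyped on a small KASP panel: 21 markers
#' with intermediate minor allele frequencies; mostly singleton
#' varieties with some clone groups (synonyms, sports, declared
#' replicates); about 12\% triploid-like samples whose elevated
#' heterozygosity raises a diploid-scale mean of about 0.44 to about
#' 0.62; a per-call miscall rate of a few per thousand and a no-call
#' rate of a few percent.
#'
#' @param nFounders number of distinct founder genotypes (>= 2).
#' @param nMarkers number of biallelic markers (>= 1).
#' @param mafRange range the per-marker minor allele frequency is drawn
#'   from, within (0, 0.5].
#' @param cloneGroupSizes integer vector the clone-group size of each
#'   founder is drawn from (with replacement).
#' @param sportMutationRate per-call probability that a clone copy
#'   carries a somatic (sport) mutation — a genuine genotype change.
#' @param triploidFraction fraction of founders marked triploid.
#' @param hetInflation probability that a homozygous founder call in a
#'   triploid-like lineage is shifted to heterozygous.
#' @param miscallRate per-call probability of a genotyping error (state
#'   flip among the three called states).
#' @param missingRate per-call probability of a no-call.
#' @param mislabelRate fraction of samples whose replicate label is
#'   reassigned to a different variety.
#' @param seed integer seed; the whole simulation is reproducible from
#'   it.
#' @return a validated \code{simConfig} list.
#' @export
simConfig <- function(nFounders = 100L, nMarkers = 21L,
                      mafRange = c(0.2, 0.5),
                      cloneGroupSizes = c(1L, 1L, 1L, 1L, 2L, 3L),
                      sportMutationRate = 0.001,
                      triploidFraction = 0.12, hetInflation = 0.32,
                      miscallRate = 0.002, missingRate = 0.035,
                      mislabelRate = 0, seed = 1L) {
    cfg <- list(nFounders = as.integer(nFounders),
                nMarkers = as.integer(nMarkers),
                mafRange = as.numeric(mafRange),
                cloneGroupSizes = as.integer(cloneGroupSizes),
                sportMutationRate = sportMutationRate,
                triploidFraction = triploidFraction,
                hetInflation = hetInflation,
                miscallRate = miscallRate,
                missingRate = missingRate,
                mislabelRate = mislabelRate,
                seed = as.integer(seed))
    bad <- character()
    if (cfg$nFounders < 2L) bad <- c(bad, "nFounders must be >= 2")
    if (cfg$nMarkers < 1L) bad <- c(bad, "nMarkers must be >= 1")
    if (length(cfg$mafRange) != 2L || any(cfg$mafRange <= 0) ||
        any(cfg$mafRange > 0.5) || cfg$mafRange[1L] > cfg$mafRange[2L])
        bad <- c(bad, "mafRange must be an increasing interval within (0, 0.5]")
    if (!length(cfg$cloneGroupSizes) || any(cfg$cloneGroupSizes < 1L))
        bad <- c(bad, "cloneGroupSizes must be positive integers")
    for (p in c("sportMutationRate", "triploidFraction", "hetInflation",
                "miscallRate", "missingRate", "mislabelRate"))
        if (cfg[[p]] < 0 || cfg[[p]] > 1)
            bad <- c(bad, sprintf("%s must be in [0, 1]", p))
    if (length(bad))
        stop("invalid simulation configuration: ",
             paste(bad, collapse = "; "))
    class(cfg) <- "simConfig"
    cfg
}

#' Simulate a clonal germplasm collection with known truth
#'
#' Founder genotypes are drawn marker-wise from Hardy-Weinberg
#' proportions at a minor allele frequency sampled per marker from
#' \code{mafRange}.  Triploid-like founders have homozygous calls
#' shifted to heterozygous with probability \code{hetInflation}
#' (phenomenological: the observed KASP readout is a diploid-style call
#' whatever the ploidy).  Each founder is copied into a clone group;
#' copies acquire sport mutations (true genotype changes) at
#' \code{sportMutationRate} per call.  Observation noise — miscalls
#' flipping uniformly to one of the two other called states, then
#' no-calls — is injected per call and fully logged.  Finally a fraction
#' of samples have their replicate label reassigned to a different
#' variety (mislabels).
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with \code{observed} (a \linkS4class{GenotypeMatrix}
#'   with variety, replicate-label and ploidy metadata) and \code{truth}
#'   (list: \code{trueGenotypes}, \code{cloneMembership},
#'   \code{injectedErrors}, \code{injectedMissing}, \code{mislabeled}).
#'   Every observed-vs-true discrepancy appears in exactly one of the
#'   two injection logs.
#' @export
simulateCollection <- function(config = simConfig()) {
    stopifnot(inherits(config, "simConfig"))
    set.seed(config$seed)
    m <- config$nMarkers
    nf <- config$nFounders
    maf <- runif(m, config$mafRange[1L], config$mafRange[2L])
    markerIds <- sprintf("M%02d", seq_len(m))
    pairPool <- combn(c("A", "C", "G", "T"), 2L)
    pairPick <- pairPool[, sample.int(ncol(pairPool), m, replace = TRUE),
                         drop = FALSE]
    mInfo <- DataFrame(marker_id = markerIds,
                       chromosome = sprintf("chr%02d",
                                            rep_len(1:17, m)[sample.int(m)]),
                       allele_x = pairPick[1L, ], allele_y = pairPick[2L, ])
    # founders: HW proportions, code = copies of allele Y at frequency maf
    founders <- vapply(seq_len(m), function(k)
        sample(0:2, nf, replace = TRUE,
               prob = c((1 - maf[k])^2, 2 * maf[k] * (1 - maf[k]),
                        maf[k]^2)),
        integer(nf))            # founders x markers
    founders <- matrix(as.integer(founders), nf, m)
    triploid <- runif(nf) < config$triploidFraction
    if (config$hetInflation > 0 && any(triploid)) {
        for (f in which(triploid)) {
            hom <- founders[f, ] != 1L
            shift <- hom & runif(m) < config$hetInflation
            founders[f, shift] <- 1L
        }
    }
    sizes <- config$cloneGroupSizes[
        sample.int(length(config$cloneGroupSizes), nf, replace = TRUE)]
    founderOf <- rep(seq_len(nf), sizes)
    n <- length(founderOf)
    true <- t(founders[founderOf, , drop = FALSE])   # markers x samples
    sampleIds <- sprintf("S%04d", seq_len(n))
    dimnames(true) <- list(markerIds, sampleIds)
    # sport mutations: genuine somatic changes on clone copies
    if (config$sportMutationRate > 0) {
        mut <- matrix(runif(m * n) < config$sportMutationRate, m, n)
        idx <- which(mut)
        for (ii in idx)
            true[ii] <- sample(setdiff(0:2, true[ii]), 1L)
    }
    variety <- sprintf("V%04d", founderOf)
    labels <- variety
    mislabeled <- character()
    if (config$mislabelRate > 0 && nf > 1L) {
        hit <- which(runif(n) < config$mislabelRate)
        for (i in hit) {
            other <- sample(setdiff(seq_len(nf), founderOf[i]), 1L)
            labels[i] <- sprintf("V%04d", other)
        }
        mislabeled <- sampleIds[hit]
    }
    sInfo <- DataFrame(sample_id = sampleIds,
                       variety_name = variety,
                       replicate_label = labels,
                       ploidy = ifelse(triploid[founderOf], 3L, 2L))
    trueGM <- GenotypeMatrix(true, markerInfo = mInfo, sampleInfo = sInfo)
    inj <- injectErrors(trueGM, miscallRate = config$miscallRate,
                        missingRate = config$missingRate, seed = NULL)
    list(observed = inj$matrix,
         truth = list(trueGenotypes = trueGM,
                      cloneMembership = setNames(variety, sampleIds),
                      injectedErrors = inj$errors,
                      injectedMissing = inj$missing,
                      mislabeled = mislabeled))
}

#' Inject miscalls and no-calls into a genotype matrix
#'
#' Each called cell independently flips to a uniformly chosen different
#' called state with probability \code{miscallRate}, then (flipped or
#' not) becomes missing with probability \code{missingRate}.  Every
#' change is logged.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param miscallRate,missingRate per-call probabilities in [0, 1].
#' @param seed optional integer seed (\code{NULL} uses the current RNG
#'   stream).
#' @return list with \code{matrix} (the perturbed
#'   \linkS4class{GenotypeMatrix}), \code{errors} (data.frame: sample,
#'   marker, original, observed codes) and \code{missing} (data.frame:
#'   sample, marker, original).
#' @export
injectErrors <- function(x, miscallRate = 0, missingRate = 0, seed = NULL) {
    stopifnot(miscallRate >= 0, miscallRate <= 1,
              missingRate >= 0, missingRate <= 1)
    if (!is.null(seed))
        set.seed(seed)
    cl <- genotypeCalls(x)
    called <- which(!is.na(cl))
    flip <- called[runif(length(called)) < miscallRate]
    errLog <- data.frame(sample = character(), marker = character(),
                         original = integer(), observed = integer())
    if (length(flip)) {
        orig <- cl[flip]
        newv <- vapply(orig, function(s) sample(setdiff(0:2, s), 1L), 0L)
        cl[flip] <- newv
        pos <- arrayInd(flip, dim(cl))
        errLog <- data.frame(sample = colnames(cl)[pos[, 2L]],
                             marker = rownames(cl)[pos[, 1L]],
                             original = as.integer(orig),
                             observed = as.integer(newv))
    }
    calledNow <- which(!is.na(cl))
    gone <- calledNow[runif(length(calledNow)) < missingRate]
    misLog <- data.frame(sample = character(), marker = character(),
                         original = integer())
    if (length(gone)) {
        pos <- arrayInd(gone, dim(cl))
        misLog <- data.frame(sample = colnames(cl)[pos[, 2L]],
                             marker = rownames(cl)[pos[, 1L]],
                             original = as.integer(cl[gone]))
        cl[gone] <- NA_integer_
    }
    # a flipped call that then fails is a no-call, not an observed error
    if (nrow(errLog) && nrow(misLog)) {
        k <- paste(errLog$sample, errLog$marker) %in%
            paste(misLog$sample, misLog$marker)
        if (any(k)) {
            misLog$original[match(
                paste(errLog$sample[k], errLog$marker[k]),
                paste(misLog$sample, misLog$marker))] <-
                errLog$original[k]
            errLog <- errLog[!k, , drop = FALSE]
        }
    }
    out <- x
    SummarizedExperiment::assay(out, "calls") <- cl
    list(matrix = out, errors = errLog, missing = misLog)
}
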