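# Unique (individual, haplotype) incidence pairs of a library: an individual
# carrying the same haplotype on both gametes counts it once per window.
.incidencePairs <- function(library) {
    nInd <- length(library@eligibleIds)
    W <- ncol(library@hapAssign)
    ind <- rep(rep(seq_len(nInd), each = 2L), times = W)
    hap <- as.vector(library@hapAssign)
    ok <- !is.na(hap)
    unique(data.frame(ind = ind[ok], hap = hap[ok]))
}

#' Marginal haplotype-coverage score of a candidate
#'
#' The score of an individual is the summed population copy count of the
#' distinct unmasked haplotypes it carries across all windows.  A haplotype
#' carried on both gametes contributes its population mass once.
#'
#' @param individual id of an eligible individual.
#' @param library a \linkS4class{HaplotypeLibrary}.
#' @param maskedHaps integer vector of masked global haplotype ids.
#' @return numeric covered copy count.
#' @examples
#' a <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 1L), c(1L, 1L))
#' lib <- buildHaplotypeLibrary(PhasedPanel(c("i1", "i2"), a), windowLength = 2)
#' candidateScore("i1", lib)
#' @export
candidateScore <- function(individual, library, maskedHaps = integer(0)) {
    i <- match(individual, library@eligibleIds)
    if (is.na(i))
        stop("unknown or ineligible individual: ", individual)
    haps <- unique(stats::na.omit(as.vector(
        library@hapAssign[c(2L * i - 1L, 2L * i), , drop = FALSE])))
    haps <- setdiff(haps, maskedHaps)
    sum(library@counts[haps])
}

#' Greedy selection and ranking of focal individuals
#'
#' Iteratively selects the individual with the highest marginal
#' haplotype-coverage score (ties broken by smallest id), masks every
#' haplotype it carries, and repeats, so that successive picks cover
#' haplotype mass not yet captured by earlier picks.  Selection stops after
#' \code{k} picks or when the best remaining marginal score is zero, at which
#' point all population haplotypes are covered.
#'
#' Individuals in \code{alreadySequenced} have their haplotypes pre-masked
#' (their diversity is already captured) and are not candidates; individuals
#' in \code{doNotSequence} are excluded as candidates but their haplotype
#' copies still count towards the scores of others.
#'
#' @param library a \linkS4class{HaplotypeLibrary}.
#' @param k maximum number of focal individuals; truncated with a warning
#'   when it exceeds the number of candidates.
#' @param alreadySequenced,doNotSequence optional character id vectors.
#' @return A \linkS4class{FocalRanking}.
#' @examples
#' a <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 1L), c(1L, 1L))
#' lib <- buildHaplotypeLibrary(PhasedPanel(c("i1", "i2"), a), windowLength = 2)
#' asTable(selectFocalIndividuals(lib, k = 2))
#' @export
selectFocalIndividuals <- function(library, k, alreadySequenced = character(0),
                                   doNotSequence = character(0)) {
    stopifnot(k >= 1)
    pairs <- .incidencePairs(library)
    nInd <- length(library@eligibleIds)
    nHap <- length(library@counts)
    counts <- as.numeric(library@counts)
    masked <- logical(nHap)
    # rows of `pairs` grouped by haplotype for fast mask updates
    rowsOfHap <- split(seq_len(nrow(pairs)), factor(pairs$hap,
                                                    levels = seq_len(nHap)))
    scores <- numeric(nInd)   # individuals with no complete window score 0
    agg <- rowsum(counts[pairs$hap], pairs$ind)
    scores[as.integer(rownames(agg))] <- agg[, 1L]
    hapsOfInd <- split(pairs$hap, factor(pairs$ind, levels = seq_len(nInd)))

    maskHapsOf <- function(i) {
        newHaps <- hapsOfInd[[i]]
        newHaps <- newHaps[!masked[newHaps]]
        if (!length(newHaps)) return(invisible())
        masked[newHaps] <<- TRUE
        touched <- unlist(rowsOfHap[newHaps], use.names = FALSE)
        dec <- rowsum(counts[pairs$hap[touched]], pairs$ind[touched])
        scores[as.integer(rownames(dec))] <<-
            scores[as.integer(rownames(dec))] - dec[, 1L]
        invisible()
    }

    candidate <- rep(TRUE, nInd)
    for (id in alreadySequenced) {
        i <- match(id, library@eligibleIds)
        if (is.na(i)) next
        maskHapsOf(i)
        candidate[i] <- FALSE
    }
    candidate[match(intersect(doNotSequence, library@eligibleIds),
                    library@eligibleIds)] <- FALSE

    nCand <- sum(candidate)
    if (k > nCand) {
        warning(sprintf("k = %d exceeds the %d available candidates; truncating",
                        k, nCand))
        k <- nCand
    }
    tieRank <- idRank(library@eligibleIds)
    pickId <- character(0); pickScore <- numeric(0)
    for (step in seq_len(k)) {
        avail <- which(candidate)
        top <- max(scores[avail])
        if (top <= 0) break
        cand <- avail[scores[avail] == top]
        winner <- cand[which.min(tieRank[cand])]
        pickId <- c(pickId, library@eligibleIds[winner])
        pickScore <- c(pickScore, scores[winner])
        maskHapsOf(winner)
        candidate[winner] <- FALSE
    }
    marginalProp <- pickScore / library@totalCopies
    new("FocalRanking", ids = pickId, marginalCopies = pickScore,
        marginalProportion = marginalProp,
        cumulativeProportion = cumsum(marginalProp),
        totalCopies = library@totalCopies)
}

#' Cumulative haplotype-coverage curve of a ranking
#'
#' @param ranking a \linkS4class{FocalRanking}.
#' @param file optional path; when given, the curve is written as CSV.
#' @return data.frame with columns \code{rank} and
#'   \code{cumulativeProportion} (monotone non-decreasing).
#' @export
coverageCurve <- function(ranking, file = NULL) {
    stopifnot(length(ranking@ids) > 0)
    out <- data.frame(rank = seq_along(ranking@ids),
                      cumulativeProportion = ranking@cumulativeProportion)
    if (!is.null(file))
        utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
    out
}
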