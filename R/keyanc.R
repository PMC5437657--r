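# Gene-origin avoidance probabilities.  For each candidate j, column j holds
# v[x] = P(the lineage of a random gene of x passes through neither any
# individual in `blocked` nor candidate j anywhere on its path).  Founder
# genes (and genes entering through unknown parents) avoid everything by
# definition.  Computed in one pass down the topologically ordered pedigree.
.avoidanceMatrix <- function(pedigree, candidateIdx, blocked = integer(0)) {
    n <- length(pedigree@ids)
    m <- length(candidateIdx)
    V <- matrix(1, nrow = n, ncol = m)
    isBlocked <- logical(n)
    isBlocked[blocked] <- TRUE
    colOf <- integer(n)
    colOf[candidateIdx] <- seq_len(m)
    sire <- pedigree@sire; dam <- pedigree@dam
    for (x in seq_len(n)) {
        if (isBlocked[x]) { V[x, ] <- 0; next }
        s <- sire[x]; d <- dam[x]
        if (s > 0L || d > 0L)
            V[x, ] <- 0.5 * (if (s > 0L) V[s, ] else 1) +
                      0.5 * (if (d > 0L) V[d, ] else 1)
        if (colOf[x] > 0L) V[x, colOf[x]] <- 0
    }
    V
}

#' Expected pedigree-inferred contribution of an ancestor
#'
#' The expected proportion of the genes of a reference set that descend from
#' the given ancestor, i.e. the probability that a random reference gene's
#' lineage passes through the ancestor, obtained by passing gene-origin
#' probabilities down the pedigree (each known parent transmits one half).
#' An individual's contribution to itself is 1.
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @param ancestor id of the ancestor.
#' @param reference character ids of the reference individuals.
#' @return numeric proportion in [0, 1].
#' @examples
#' ped <- Pedigree(id = c("s", "d", "o"), sire = c(0, 0, "s"),
#'                 dam = c(0, 0, "d"))
#' expectedContribution(ped, "s", "o")   # 0.5
#' @export
expectedContribution <- function(pedigree, ancestor, reference) {
    a <- match(ancestor, pedigree@ids)
    r <- match(reference, pedigree@ids)
    if (is.na(a)) stop("unknown ancestor: ", ancestor)
    if (anyNA(r)) stop("unknown reference individuals: ",
                       paste(reference[is.na(r)], collapse = ", "))
    V <- .avoidanceMatrix(pedigree, a)
    mean(1 - V[r, 1L])
}

#' Select key ancestors by largest marginal contributions
#'
#' The classical key-ancestors baseline: iteratively picks the individual
#' with the largest marginal pedigree-inferred contribution to the reference
#' set.  The marginal contribution of a candidate is the expected proportion
#' of reference genes whose descent path passes through the candidate but
#' through none of the previously selected ancestors, so successive
#' marginals account for disjoint portions of the reference gene pool and
#' their cumulative sum can never exceed 1.  Ties are broken by smallest id.
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @param reference character ids of the reference set; defaults to the
#'   youngest generation (individuals with the largest generation number, or
#'   individuals that are not parents when generations are unknown).
#' @param k number of ancestors to select.
#' @param candidates optional candidate pool; defaults to all individuals.
#' @return A \linkS4class{ContributionRanking}.
#' @examples
#' ped <- Pedigree(id = c("s", "d", "o1", "o2"), sire = c(0, 0, "s", "s"),
#'                 dam = c(0, 0, "d", "d"))
#' asTable(selectKeyAncestors(ped, reference = c("o1", "o2"), k = 2))
#' @export
selectKeyAncestors <- function(pedigree, reference = NULL, k,
                               candidates = NULL) {
    stopifnot(k >= 1)
    if (is.null(reference)) {
        g <- pedigree@generation
        reference <- if (!all(is.na(g)))
            pedigree@ids[!is.na(g) & g == max(g, na.rm = TRUE)]
        else
            pedigree@ids[!(seq_along(pedigree@ids) %in%
                           c(pedigree@sire, pedigree@dam))]
    }
    r <- match(reference, pedigree@ids)
    if (anyNA(r)) stop("unknown reference individuals")
    if (is.null(candidates)) candidates <- pedigree@ids
    candIdx <- match(candidates, pedigree@ids)
    if (anyNA(candIdx)) stop("unknown candidate individuals")
    k <- min(k, length(candIdx))
    tieRank <- idRank(pedigree@ids)

    n <- length(pedigree@ids)
    sire <- pedigree@sire; dam <- pedigree@dam
    refw <- numeric(n)
    refw[r] <- refw[r] + 1 / length(r)   # reference gene mass per individual

    # The marginal contribution of candidate j given the selected set S is
    # P(a random reference gene's lineage passes j and avoids S everywhere).
    # The path splits at j into the segment below j (reference gene mass u
    # reaching j while avoiding S) and the lineage above j (probability v
    # that j's own gene avoids S), so marginal(j) = u(j) * v(j): two O(n)
    # sweeps per pick instead of one propagation per candidate.
    isSel <- logical(n)
    isCand <- logical(n); isCand[candIdx] <- TRUE
    pickId <- character(0); pickMarg <- numeric(0)
    for (step in seq_len(k)) {
        v <- numeric(n)
        for (x in seq_len(n)) {
            if (isSel[x]) next          # v stays 0: gene already explained
            s <- sire[x]; d <- dam[x]
            v[x] <- if (s == 0L && d == 0L) 1 else
                0.5 * (if (s > 0L) v[s] else 1) +
                0.5 * (if (d > 0L) v[d] else 1)
        }
        u <- refw
        for (x in rev(seq_len(n))) {
            if (isSel[x]) { u[x] <- 0; next }  # paths through S are blocked
            half <- 0.5 * u[x]
            s <- sire[x]; d <- dam[x]
            if (s > 0L) u[s] <- u[s] + half
            if (d > 0L) u[d] <- u[d] + half
        }
        marg <- ifelse(isCand & !isSel, u * v, -Inf)
        top <- max(marg)
        if (top <= 1e-15) break
        best <- which(marg >= top - 1e-15)
        winner <- best[which.min(tieRank[best])]
        pickId <- c(pickId, pedigree@ids[winner])
        pickMarg <- c(pickMarg, marg[winner])
        isSel[winner] <- TRUE
    }
    new("ContributionRanking", ids = pickId, marginal = pickMarg,
        cumulative = cumsum(pickMarg))
}
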