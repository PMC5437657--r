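#' Accessors
#'
#' Small accessor generics shared across the package's classes.
#'
#' @param x an object.
#' @return \code{ids}: character identifiers; \code{nIndividuals},
#'   \code{nMarkers}: integer counts; \code{asTable}: a base data.frame view
#'   of a ranking or pedigree.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ids", function(x) standardGeneric("ids"))

#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname accessors
#' @export
setGeneric("asTable", function(x) standardGeneric("asTable"))

#' @rdname accessors
#' @export
setMethod("ids", "PhasedPanel", function(x) x@ids)

#' @rdname accessors
#' @export
setMethod("ids", "Pedigree", function(x) x@ids)

#' @rdname accessors
#' @export
setMethod("ids", "FocalRanking", function(x) x@ids)

#' @rdname accessors
#' @export
setMethod("ids", "ContributionRanking", function(x) x@ids)

#' @rdname accessors
#' @export
setMethod("nIndividuals", "PhasedPanel", function(x) length(x@ids))

#' @rdname accessors
#' @export
setMethod("nIndividuals", "Pedigree", function(x) length(x@ids))

#' @rdname accessors
#' @export
setMethod("nMarkers", "PhasedPanel", function(x) ncol(x@alleles))

#' @rdname accessors
#' @export
setMethod("asTable", "Pedigree", function(x) {
    data.frame(id = x@ids,
               sire = ifelse(x@sire > 0L, x@ids[pmax(x@sire, 1L)], "0"),
               dam = ifelse(x@dam > 0L, x@ids[pmax(x@dam, 1L)], "0"),
               sex = x@sex, generation = x@generation,
               stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("asTable", "FocalRanking", function(x) {
    data.frame(rank = seq_along(x@ids), id = x@ids,
               marginalCopies = x@marginalCopies,
               marginalProportion = x@marginalProportion,
               cumulativeProportion = x@cumulativeProportion,
               stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("asTable", "ContributionRanking", function(x) {
    data.frame(rank = seq_along(x@ids), id = x@ids,
               marginalContribution = x@marginal,
               cumulativeContribution = x@cumulative,
               stringsAsFactors = FALSE)
})

setMethod("show", "PhasedPanel", function(object) {
    cat(sprintf("PhasedPanel: %d individuals, %d markers on %d chromosome(s)\n",
                length(object@ids), ncol(object@alleles),
                length(unique(object@chr))))
    pf <- mean(!is.na(object@alleles))
    cat(sprintf("  phased fraction (overall): %.3f\n", pf))
})

setMethod("show", "Pedigree", function(object) {
    cat(sprintf("Pedigree: %d records (%d founders)\n", length(object@ids),
                sum(object@sire == 0L & object@dam == 0L)))
})

setMethod("show", "HaplotypeLibrary", function(object) {
    cat(sprintf(paste0("HaplotypeLibrary: %d windows, %d distinct haplotypes, ",
                       "%d copies\n  %d eligible individuals, %d eligible markers\n"),
                nrow(object@windows), length(object@counts),
                as.integer(object@totalCopies), length(object@eligibleIds),
                length(object@eligibleMarkers)))
})

setMethod("show", "FocalRanking", function(object) {
    k <- length(object@ids)
    cat(sprintf("FocalRanking: %d focal individuals, cumulative coverage %.4f\n",
                k, if (k) object@cumulativeProportion[k] else 0))
})

setMethod("show", "ContributionRanking", function(object) {
    k <- length(object@ids)
    cat(sprintf("ContributionRanking: %d ancestors, cumulative contribution %.4f\n",
                k, if (k) object@cumulative[k] else 0))
})

setMethod("show", "AllocationResult", function(object) {
    cat(sprintf(paste0("AllocationResult: %d individuals across %d families\n",
                       "  total cost %.0f GBP (budget %.0f), objective %.4f, %s\n"),
                nrow(object@assignments), nrow(object@families),
                object@totalCost, object@budget, object@objective,
                if (object@feasible) "feasible" else "INFEASIBLE"))
})
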