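#' @import methods
NULL

#' PhasedPanel: phased diploid SNP genotypes
#'
#' Holds a panel of phased diploid genotypes: for each individual, two allele
#' vectors (paternal then maternal) per marker, over the codes 0/1 with
#' \code{NA} for missing or unphased alleles.  Alleles are stored as an
#' integer matrix with two consecutive rows per individual; marker columns are
#' grouped by chromosome.
#'
#' @slot ids character vector of individual identifiers.
#' @slot alleles integer matrix with \code{2 * length(ids)} rows (paternal row
#'   first, maternal row second for each individual) and one column per marker.
#' @slot chr integer vector of chromosome indices, one per marker column.
#' @exportClass PhasedPanel
setClass("PhasedPanel",
         representation(ids = "character", alleles = "matrix", chr = "integer"))

setValidity("PhasedPanel", function(object) {
    msg <- character()
    n <- length(object@ids)
    if (n == 0L)
        msg <- c(msg, "panel must contain at least one individual")
    if (anyDuplicated(object@ids))
        msg <- c(msg, "individual ids must be unique")
    if (nrow(object@alleles) != 2L * n)
        msg <- c(msg, "alleles must have two rows per individual")
    if (length(object@chr) != ncol(object@alleles))
        msg <- c(msg, "chr must have one entry per marker column")
    a <- object@alleles
    if (!all(a[!is.na(a)] %in% c(0L, 1L)))
        msg <- c(msg, "alleles must be 0, 1 or NA")
    if (is.unsorted(object@chr))
        msg <- c(msg, "marker columns must be grouped by chromosome")
    if (length(msg)) msg else TRUE
})

#' Construct a PhasedPanel
#'
#' @param ids character vector of individual identifiers.
#' @param alleles integer matrix, two consecutive rows (paternal, maternal)
#'   per individual, values in \{0, 1, NA\}.
#' @param chr chromosome index per marker column; defaults to a single
#'   chromosome.
#' @return A \linkS4class{PhasedPanel}.
#' @examples
#' a <- rbind(c(0L, 1L), c(1L, 1L))
#' PhasedPanel("ind1", a)
#' @export
PhasedPanel <- function(ids, alleles, chr = rep(1L, ncol(alleles))) {
    storage.mode(alleles) <- "integer"
    new("PhasedPanel", ids = as.character(ids), alleles = alleles,
        chr = as.integer(chr))
}

#' Pedigree with topologically ordered records
#'
#' Records are stored in an order where every known parent precedes its
#' offspring.  Parents are stored as integer indices into the record list,
#' with 0 denoting an unknown parent.  Sex is coded 1 = male, 2 = female,
#' NA = unknown; generation may be NA when not known.
#'
#' @slot ids character identifiers, unique.
#' @slot sire,dam integer parent indices (0 = unknown).
#' @slot sex integer, 1 male / 2 female / NA.
#' @slot generation integer generation number (founders = 0) or NA.
#' @exportClass Pedigree
setClass("Pedigree",
         representation(ids = "character", sire = "integer", dam = "integer",
                        sex = "integer", generation = "integer"))

setValidity("Pedigree", function(object) {
    msg <- character()
    n <- length(object@ids)
    if (anyDuplicated(object@ids))
        msg <- c(msg, "pedigree ids must be unique")
    for (slot in c("sire", "dam", "sex", "generation"))
        if (length(methods::slot(object, slot)) != n)
            msg <- c(msg, sprintf("%s must have one entry per record", slot))
    idx <- seq_len(n)
    if (any(object@sire >= idx | object@dam >= idx, na.rm = TRUE))
        msg <- c(msg, "parents must precede offspring in record order")
    if (any(object@sire < 0L | object@dam < 0L, na.rm = TRUE))
        msg <- c(msg, "parent indices must be >= 0")
    s <- object@sire[object@sire > 0L]
    if (any(!is.na(object@sex[s]) & object@sex[s] != 1L))
        msg <- c(msg, "sires must be male where sex is known")
    d <- object@dam[object@dam > 0L]
    if (any(!is.na(object@sex[d]) & object@sex[d] != 2L))
        msg <- c(msg, "dams must be female where sex is known")
    if (length(msg)) msg else TRUE
})

#' Construct a Pedigree from parent identifiers
#'
#' Records may be given in any order; they are topologically sorted so that
#' parents precede offspring.  A cycle (an individual that is its own
#' ancestor) is an error.
#'
#' @param id,sire,dam vectors of identifiers; "0", 0 or NA denote an unknown
#'   parent.
#' @param sex optional, 1/"M" male, 2/"F" female.
#' @param generation optional integer generation numbers.
#' @return A \linkS4class{Pedigree}.
#' @examples
#' Pedigree(id = c("s", "d", "o"), sire = c(0, 0, "s"), dam = c(0, 0, "d"))
#' @export
Pedigree <- function(id, sire, dam, sex = NULL, generation = NULL) {
    id <- as.character(id)
    norm <- function(x) {
        x <- as.character(x)
        x[is.na(x) | x %in% c("0", "")] <- NA_character_
        x
    }
    sire <- norm(sire); dam <- norm(dam)
    if (!is.null(sex)) {
        sex <- toupper(as.character(sex))
        sex <- ifelse(sex %in% c("1", "M"), 1L,
                      ifelse(sex %in% c("2", "F"), 2L, NA_integer_))
    } else sex <- rep(NA_integer_, length(id))
    if (is.null(generation)) generation <- rep(NA_integer_, length(id))
    ord <- .topoOrder(id, sire, dam)
    id <- id[ord]; sire <- sire[ord]; dam <- dam[ord]
    sex <- sex[ord]; generation <- as.integer(generation)[ord]
    si <- match(sire, id); si[is.na(si)] <- 0L
    di <- match(dam, id); di[is.na(di)] <- 0L
    new("Pedigree", ids = id, sire = si, dam = di, sex = sex,
        generation = generation)
}

# Kahn topological sort over the parent relation; detects cycles.
.topoOrder <- function(id, sire, dam) {
    n <- length(id)
    si <- match(sire, id); di <- match(dam, id)
    indeg <- (!is.na(si)) + (!is.na(di))
    children <- vector("list", n)
    for (i in seq_len(n)) {
        for (p in c(si[i], di[i]))
            if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
    queue <- which(indeg == 0L)
    ord <- integer(0)
    while (length(queue)) {
        x <- queue[1L]; queue <- queue[-1L]
        ord <- c(ord, x)
        for (ch in children[[x]]) {
            indeg[ch] <- indeg[ch] - 1L
            if (indeg[ch] == 0L) queue <- c(queue, ch)
        }
    }
    if (length(ord) != n)
        stop("pedigree contains a cycle: an individual is its own ancestor")
    ord
}

#' Windowed population haplotype library
#'
#' For consecutive fixed-length marker windows, the distinct haplotype strings
#' (restricted to eligible markers, matched at 100% identity) observed among
#' eligible individuals, their population copy counts, and the per-gamete
#' haplotype assignments.
#'
#' @slot windows data.frame with columns \code{chr}, \code{start} (0-based
#'   within-chromosome marker index) and \code{length}.
#' @slot hapAssign integer matrix, one row per gamete of each eligible
#'   individual (2 consecutive rows per individual) and one column per window;
#'   entries are global haplotype ids, NA where the gamete has missing data in
#'   the window.
#' @slot counts integer copy count per global haplotype id.
#' @slot windowOfHap integer window index per global haplotype id.
#' @slot hapKeys character allele strings per global haplotype id.
#' @slot eligibleIds character ids of eligible individuals (row blocks of
#'   \code{hapAssign}).
#' @slot eligibleMarkers integer global marker column indices retained by the
#'   phased-fraction filter.
#' @slot totalCopies numeric, total haplotype copies in the library.
#' @exportClass HaplotypeLibrary
setClass("HaplotypeLibrary",
         representation(windows = "data.frame", hapAssign = "matrix",
                        counts = "integer", windowOfHap = "integer",
                        hapKeys = "character", eligibleIds = "character",
                        eligibleMarkers = "integer", totalCopies = "numeric"))

setValidity("HaplotypeLibrary", function(object) {
    msg <- character()
    if (nrow(object@hapAssign) != 2L * length(object@eligibleIds))
        msg <- c(msg, "hapAssign must have two rows per eligible individual")
    if (ncol(object@hapAssign) != nrow(object@windows))
        msg <- c(msg, "hapAssign must have one column per window")
    if (length(object@counts) != length(object@windowOfHap))
        msg <- c(msg, "counts and windowOfHap must align")
    # copy-count conservation: per window, counts sum to complete gametes
    for (w in seq_len(ncol(object@hapAssign))) {
        h <- object@hapAssign[, w]
        nw <- sum(object@counts[object@windowOfHap == w])
        if (nw != sum(!is.na(h)))
            msg <- c(msg, sprintf(
                "window %d: copy counts (%d) != complete gametes (%d)",
                w, nw, sum(!is.na(h))))
    }
    if (!isTRUE(all.equal(object@totalCopies, sum(object@counts))))
        msg <- c(msg, "totalCopies must equal sum of counts")
    if (length(msg)) msg else TRUE
})

#' Ranking of focal individuals by marginal haplotype coverage
#'
#' @slot ids character, selected focal individuals in pick order.
#' @slot marginalCopies numeric, haplotype copies newly covered by each pick.
#' @slot marginalProportion numeric, the same as a proportion of total copies.
#' @slot cumulativeProportion numeric, running coverage of the library.
#' @slot totalCopies numeric, reference total of the library.
#' @exportClass FocalRanking
setClass("FocalRanking",
         representation(ids = "character", marginalCopies = "numeric",
                        marginalProportion = "numeric",
                        cumulativeProportion = "numeric",
                        totalCopies = "numeric"))

setValidity("FocalRanking", function(object) {
    msg <- character()
    k <- length(object@ids)
    if (length(object@marginalCopies) != k ||
        length(object@marginalProportion) != k ||
        length(object@cumulativeProportion) != k)
        msg <- c(msg, "ranking slots must have equal length")
    if (k > 1 && any(diff(object@cumulativeProportion) < -1e-12))
        msg <- c(msg, "cumulative proportion must be non-decreasing")
    if (k > 1 && any(diff(object@marginalCopies) > 1e-9))
        msg <- c(msg, paste("marginal scores must be non-increasing",
                            "(greedy weighted coverage is submodular)"))
    p <- c(object@marginalProportion, object@cumulativeProportion)
    if (any(p < -1e-12 | p > 1 + 1e-12))
        msg <- c(msg, "proportions must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Ranking of key ancestors by marginal genetic contribution
#'
#' @slot ids character, ancestors in pick order.
#' @slot marginal numeric marginal contribution (proportion of reference
#'   genes not explained by earlier picks).
#' @slot cumulative numeric running sum of marginals.
#' @exportClass ContributionRanking
setClass("ContributionRanking",
         representation(ids = "character", marginal = "numeric",
                        cumulative = "numeric"))

setValidity("ContributionRanking", function(object) {
    msg <- character()
    if (any(object@marginal < -1e-9 | object@marginal > 1 + 1e-9))
        msg <- c(msg, "marginal contributions must lie in [0, 1]")
    if (length(object@cumulative) &&
        max(object@cumulative) > 1 + 1e-9)
        msg <- c(msg, "cumulative contribution cannot exceed 1")
    if (length(msg)) msg else TRUE
})

#' Sequencing cost model
#'
#' @slot libraryCost cost (GBP) of preparing one new DNA library.
#' @slot perXCost cost (GBP) of one 1x unit of sequencing.
#' @exportClass CostModel
setClass("CostModel",
         representation(libraryCost = "numeric", perXCost = "numeric"))

setValidity("CostModel", function(object) {
    if (object@libraryCost < 0 || object@perXCost < 0)
        "costs must be non-negative" else TRUE
})

#' Construct a CostModel
#'
#' Defaults follow a typical short-read pricing structure: GBP 40 per DNA
#' library and GBP 85 per 1x of sequencing.
#'
#' @param libraryCost cost of a new DNA library (GBP).
#' @param perXCost cost per 1x sequencing coverage (GBP).
#' @return A \linkS4class{CostModel}.
#' @examples
#' CostModel()         # 40 + 85 GBP
#' @export
CostModel <- function(libraryCost = 40, perXCost = 85) {
    new("CostModel", libraryCost = libraryCost, perXCost = perXCost)
}

#' Differential evolution settings for budget allocation
#'
#' @slot popSize number of candidate solutions.
#' @slot F mutation factor.
#' @slot CR crossover rate.
#' @slot nRounds number of rounds.
#' @slot lambda penalty weight on relative budget overrun.
#' @slot temperature softmax temperature for stochastic scenario sampling
#'   during the search (0 = deterministic argmax decoding).
#' @slot seed optional integer seed.
#' @exportClass DEConfig
setClass("DEConfig",
         representation(popSize = "integer", F = "numeric", CR = "numeric",
                        nRounds = "integer", lambda = "numeric",
                        temperature = "numeric", seed = "integer"))

setValidity("DEConfig", function(object) {
    msg <- character()
    if (object@nRounds < 1L) msg <- c(msg, "nRounds must be >= 1")
    if (object@popSize < 4L) msg <- c(msg, "popSize must be >= 4")
    if (object@F <= 0 || object@F > 2) msg <- c(msg, "F must be in (0, 2]")
    if (object@CR <= 0 || object@CR > 1) msg <- c(msg, "CR must be in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Construct differential evolution settings
#'
#' Defaults are standard rand/1/bin settings: 50 candidates, F = 0.8,
#' CR = 0.9, 10,000 rounds.
#'
#' @param popSize,F,CR,nRounds,lambda,temperature,seed see
#'   \linkS4class{DEConfig}.
#' @return A \linkS4class{DEConfig}.
#' @export
DEConfig <- function(popSize = 50, F = 0.8, CR = 0.9, nRounds = 10000,
                     lambda = 10, temperature = 1, seed = NULL) {
    new("DEConfig", popSize = as.integer(popSize), F = F, CR = CR,
        nRounds = as.integer(nRounds), lambda = lambda,
        temperature = temperature,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Result of allocating a sequencing budget across focal families
#'
#' @slot assignments data.frame with one row per distinct individual:
#'   \code{id}, target \code{coverage}, \code{newCoverage} (increment above
#'   prior data) and \code{cost} (GBP).
#' @slot families data.frame with one row per focal family: focal id, member
#'   ids, the family haplotype weight \code{pF}, the expected phasing
#'   accuracy \code{phi} and the member coverages.
#' @slot totalCost numeric (GBP).
#' @slot objective numeric value of the goodness criterion.
#' @slot feasible logical, cost within budget.
#' @slot budget numeric (GBP).
#' @slot trace numeric best objective per round (non-decreasing).
#' @exportClass AllocationResult
setClass("AllocationResult",
         representation(assignments = "data.frame", families = "data.frame",
                        totalCost = "numeric", objective = "numeric",
                        feasible = "logical", budget = "numeric",
                        trace = "numeric"))

#' Simulation settings for synthetic populations
#'
#' Defaults reproduce the structure of a typical intensively selected
#' livestock nucleus: 10 chromosomes of 1 Morgan with 1000 SNPs each, 1000
#' base haplotypes, discrete generations of 1000 individuals with an equal
#' sex ratio, the 25 highest-TBV males truncation-selected as sires, all 500
#' females used as dams, and a polygenic trait with 10,000 additive QTN.
#'
#' @param nChromosomes,nSnpsPerChr,nBaseHaplotypes,nGenerations counts.
#' @param nPerGeneration individuals per discrete generation.
#' @param nSiresSelected males truncation-selected on TBV each generation.
#' @param nDams females used as dams each generation (unselected).
#' @param nQtn number of QTN, distributed equally across chromosomes.
#' @param chrLengthMorgans genetic length per chromosome (Morgans).
#' @param nUnrelated population size for the unrelated-population mode.
#' @param freqRange range of base-haplotype marker allele frequencies.
#' @param seed optional integer seed.
#' @return A validated list of class \code{SimConfig}.
#' @examples
#' SimConfig(nGenerations = 5, nPerGeneration = 100, nSiresSelected = 5,
#'           nDams = 50, nChromosomes = 2, nSnpsPerChr = 100, nQtn = 100)
#' @export
SimConfig <- function(nChromosomes = 10, nSnpsPerChr = 1000,
                      nBaseHaplotypes = 1000, nGenerations = 0,
                      nPerGeneration = 1000, nSiresSelected = 25,
                      nDams = 500, nQtn = 10000, chrLengthMorgans = 1,
                      nUnrelated = 0, freqRange = c(0.05, 0.95),
                      seed = NULL) {
    cfg <- list(nChromosomes = as.integer(nChromosomes),
                nSnpsPerChr = as.integer(nSnpsPerChr),
                nBaseHaplotypes = as.integer(nBaseHaplotypes),
                nGenerations = as.integer(nGenerations),
                nPerGeneration = as.integer(nPerGeneration),
                nSiresSelected = as.integer(nSiresSelected),
                nDams = as.integer(nDams),
                nQtn = as.integer(nQtn),
                chrLengthMorgans = as.numeric(chrLengthMorgans),
                nUnrelated = as.integer(nUnrelated),
                freqRange = as.numeric(freqRange),
                seed = if (is.null(seed)) NULL else as.integer(seed))
    with(cfg, {
        stopifnot(nChromosomes >= 1, nSnpsPerChr >= 1, nBaseHaplotypes >= 2,
                  nPerGeneration >= 1, nSiresSelected >= 1, nDams >= 1,
                  chrLengthMorgans > 0, nQtn >= 1)
        if (nSiresSelected > nPerGeneration / 2)
            stop("nSiresSelected cannot exceed the number of males per generation")
        if (nQtn %% nChromosomes != 0L)
            stop("nQtn must be divisible by nChromosomes ",
                 "(QTN are distributed equally across chromosomes)")
    })
    structure(cfg, class = "SimConfig")
}
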