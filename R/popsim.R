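#' Simulate base haplotypes
#'
#' Generates a set of binary base haplotypes per chromosome from which
#' synthetic populations are founded.  Marker allele frequencies are drawn
#' from a uniform distribution on \code{config$freqRange} and alleles are then
#' sampled independently per haplotype; any marker that comes out monomorphic
#' among the base haplotypes is resampled so that every marker segregates.
#' This is a deliberately simple neutral stand-in for a coalescent history:
#' the downstream selection and allocation machinery consumes only phased SNP
#' panels and does not depend on coalescent fine structure (see the package
#' vignette).
#'
#' @param config a \code{\link{SimConfig}}.
#' @return A list of class \code{BaseHaplotypes} with elements
#'   \code{haplotypes} (per chromosome, an \code{nBaseHaplotypes x
#'   nSnpsPerChr} integer matrix of 0/1 alleles) and \code{config}.
#' @examples
#' base <- simulateBaseHaplotypes(SimConfig(nChromosomes = 1,
#'     nSnpsPerChr = 20, nBaseHaplotypes = 10, nQtn = 5, seed = 1))
#' dim(base$haplotypes[[1]])
#' @export
simulateBaseHaplotypes <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    if (config$nBaseHaplotypes < 2L)
        stop("at least 2 base haplotypes are required for markers to segregate")
    withSeed(config$seed, {
        H <- config$nBaseHaplotypes
        m <- config$nSnpsPerChr
        haps <- lapply(seq_len(config$nChromosomes), function(c) {
            p <- stats::runif(m, config$freqRange[1], config$freqRange[2])
            a <- matrix(stats::rbinom(H * m, 1L, rep(p, each = H)), nrow = H)
            mono <- which(colSums(a) %in% c(0L, H))
            while (length(mono)) {
                p2 <- stats::runif(length(mono), config$freqRange[1],
                                   config$freqRange[2])
                a[, mono] <- stats::rbinom(H * length(mono), 1L,
                                           rep(p2, each = H))
                mono <- mono[colSums(a[, mono, drop = FALSE]) %in% c(0L, H)]
            }
            storage.mode(a) <- "integer"
            a
        })
        structure(list(haplotypes = haps, config = config),
                  class = "BaseHaplotypes")
    })
}

# One meiosis: recombine the parent's two chromosome rows (Haldane model,
# crossovers ~ Poisson(length in Morgans), positions uniform, no interference).
.meiosis <- function(h1, h2, pos, lenM) {
    k <- stats::rpois(1L, lenM)
    if (k == 0L)
        return(if (stats::runif(1) < 0.5) h1 else h2)
    xo <- sort(stats::runif(k, 0, lenM))
    seg <- findInterval(pos, xo)
    first <- stats::runif(1) < 0.5
    use1 <- (seg %% 2L == 0L) == first
    out <- h2
    out[use1] <- h1[use1]
    out
}

#' Simulate a pedigreed population under truncation selection
#'
#' Gene-drops the base haplotypes through discrete generations of
#' \code{nPerGeneration} individuals with an equal sex ratio (sex alternates
#' within each generation).  Founders draw their two chromosomes per
#' chromosome uniformly without replacement from the base haplotypes.  In
#' each later generation the \code{nSiresSelected} males with the highest
#' true breeding value (TBV) are used as sires and \code{nDams} females as
#' dams (unselected); each offspring draws its sire and dam uniformly with
#' replacement and receives one recombinant gamete from each parent
#' (crossovers Poisson with mean \code{chrLengthMorgans}, uniform positions,
#' no interference).  The trait is additive: QTN positions are drawn equally
#' across chromosomes and effects from N(0, 1/nQtn); TBV is the sum of
#' effects times allele dosage.
#'
#' The resulting panel is fully phased by construction (phase is known from
#' transmission).
#'
#' @param config a \code{\link{SimConfig}} with \code{nGenerations >= 1}.
#' @param base result of \code{\link{simulateBaseHaplotypes}}; generated from
#'   \code{config} when NULL.
#' @param selection logical; when FALSE, sires are drawn uniformly from all
#'   males instead of being truncation-selected on TBV (neutral gene
#'   dropping, useful for drift checks).
#' @return list with \code{pedigree} (\linkS4class{Pedigree}),
#'   \code{panel} (\linkS4class{PhasedPanel}) and \code{trait} (list with
#'   \code{qtnCols}, \code{effects} and \code{tbv}).
#' @examples
#' cfg <- SimConfig(nChromosomes = 2, nSnpsPerChr = 50, nBaseHaplotypes = 20,
#'                  nGenerations = 2, nPerGeneration = 20, nSiresSelected = 3,
#'                  nDams = 10, nQtn = 10, seed = 7)
#' pop <- simulatePedigreePopulation(cfg)
#' nIndividuals(pop$pedigree)   # founders + 2 generations
#' @export
simulatePedigreePopulation <- function(config, base = NULL, selection = TRUE) {
    stopifnot(inherits(config, "SimConfig"), config$nGenerations >= 1L)
    if (is.null(base)) base <- simulateBaseHaplotypes(config)
    withSeed(config$seed, .simPedigree(config, base, selection))
}

.simPedigree <- function(config, base, selection = TRUE) {
    nChr <- config$nChromosomes
    m <- config$nSnpsPerChr
    N <- config$nPerGeneration
    G <- config$nGenerations
    H <- config$nBaseHaplotypes
    total <- N * (G + 1L)
    M <- nChr * m
    chrOf <- rep(seq_len(nChr), each = m)
    chrCols <- lapply(seq_len(nChr), function(c) which(chrOf == c))
    pos <- config$chrLengthMorgans * (seq_len(m) - 0.5) / m

    alleles <- matrix(NA_integer_, nrow = 2L * total, ncol = M)
    sire <- integer(total); dam <- integer(total)
    sex <- rep_len(c(1L, 2L), N)          # alternating => exact sex ratio
    sexAll <- rep_len(sex, total)
    generation <- rep(0L:G, each = N)

    # founders: two distinct base haplotypes per individual per chromosome
    for (c in seq_len(nChr)) {
        draws <- vapply(seq_len(N), function(i) sample.int(H, 2L), integer(2))
        alleles[seq_len(2L * N), chrCols[[c]]] <-
            base$haplotypes[[c]][as.vector(draws), ]
    }

    # additive trait
    qtnPerChr <- config$nQtn %/% nChr
    if (qtnPerChr > m)
        stop("nQtn per chromosome exceeds the number of markers")
    qtnCols <- unlist(lapply(chrCols, function(cols)
        sort(sample(cols, qtnPerChr))))
    effects <- stats::rnorm(config$nQtn, 0, sqrt(1 / config$nQtn))
    tbvOf <- function(rows)   # rows = paternal row indices
        as.vector((alleles[rows, qtnCols, drop = FALSE] +
                   alleles[rows + 1L, qtnCols, drop = FALSE]) %*% effects)

    tbv <- numeric(total)
    tbv[seq_len(N)] <- tbvOf(2L * seq_len(N) - 1L)

    for (g in seq_len(G)) {
        prev <- ((g - 1L) * N + 1L):(g * N)
        males <- prev[sexAll[prev] == 1L]
        females <- prev[sexAll[prev] == 2L]
        if (!length(males) || !length(females))
            stop(sprintf("generation %d lacks %s; cannot breed", g - 1L,
                         if (!length(males)) "males" else "females"))
        sires <- if (selection)
            males[order(-tbv[males])][seq_len(min(config$nSiresSelected,
                                                  length(males)))]
        else males[sample.int(length(males),
                              min(config$nSiresSelected, length(males)))]
        dams <- females[seq_len(min(config$nDams, length(females)))]
        cur <- (g * N + 1L):((g + 1L) * N)
        sire[cur] <- sires[sample.int(length(sires), N, replace = TRUE)]
        dam[cur] <- dams[sample.int(length(dams), N, replace = TRUE)]
        for (i in cur) {
            pr <- 2L * i - 1L
            sp <- 2L * sire[i] - 1L
            dp <- 2L * dam[i] - 1L
            for (c in seq_len(nChr)) {
                cols <- chrCols[[c]]
                alleles[pr, cols] <- .meiosis(alleles[sp, cols],
                                              alleles[sp + 1L, cols],
                                              pos, config$chrLengthMorgans)
                alleles[pr + 1L, cols] <- .meiosis(alleles[dp, cols],
                                                   alleles[dp + 1L, cols],
                                                   pos, config$chrLengthMorgans)
            }
        }
        tbv[cur] <- tbvOf(2L * cur - 1L)
    }

    idsAll <- as.character(seq_len(total))
    ped <- new("Pedigree", ids = idsAll, sire = sire, dam = dam,
               sex = sexAll, generation = generation)
    panel <- PhasedPanel(idsAll, alleles, chrOf)
    list(pedigree = ped, panel = panel,
         trait = list(qtnCols = qtnCols, effects = effects, tbv = tbv))
}

#' Simulate an unrelated population
#'
#' Each individual's two chromosomes are drawn independently and uniformly
#' from the base haplotypes; the pedigree has all parents unknown.  This
#' emulates a nominally unrelated collection such as a natural population or
#' a gene bank.
#'
#' @param config a \code{\link{SimConfig}} with \code{nUnrelated >= 1}.
#' @param base result of \code{\link{simulateBaseHaplotypes}}; generated from
#'   \code{config} when NULL.
#' @return list with \code{pedigree} and \code{panel}.
#' @examples
#' cfg <- SimConfig(nChromosomes = 1, nSnpsPerChr = 30, nBaseHaplotypes = 10,
#'                  nQtn = 5, nUnrelated = 8, seed = 3)
#' pop <- simulateUnrelatedPopulation(cfg)
#' @export
simulateUnrelatedPopulation <- function(config, base = NULL) {
    stopifnot(inherits(config, "SimConfig"), config$nUnrelated >= 1L)
    if (is.null(base)) base <- simulateBaseHaplotypes(config)
    withSeed(config$seed, {
        n <- config$nUnrelated
        nChr <- config$nChromosomes
        m <- config$nSnpsPerChr
        H <- config$nBaseHaplotypes
        chrOf <- rep(seq_len(nChr), each = m)
        alleles <- matrix(NA_integer_, nrow = 2L * n, ncol = nChr * m)
        for (c in seq_len(nChr)) {
            rows <- sample.int(H, 2L * n, replace = TRUE)
            alleles[, chrOf == c] <- base$haplotypes[[c]][rows, ]
        }
        idsAll <- as.character(seq_len(n))
        ped <- new("Pedigree", ids = idsAll, sire = integer(n),
                   dam = integer(n), sex = rep_len(c(1L, 2L), n),
                   generation = rep(0L, n))
        list(pedigree = ped, panel = PhasedPanel(idsAll, alleles, chrOf))
    })
}
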