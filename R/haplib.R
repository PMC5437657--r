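#' Per-individual and per-marker phased fractions
#'
#' @param panel a \linkS4class{PhasedPanel}.
#' @param what "individual" or "marker".
#' @param individuals optional subset of ids over which marker fractions are
#'   computed.
#' @return numeric vector of phased fractions in [0, 1].
#' @export
phasedFraction <- function(panel, what = c("individual", "marker"),
                           individuals = NULL) {
    what <- match.arg(what)
    ok <- !is.na(panel@alleles)
    if (what == "individual") {
        odd <- seq(1L, nrow(ok), by = 2L)
        f <- (rowMeans(ok[odd, , drop = FALSE]) +
              rowMeans(ok[odd + 1L, , drop = FALSE])) / 2
        names(f) <- panel@ids
        f
    } else {
        if (!is.null(individuals)) {
            idx <- match(individuals, panel@ids)
            rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
            ok <- ok[rows, , drop = FALSE]
        }
        colMeans(ok)
    }
}

#' Filter individuals and markers on phased-data completeness
#'
#' Retains individuals whose overall phased fraction is at least
#' \code{minPhased}, then markers whose phased fraction across the retained
#' individuals is at least \code{minPhased} (the filter is applied in that
#' order: individuals first, then markers).  The default threshold of 0.9
#' keeps individuals and SNPs with at least 90\% phased genotype data.
#'
#' @param panel a \linkS4class{PhasedPanel}.
#' @param minPhased minimum phased fraction in [0, 1].
#' @return list with \code{individuals} (character ids) and \code{markers}
#'   (integer global marker column indices).
#' @examples
#' a <- rbind(c(0L, 1L), c(1L, NA))
#' filterEligible(PhasedPanel("i1", a), minPhased = 0.5)
#' @export
filterEligible <- function(panel, minPhased = 0.9) {
    stopifnot(minPhased >= 0, minPhased <= 1)
    fInd <- phasedFraction(panel, "individual")
    keepInd <- panel@ids[fInd >= minPhased]
    if (!length(keepInd))
        stop(sprintf("no eligible individuals: 0 of %d have phased fraction >= %g",
                     length(panel@ids), minPhased))
    fMark <- phasedFraction(panel, "marker", individuals = keepInd)
    keepMark <- which(fMark >= minPhased)
    if (!length(keepMark))
        stop(sprintf("no eligible markers: 0 of %d have phased fraction >= %g among %d retained individuals",
                     nMarkers(panel), minPhased, length(keepInd)))
    list(individuals = keepInd, markers = keepMark)
}

#' Tile chromosomes into fixed-length haplotype windows
#'
#' Windows are consecutive, non-overlapping blocks of \code{windowLength}
#' markers anchored at the first marker of each chromosome; a trailing
#' remainder shorter than \code{windowLength} is dropped so that all
#' haplotype strings are comparable at 100\% identity.
#'
#' @param markersPerChr integer vector, number of markers on each chromosome
#'   (names taken as chromosome indices when present).
#' @param windowLength window length in markers (default 250).
#' @return data.frame with columns \code{chr}, \code{start} (0-based
#'   within-chromosome marker index) and \code{length}.
#' @examples
#' buildWindows(c(1000, 1000), 250)   # 4 windows per chromosome
#' @export
buildWindows <- function(markersPerChr, windowLength = 250) {
    stopifnot(windowLength >= 1)
    if (windowLength > max(markersPerChr))
        stop("windowLength exceeds the number of markers on every chromosome")
    chrIdx <- if (!is.null(names(markersPerChr)))
        as.integer(names(markersPerChr)) else seq_along(markersPerChr)
    out <- do.call(rbind, lapply(seq_along(markersPerChr), function(i) {
        nW <- markersPerChr[i] %/% windowLength
        if (nW == 0L) return(NULL)
        data.frame(chr = chrIdx[i],
                   start = (seq_len(nW) - 1L) * windowLength,
                   length = windowLength)
    }))
    rownames(out) <- NULL
    out
}

#' Build the windowed population haplotype library
#'
#' For each window and each gamete of each eligible individual, the allele
#' string over the eligible markers inside the window is matched at 100\%
#' identity against the strings already seen; distinct strings become library
#' haplotypes and every occurrence increments the copy count.  A gamete with
#' any missing allele at an eligible marker inside a window contributes no
#' haplotype for that window (exact identity cannot be certified).
#' Haplotypes that differ at a single marker are distinct library entries.
#'
#' @param panel a \linkS4class{PhasedPanel}.
#' @param windows data.frame from \code{\link{buildWindows}}; computed from
#'   the panel when NULL.
#' @param eligible list from \code{\link{filterEligible}}; computed from the
#'   panel when NULL.
#' @param windowLength,minPhased used only when \code{windows} or
#'   \code{eligible} are NULL.
#' @param verbose report skipped-gamete counts.
#' @return A \linkS4class{HaplotypeLibrary}.
#' @examples
#' a <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 0L), c(0L, 0L))
#' lib <- buildHaplotypeLibrary(PhasedPanel(c("i1", "i2"), a),
#'                              windowLength = 2)
#' lib@counts   # one haplotype, 4 copies
#' @export
buildHaplotypeLibrary <- function(panel, windows = NULL, eligible = NULL,
                                  windowLength = 250, minPhased = 0.9,
                                  verbose = FALSE) {
    if (is.null(eligible))
        eligible <- filterEligible(panel, minPhased)
    if (is.null(windows)) {
        mpc <- table(panel@chr)
        windows <- buildWindows(stats::setNames(as.integer(mpc), names(mpc)),
                                windowLength)
    }
    stopifnot(length(eligible$individuals) > 0, length(eligible$markers) > 0)
    idx <- match(eligible$individuals, panel@ids)
    rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    nG <- length(rows)

    # global column index of the first marker of each chromosome
    chrStart <- c(0L, cumsum(as.integer(table(panel@chr))))
    chrLevels <- sort(unique(panel@chr))

    hapAssign <- matrix(NA_integer_, nrow = nG, ncol = nrow(windows))
    counts <- integer(0); windowOfHap <- integer(0); hapKeys <- character(0)
    keep <- logical(nrow(windows))
    nSkipped <- 0L
    for (w in seq_len(nrow(windows))) {
        ci <- match(windows$chr[w], chrLevels)
        cols <- chrStart[ci] + windows$start[w] + seq_len(windows$length[w])
        cols <- intersect(cols, eligible$markers)
        if (!length(cols)) next
        A <- panel@alleles[rows, cols, drop = FALSE]
        complete <- rowSums(is.na(A)) == 0L
        nSkipped <- nSkipped + sum(!complete)
        if (!any(complete)) next
        keys <- rep(NA_character_, nG)
        keys[complete] <- do.call(paste0,
                                  as.data.frame(A[complete, , drop = FALSE]))
        f <- factor(keys)
        offset <- length(counts)
        hapAssign[, w] <- offset + as.integer(f)
        counts <- c(counts, as.integer(table(f)))
        windowOfHap <- c(windowOfHap, rep(w, nlevels(f)))
        hapKeys <- c(hapKeys, levels(f))
        keep[w] <- TRUE
    }
    if (!all(keep)) {
        # windows with no eligible markers or no complete gamete are dropped
        old <- which(keep)
        hapAssign <- hapAssign[, keep, drop = FALSE]
        windowOfHap <- match(windowOfHap, old)
        windows <- windows[keep, , drop = FALSE]
        rownames(windows) <- NULL
    }
    if (verbose)
        message(sprintf("haplotype library: %d windows, %d haplotypes, %d skipped gametes",
                        nrow(windows), length(counts), nSkipped))
    new("HaplotypeLibrary", windows = windows, hapAssign = hapAssign,
        counts = counts, windowOfHap = windowOfHap, hapKeys = hapKeys,
        eligibleIds = eligible$individuals,
        eligibleMarkers = as.integer(eligible$markers),
        totalCopies = as.numeric(sum(counts)))
}

#' Haplotype coverage of a set of individuals
#'
#' The proportion of all haplotype copies in the library whose haplotype is
#' carried by at least one individual of the set (the quantity a sequencing
#' campaign on that set would capture).
#'
#' @param library a \linkS4class{HaplotypeLibrary}.
#' @param individuals character ids (must be eligible individuals).
#' @return numeric proportion in [0, 1].
#' @export
coverageOfSet <- function(library, individuals) {
    idx <- match(individuals, library@eligibleIds)
    if (anyNA(idx))
        stop("unknown or ineligible individuals: ",
             paste(individuals[is.na(idx)], collapse = ", "))
    rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    haps <- unique(stats::na.omit(as.vector(library@hapAssign[rows, ,
                                                              drop = FALSE])))
    sum(library@counts[haps]) / library@totalCopies
}
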