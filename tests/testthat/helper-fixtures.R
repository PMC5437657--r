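# Small builders and independent brute-force oracles used across the suite.

# Panel from a list of per-individual gamete pairs, e.g.
# makePanel(i1 = c("0011", "0110")) ; "9" = missing.
makePanel <- function(..., chr = NULL) {
    g <- list(...)
    a <- do.call(rbind, lapply(g, function(pair) {
        rbind(as.integer(strsplit(pair[1], "")[[1]]),
              as.integer(strsplit(pair[2], "")[[1]]))
    }))
    a[a == 9L] <- NA_integer_
    PhasedPanel(names(g), a, if (is.null(chr)) rep(1L, ncol(a)) else chr)
}

# Random fully phased panel.
randomPanel <- function(nInd, nMarkers, seed, missingRate = 0) {
    set.seed(seed)
    a <- matrix(sample(0:1, 2 * nInd * nMarkers, replace = TRUE),
                nrow = 2 * nInd)
    if (missingRate > 0)
        a[sample(length(a), round(missingRate * length(a)))] <- NA_integer_
    PhasedPanel(sprintf("i%02d", seq_len(nInd)), a)
}

# Brute-force haplotype counting: per window, tabulate the allele strings of
# all complete gametes.  Completely independent of buildHaplotypeLibrary.
oracleWindowCounts <- function(panel, starts, len, eligibleInds = panel@ids,
                               eligibleMarkers = seq_len(ncol(panel@alleles))) {
    lapply(starts, function(s) {
        cols <- intersect(s + seq_len(len), eligibleMarkers)
        out <- c()
        for (id in eligibleInds) {
            i <- match(id, panel@ids)
            for (r in c(2 * i - 1, 2 * i)) {
                al <- panel@alleles[r, cols]
                if (!anyNA(al))
                    out <- c(out, paste(al, collapse = ""))
            }
        }
        table(out)
    })
}

# Brute-force greedy replay: at each step recompute every candidate's
# marginal (union of its unmasked haplotype strings weighted by population
# copy counts) by direct enumeration over strings.
oracleGreedy <- function(panel, starts, len, k) {
    wins <- lapply(starts, function(s) s + seq_len(len))
    stringsOf <- function(id) {
        i <- match(id, panel@ids)
        unlist(lapply(seq_along(wins), function(w) {
            v <- unique(c(paste(panel@alleles[2 * i - 1, wins[[w]]], collapse = ""),
                          paste(panel@alleles[2 * i, wins[[w]]], collapse = "")))
            paste0("w", w, ":", v)
        }))
    }
    counts <- table(unlist(lapply(panel@ids, function(id) {
        i <- match(id, panel@ids)
        unlist(lapply(seq_along(wins), function(w)
            paste0("w", w, ":",
                   c(paste(panel@alleles[2 * i - 1, wins[[w]]], collapse = ""),
                     paste(panel@alleles[2 * i, wins[[w]]], collapse = "")))))
    })))
    masked <- character(0)
    cand <- panel@ids
    picks <- character(0); marg <- numeric(0)
    for (step in seq_len(k)) {
        sc <- vapply(cand, function(id)
            sum(counts[setdiff(stringsOf(id), masked)]), 0)
        if (max(sc) <= 0) break
        best <- cand[sc == max(sc)][1]   # ids are in increasing order
        picks <- c(picks, best); marg <- c(marg, max(sc))
        masked <- union(masked, stringsOf(best))
        cand <- setdiff(cand, best)
    }
    list(picks = picks, marginal = marg, total = sum(counts))
}

# Monte-Carlo gene-dropping estimate of the expected contribution of one
# ancestor to a reference set: drop genes down the pedigree, flagging genes
# transmitted through the ancestor (the ancestor's own genes are flagged).
geneDropContribution <- function(pedTable, ancestor, reference, nRep = 4000) {
    ids <- pedTable$id
    n <- length(ids)
    si <- match(pedTable$sire, ids); di <- match(pedTable$dam, ids)
    hits <- 0
    for (rep in seq_len(nRep)) {
        flag <- matrix(FALSE, n, 2)
        for (x in seq_len(n)) {
            if (ids[x] == ancestor) { flag[x, ] <- TRUE; next }
            for (side in 1:2) {
                p <- if (side == 1) si[x] else di[x]
                if (!is.na(p))
                    flag[x, side] <- flag[p, sample(1:2, 1)]
            }
        }
        hits <- hits + mean(flag[match(reference, ids), ])
    }
    hits / nRep
}
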