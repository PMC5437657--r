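#' Default sequencing coverage levels
#'
#' The allowed per-individual sequencing coverages: 0, 1, 2, 5, 10 and 20x.
#' @export
DEFAULT_COVERAGES <- c(0, 1, 2, 5, 10, 20)

# normalize prior sequencing info to per-id coverage and library flags
.priorFor <- function(ids, prior) {
    if (is.null(prior))
        return(list(coverage = numeric(length(ids)),
                    hasLibrary = logical(length(ids))))
    stopifnot(all(c("id", "coverage") %in% names(prior)))
    if (is.null(prior$hasLibrary)) prior$hasLibrary <- prior$coverage > 0
    if (any(prior$coverage < 0))
        stop("prior coverage must be non-negative")
    dup <- duplicated(prior$id)
    if (any(dup)) {
        agg <- unique(prior[c("id", "coverage", "hasLibrary")])
        if (anyDuplicated(agg$id))
            stop("conflicting prior-sequencing records for: ",
                 paste(unique(agg$id[duplicated(agg$id)]), collapse = ", "))
        prior <- agg
    }
    i <- match(ids, prior$id)
    list(coverage = ifelse(is.na(i), 0, prior$coverage[i]),
         hasLibrary = ifelse(is.na(i), FALSE, prior$hasLibrary[i]))
}

#' Cost of one sequencing scenario
#'
#' Each member whose target coverage exceeds its prior coverage pays for a
#' new DNA library (unless one already exists) plus the per-1x sequencing
#' cost of the increment; existing sequence data is subtracted.  Members with
#' a target of 0, or a target already met by prior data, incur no cost.
#'
#' @param coverages numeric target coverages (x), one per member.
#' @param costModel a \linkS4class{CostModel}.
#' @param priorCoverage,priorLibrary existing per-member coverage (x) and
#'   library flags; recycled.
#' @return total cost in GBP.
#' @examples
#' scenarioCost(10)                       # 40 + 10 * 85 = 890 GBP
#' scenarioCost(2)                        # 210 GBP
#' scenarioCost(10, priorCoverage = 2, priorLibrary = TRUE)   # 680 GBP
#' @export
scenarioCost <- function(coverages, costModel = CostModel(),
                         priorCoverage = 0, priorLibrary = FALSE) {
    if (any(priorCoverage < 0))
        stop("prior coverage must be non-negative")
    n <- length(coverages)
    pc <- rep_len(priorCoverage, n)
    pl <- rep_len(priorLibrary, n)
    newSeq <- coverages > pc
    sum(newSeq * (costModel@libraryCost * (!pl) +
                  costModel@perXCost * (coverages - pc)))
}

#' Overall cost of coverage assignments across focal families
#'
#' Coverages live on physical individuals: an ancestor shared between
#' families is costed once, at the maximum coverage requested for it across
#' families.
#'
#' @param assignments data.frame with columns \code{id} and \code{coverage};
#'   ids may repeat across families.
#' @param costModel a \linkS4class{CostModel}.
#' @param prior optional data.frame \code{id, coverage, hasLibrary}.
#' @return total cost in GBP.
#' @examples
#' a <- data.frame(id = c("gs", "f1", "gs", "f2"), coverage = c(5, 2, 5, 1))
#' combinationCost(a)    # the shared grandsire "gs" is paid once
#' @export
combinationCost <- function(assignments, costModel = CostModel(),
                            prior = NULL) {
    stopifnot(all(c("id", "coverage") %in% names(assignments)))
    cov <- tapply(assignments$coverage, assignments$id, max)
    ids <- names(cov)
    p <- .priorFor(ids, prior)
    scenarioCost(as.numeric(cov), costModel, p$coverage, p$hasLibrary)
}

#' Number of distinct sequencing scenarios for a family
#'
#' @param nLevels number of allowed coverage levels.
#' @param familySize family members (default 7: focal, parents,
#'   grandparents).
#' @return \code{nLevels ^ familySize}.
#' @examples
#' countScenarios(6)   # 279936
#' @export
countScenarios <- function(nLevels, familySize = 7) {
    stopifnot(nLevels >= 1, familySize >= 1)
    as.numeric(nLevels)^familySize
}

#' Resolve focal families from a ranking and a pedigree
#'
#' A focal family is the focal individual, its sire and dam, and its four
#' grandparents; unknown members are NA.  The family weight \code{pF} is the
#' focal individual's marginal covered proportion from the ranking, i.e. the
#' proportion of population haplotype mass that sequencing this family's
#' focal individual would newly capture.
#'
#' @param ranking a \linkS4class{FocalRanking}.
#' @param pedigree a \linkS4class{Pedigree}.
#' @return data.frame with columns \code{focal}, \code{sire}, \code{dam},
#'   \code{gp1}..\code{gp4} and \code{pF}.
#' @export
focalFamilies <- function(ranking, pedigree) {
    idx <- match(ranking@ids, pedigree@ids)
    if (anyNA(idx))
        stop("focal individuals missing from pedigree: ",
             paste(ranking@ids[is.na(idx)], collapse = ", "))
    idOf <- function(i) ifelse(is.na(i) | i == 0L, NA_character_,
                               pedigree@ids[pmax(i, 1L)])
    parentOf <- function(i, slot) ifelse(i == 0L, 0L,
                                         methods::slot(pedigree, slot)[pmax(i, 1L)])
    s <- pedigree@sire[idx]; d <- pedigree@dam[idx]
    data.frame(focal = ranking@ids,
               sire = idOf(s), dam = idOf(d),
               gp1 = idOf(parentOf(s, "sire")),
               gp2 = idOf(parentOf(s, "dam")),
               gp3 = idOf(parentOf(d, "sire")),
               gp4 = idOf(parentOf(d, "dam")),
               pF = ranking@marginalProportion,
               stringsAsFactors = FALSE)
}

#' Goodness criterion of a coverage assignment
#'
#' The objective maximised by the budget allocator:
#' \deqn{G = \sum_f p_f \phi(scenario_f) - \lambda \max(0, cost - budget)/budget,}
#' the expected proportion of population haplotype mass phased at the
#' sequence level, penalised by the relative budget overrun.  Scenario
#' coverages used for the accuracy are the effective ones (the larger of the
#' target and any prior coverage); the cost charges only the increment.
#'
#' @param coverages named numeric vector of target coverages per individual.
#' @param families data.frame from \code{\link{focalFamilies}}.
#' @param accuracy an accuracy model function (default
#'   \code{\link{defaultAccuracy}}).
#' @param costModel a \linkS4class{CostModel}.
#' @param prior optional prior-sequencing data.frame.
#' @param budget total budget in GBP (> 0).
#' @param lambda penalty weight.
#' @return list with \code{objective}, \code{cost}, \code{phi} (per family)
#'   and \code{phased} (the unpenalised first term).
#' @export
goodness <- function(coverages, families, accuracy = defaultAccuracy,
                     costModel = CostModel(), prior = NULL, budget,
                     lambda = 10) {
    if (budget <= 0) stop("budget must be positive")
    stopifnot(nrow(families) >= 1, !is.null(names(coverages)))
    p <- .priorFor(names(coverages), prior)
    eff <- pmax(coverages, p$coverage)
    memberCols <- c("focal", "sire", "dam", "gp1", "gp2", "gp3", "gp4")
    scen <- sapply(memberCols, function(cn) {
        i <- match(families[[cn]], names(coverages))
        ifelse(is.na(i), 0, eff[pmax(i, 1L)])
    })
    if (is.null(dim(scen))) scen <- matrix(scen, nrow = 1L)
    phi <- .evalAccuracy(accuracy, scen)
    cost <- scenarioCost(as.numeric(coverages), costModel, p$coverage,
                         p$hasLibrary)
    phased <- sum(families$pF * phi)
    list(objective = phased - lambda * max(0, cost - budget) / budget,
         cost = cost, phi = phi, phased = phased)
}

#' Sample a sequencing scenario from logits
#'
#' Per member, coverage-level probabilities are the softmax of that member's
#' logits (divided by \code{temperature}); a coverage is drawn from the
#' resulting multinomial.  As the temperature approaches 0 the draw becomes
#' the deterministic argmax, which is used for final reporting.
#'
#' @param logits numeric matrix, one row per member, one column per coverage
#'   level.
#' @param coverages allowed coverage levels.
#' @param temperature softmax temperature (0 = argmax).
#' @return numeric vector of sampled coverages, one per member.
#' @export
sampleScenario <- function(logits, coverages = DEFAULT_COVERAGES,
                           temperature = 1) {
    stopifnot(is.matrix(logits), ncol(logits) == length(coverages))
    lvl <- .sampleLevels(logits, temperature)
    coverages[lvl]
}

# Draw one level per row of a logits matrix; temperature 0 => argmax.
.sampleLevels <- function(logits, temperature) {
    if (temperature <= 0)
        return(max.col(logits, ties.method = "first"))
    z <- exp((logits - apply(logits, 1L, max)) / temperature)
    pr <- z / rowSums(z)
    u <- stats::runif(nrow(pr))
    lvl <- integer(nrow(pr))
    acc <- numeric(nrow(pr))
    for (l in seq_len(ncol(pr))) {
        acc <- acc + pr[, l]
        lvl[lvl == 0L & u <= acc] <- l
    }
    lvl[lvl == 0L] <- ncol(pr)    # numerical slack
    lvl
}

#' Allocate a fixed sequencing budget across focal families
#'
#' Searches, with a rand/1/bin differential evolution over per-individual
#' coverage-level logits, for the combination of family sequencing scenarios
#' that maximises the \code{\link{goodness}} criterion: the proportion of
#' population haplotype mass expected to be phased at the sequence level,
#' subject to the budget.  Individuals shared between families receive a
#' single coverage and are paid for once.  During the search scenarios are
#' sampled from the softmax probabilities encoded by each candidate solution;
#' an elitist best-so-far solution, re-evaluated with deterministic argmax
#' decoding, is tracked and never lost.  If the final best solution exceeds
#' the budget it is repaired by greedily decrementing the coverage of the
#' member whose reduction loses the least expected phased mass until the
#' cost fits.
#'
#' @param families data.frame from \code{\link{focalFamilies}} (columns
#'   \code{focal}, \code{sire}, \code{dam}, \code{gp1}..\code{gp4},
#'   \code{pF}).
#' @param budget total budget in GBP (> 0).
#' @param costModel a \linkS4class{CostModel}.
#' @param accuracy accuracy model function.
#' @param prior optional data.frame \code{id, coverage, hasLibrary}.
#' @param coverages allowed coverage levels.
#' @param deConfig a \linkS4class{DEConfig}.
#' @return An \linkS4class{AllocationResult}.
#' @examples
#' fam <- data.frame(focal = "x", sire = "s", dam = "d", gp1 = NA, gp2 = NA,
#'                   gp3 = NA, gp4 = NA, pF = 0.2)
#' res <- allocateBudget(fam, budget = 3000,
#'                       deConfig = DEConfig(nRounds = 200, seed = 1))
#' res@totalCost <= 3000
#' @export
allocateBudget <- function(families, budget, costModel = CostModel(),
                           accuracy = defaultAccuracy, prior = NULL,
                           coverages = DEFAULT_COVERAGES,
                           deConfig = DEConfig()) {
    if (budget <= 0) stop("budget must be positive")
    stopifnot(nrow(families) >= 1)
    memberCols <- c("focal", "sire", "dam", "gp1", "gp2", "gp3", "gp4")
    members <- unique(stats::na.omit(unlist(families[memberCols],
                                            use.names = FALSE)))
    nInd <- length(members)
    L <- length(coverages)
    nFam <- nrow(families)
    pF <- families$pF
    # index into members, sentinel nInd + 1 = a padded always-zero column
    memberIdx <- sapply(memberCols, function(cn) {
        i <- match(families[[cn]], members)
        ifelse(is.na(i), nInd + 1L, i)
    })
    if (is.null(dim(memberIdx))) memberIdx <- matrix(memberIdx, nrow = 1L)
    p <- .priorFor(members, prior)

    evalLevels <- function(lvl) {
        # lvl: P x nInd matrix of coverage-level indices
        cov <- matrix(coverages[lvl], nrow = nrow(lvl))
        eff <- sweep(cov, 2L, p$coverage, pmax)
        effPad <- cbind(eff, 0)
        scen <- do.call(cbind, lapply(seq_len(7L), function(s)
            as.vector(effPad[, memberIdx[, s], drop = FALSE])))
        phi <- matrix(.evalAccuracy(accuracy, scen), nrow = nrow(lvl))
        newSeq <- sweep(cov, 2L, p$coverage, ">")
        costPer <- newSeq * (costModel@libraryCost *
                             rep(!p$hasLibrary, each = nrow(cov)) +
                             costModel@perXCost *
                             sweep(cov, 2L, p$coverage, "-"))
        cost <- rowSums(costPer)
        G <- as.vector(phi %*% pF) -
            deConfig@lambda * pmax(0, cost - budget) / budget
        list(G = G, cost = cost, phi = phi)
    }
    decode <- function(pop, temperature) {
        # pop: P x (nInd * L); returns P x nInd level indices
        lvl <- matrix(0L, nrow = nrow(pop), ncol = nInd)
        for (j in seq_len(nInd)) {
            cols <- (j - 1L) * L + seq_len(L)
            lvl[, j] <- .sampleLevels(pop[, cols, drop = FALSE], temperature)
        }
        lvl
    }

    withSeed(if (is.na(deConfig@seed)) NULL else deConfig@seed, {
        P <- deConfig@popSize
        D <- nInd * L
        pop <- matrix(stats::rnorm(P * D), nrow = P)
        curG <- evalLevels(decode(pop, deConfig@temperature))$G
        elite <- pop[which.max(curG), ]
        eliteG <- evalLevels(decode(matrix(elite, nrow = 1L), 0))$G
        trace <- numeric(deConfig@nRounds)
        for (round in seq_len(deConfig@nRounds)) {
            r <- matrix(sample.int(P, 3L * P, replace = TRUE), ncol = 3L)
            bad <- which(r[, 1L] == seq_len(P) | r[, 2L] == seq_len(P) |
                         r[, 3L] == seq_len(P) | r[, 1L] == r[, 2L] |
                         r[, 1L] == r[, 3L] | r[, 2L] == r[, 3L])
            while (length(bad)) {
                r[bad, ] <- matrix(sample.int(P, 3L * length(bad),
                                              replace = TRUE), ncol = 3L)
                bad <- which(r[, 1L] == seq_len(P) | r[, 2L] == seq_len(P) |
                             r[, 3L] == seq_len(P) | r[, 1L] == r[, 2L] |
                             r[, 1L] == r[, 3L] | r[, 2L] == r[, 3L])
            }
            mutant <- pop[r[, 1L], , drop = FALSE] +
                deConfig@F * (pop[r[, 2L], , drop = FALSE] -
                              pop[r[, 3L], , drop = FALSE])
            cross <- matrix(stats::runif(P * D) < deConfig@CR, nrow = P)
            cross[cbind(seq_len(P), sample.int(D, P, replace = TRUE))] <- TRUE
            trial <- pop
            trial[cross] <- mutant[cross]
            trialG <- evalLevels(decode(trial, deConfig@temperature))$G
            accept <- trialG >= curG
            pop[accept, ] <- trial[accept, , drop = FALSE]
            curG[accept] <- trialG[accept]
            # elitist tracking with deterministic decoding
            bi <- which.max(curG)
            bG <- evalLevels(decode(pop[bi, , drop = FALSE], 0))$G
            if (bG > eliteG) {
                eliteG <- bG
                elite <- pop[bi, ]
            }
            trace[round] <- eliteG
        }

        lvl <- decode(matrix(elite, nrow = 1L), 0)
        cov <- as.numeric(coverages[lvl])
        ev <- evalLevels(lvl)
        # greedy repair: step down the member losing the least phased mass
        while (ev$cost > budget) {
            reducible <- which(cov > 0)
            if (!length(reducible)) break
            bestJ <- NA_integer_; bestLoss <- Inf; bestSave <- -Inf
            for (j in reducible) {
                covJ <- cov
                covJ[j] <- max(coverages[coverages < cov[j]])
                lvlJ <- matrix(match(covJ, coverages), nrow = 1L)
                evJ <- evalLevels(lvlJ)
                loss <- ev$G - evJ$G
                save <- ev$cost - evJ$cost
                if (loss < bestLoss - 1e-12 ||
                    (abs(loss - bestLoss) <= 1e-12 && save > bestSave)) {
                    bestJ <- j; bestLoss <- loss; bestSave <- save
                }
            }
            cov[bestJ] <- max(coverages[coverages < cov[bestJ]])
            ev <- evalLevels(matrix(match(cov, coverages), nrow = 1L))
        }
        if (all(cov == 0) && any(pF > 0))
            warning("no feasible nonzero allocation under the budget; ",
                    "returning the all-zero assignment")

        eff <- pmax(cov, p$coverage)
        newCov <- pmax(cov - p$coverage, 0) * (cov > p$coverage)
        indCost <- (cov > p$coverage) *
            (costModel@libraryCost * (!p$hasLibrary) +
             costModel@perXCost * (cov - p$coverage))
        assignments <- data.frame(id = members, coverage = cov,
                                  effectiveCoverage = eff,
                                  newCoverage = newCov, cost = indCost,
                                  stringsAsFactors = FALSE)
        famOut <- families
        famOut$phi <- as.vector(ev$phi)
        for (s in seq_len(7L))
            famOut[[paste0("cov_", memberCols[s])]] <-
                c(eff, 0)[memberIdx[, s]]
        new("AllocationResult", assignments = assignments, families = famOut,
            totalCost = ev$cost, objective = ev$G,
            feasible = ev$cost <= budget, budget = budget, trace = trace)
    })
}
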