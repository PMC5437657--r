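#' Run configuration for the end-to-end pipeline
#'
#' Collects file paths and parameters for a select (+ optional allocate)
#' run.  Either \code{panel} (path or \linkS4class{PhasedPanel}) must be
#' given, or \code{simulate} must hold a \code{\link{SimConfig}} from which a
#' population is simulated first.
#'
#' @param outDir output directory (created if missing).
#' @param panel path to a phased panel file, or a \linkS4class{PhasedPanel}.
#' @param panelFormat "haplotypes" or "vcf".
#' @param chrPerMarker chromosome index per marker for text panels.
#' @param pedigree path to a pedigree file, or a \linkS4class{Pedigree};
#'   required for budget allocation.
#' @param prior path to a prior-sequencing CSV, or a data.frame.
#' @param accuracyTable path to an accuracy-table CSV (optional; the default
#'   surrogate accuracy model is used when absent).
#' @param windowLength,minPhased haplotype library parameters.
#' @param k number of focal individuals to select.
#' @param budget optional budget (GBP); allocation runs when non-NULL.
#' @param libraryCost,perXCost cost model (GBP).
#' @param coverages allowed coverage levels.
#' @param deRounds,dePopSize differential evolution settings.
#' @param simulate optional \code{\link{SimConfig}}.
#' @param seed integer seed for all randomness.
#' @return a validated list of class \code{RunConfig}.
#' @export
runConfig <- function(outDir, panel = NULL, panelFormat = "haplotypes",
                      chrPerMarker = NULL, pedigree = NULL, prior = NULL,
                      accuracyTable = NULL, windowLength = 250,
                      minPhased = 0.9, k = 50, budget = NULL,
                      libraryCost = 40, perXCost = 85,
                      coverages = DEFAULT_COVERAGES, deRounds = 10000,
                      dePopSize = 50, simulate = NULL, seed = 1) {
    for (p in list(panel, pedigree, prior, accuracyTable))
        if (is.character(p) && !file.exists(p))
            stop("file does not exist: ", p)
    stopifnot(windowLength >= 1, minPhased >= 0, minPhased <= 1, k >= 1)
    if (is.null(panel) && is.null(simulate))
        stop("either a panel or a simulation config is required")
    structure(as.list(environment()), class = "RunConfig")
}

#' Run the pipeline: simulate, select, allocate
#'
#' Executes the stages requested by the configuration and writes their
#' artifacts under \code{outDir}: the simulated panel/pedigree (when
#' simulating), the focal ranking and coverage curve CSVs, and (when a budget
#' is given) the allocation CSV and a JSON summary.  All randomness is
#' seeded from the configuration, so a rerun with the same config reproduces
#' the outputs byte for byte.
#'
#' @param config a \code{\link{runConfig}}.
#' @param verbose log stage progress.
#' @return invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config, verbose = TRUE) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    say <- function(...) if (verbose) message("[seqalloc] ", sprintf(...))
    panel <- config$panel
    pedigree <- config$pedigree

    if (!is.null(config$simulate)) {
        say("simulate: %d generations of %d", config$simulate$nGenerations,
            config$simulate$nPerGeneration)
        cfg <- config$simulate
        if (is.null(cfg$seed)) cfg$seed <- config$seed
        pop <- if (cfg$nUnrelated > 0L) simulateUnrelatedPopulation(cfg)
               else simulatePedigreePopulation(cfg)
        panel <- pop$panel
        pedigree <- pop$pedigree
        writePhasedPanel(panel, file.path(config$outDir, "panel.txt"))
        writePedigree(pedigree, file.path(config$outDir, "pedigree.txt"))
    }
    if (is.character(panel))
        panel <- readPhasedPanel(panel, config$panelFormat,
                                 chr = config$chrPerMarker)
    if (is.character(pedigree))
        pedigree <- readPedigree(pedigree)

    say("select: building haplotype library (window %d, min phased %.2f)",
        config$windowLength, config$minPhased)
    lib <- tryCatch(
        buildHaplotypeLibrary(panel, windowLength = config$windowLength,
                              minPhased = config$minPhased,
                              verbose = verbose),
        error = function(e) stop("stage select: ", conditionMessage(e)))
    say("select: library has %d haplotypes in %d windows",
        length(lib@counts), nrow(lib@windows))
    ranking <- withSeed(config$seed, selectFocalIndividuals(lib, config$k))
    utils::write.csv(asTable(ranking),
                     file.path(config$outDir, "focal_ranking.csv"),
                     row.names = FALSE, quote = FALSE)
    coverageCurve(ranking, file.path(config$outDir, "coverage_curve.csv"))
    say("select: top %d focal individuals cover %.4f of haplotype mass",
        length(ranking@ids), max(ranking@cumulativeProportion))

    allocation <- NULL
    if (!is.null(config$budget)) {
        if (is.null(pedigree))
            stop("stage allocate: budget allocation across focal families ",
                 "requires pedigree data; supply a pedigree file ",
                 "(allocation is currently limited to populations with ",
                 "pedigree data)")
        prior <- config$prior
        if (is.character(prior)) prior <- readPriorSequencing(prior)
        accuracy <- if (!is.null(config$accuracyTable))
            accuracyFromTable(config$accuracyTable) else defaultAccuracy
        fams <- focalFamilies(ranking, pedigree)
        say("allocate: %d families, budget %.0f GBP, %d rounds",
            nrow(fams), config$budget, config$deRounds)
        allocation <- allocateBudget(
            fams, budget = config$budget,
            costModel = CostModel(config$libraryCost, config$perXCost),
            accuracy = accuracy, prior = prior,
            coverages = config$coverages,
            deConfig = DEConfig(popSize = config$dePopSize,
                                nRounds = config$deRounds,
                                seed = config$seed))
        utils::write.csv(allocation@assignments,
                         file.path(config$outDir, "allocation.csv"),
                         row.names = FALSE, quote = FALSE)
        summary <- list(totalCost = allocation@totalCost,
                        budget = config$budget,
                        objective = allocation@objective,
                        feasible = allocation@feasible,
                        phiPerFamily = allocation@families$phi,
                        pFPerFamily = allocation@families$pF)
        jsonlite::write_json(summary,
                             file.path(config$outDir, "summary.json"),
                             auto_unbox = TRUE, digits = NA)
        say("allocate: cost %.0f GBP, objective %.4f",
            allocation@totalCost, allocation@objective)
    }
    invisible(list(panel = panel, pedigree = pedigree, library = lib,
                   ranking = ranking, allocation = allocation))
}
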