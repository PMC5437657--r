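test_that("scenario costs follow the library + per-x pricing with prior subtraction", {
    expect_equal(scenarioCost(10), 890)
    expect_equal(scenarioCost(2), 210)
    expect_equal(scenarioCost(10, priorCoverage = 2, priorLibrary = TRUE), 680)
    expect_equal(scenarioCost(rep(0, 7)), 0)
    # target below existing data costs nothing
    expect_equal(scenarioCost(1, priorCoverage = 2, priorLibrary = TRUE), 0)
    # prior data but no library: library is paid again on new sequencing
    expect_equal(scenarioCost(5, priorCoverage = 1, priorLibrary = FALSE),
                 40 + 4 * 85)
    expect_error(scenarioCost(5, priorCoverage = -1), "non-negative")
    cm <- CostModel(libraryCost = 100, perXCost = 10)
    expect_equal(scenarioCost(c(2, 0), cm), 120)
})

test_that("combination cost pays shared ancestors once at the max requested coverage", {
    shared <- data.frame(id = c("gs", "f1", "gs", "f2"),
                         coverage = c(5, 2, 5, 1))
    expect_equal(combinationCost(shared),
                 scenarioCost(5) + scenarioCost(2) + scenarioCost(1))
    asym <- data.frame(id = c("gs", "gs"), coverage = c(5, 10))
    expect_equal(combinationCost(asym), scenarioCost(10))
    # disjoint families are additive
    f1 <- data.frame(id = c("a", "b"), coverage = c(10, 2))
    f2 <- data.frame(id = c("c", "d"), coverage = c(5, 1))
    expect_equal(combinationCost(rbind(f1, f2)),
                 combinationCost(f1) + combinationCost(f2))
    # family of 7, all new libraries, 50x total
    fam <- data.frame(id = letters[1:7], coverage = c(10, 2, 20, 10, 5, 2, 1))
    expect_equal(combinationCost(fam), 7 * 40 + 50 * 85)
    expect_error(
        combinationCost(f1, prior = data.frame(id = c("a", "a"),
                                               coverage = c(1, 2),
                                               hasLibrary = c(TRUE, TRUE))),
        "conflicting")
})

test_that("scenario space size is the combinatorial count", {
    expect_equal(countScenarios(2, 1), 2)
    expect_equal(countScenarios(6, 2), 36)
    expect_equal(countScenarios(6, 7), 279936)
})

test_that("default accuracy is zero with no data and monotone in every member", {
    expect_equal(defaultAccuracy(rep(0, 7)), 0)
    expect_true(all(defaultAccuracy(matrix(runif(70, 0, 20), ncol = 7)) <= 1))
    # grid scan over all scenarios at the reduced coverage set {0, 1, 20}
    lv <- c(0, 1, 20)
    grid <- as.matrix(expand.grid(rep(list(lv), 7)))
    phi <- defaultAccuracy(grid)
    for (m in 1:7) {
        for (from in 1:2) {
            lower <- grid[, m] == lv[from]
            bumped <- grid[lower, , drop = FALSE]
            bumped[, m] <- lv[from + 1]
            expect_true(all(defaultAccuracy(bumped) >= phi[lower] - 1e-12))
        }
    }
})

test_that("table-backed accuracy returns exact listed values and rejects bad tables", {
    tab <- expand.grid(focal = c(0, 20), sire = c(0, 20), dam = 0,
                       gp1 = 0, gp2 = 0, gp3 = 0, gp4 = 0)
    tab$phi <- 0.04 * seq_len(nrow(tab))
    acc <- accuracyFromTable(tab)
    expect_equal(acc(c(20, 0, 0, 0, 0, 0, 0)), tab$phi[2])
    expect_equal(acc(as.matrix(tab[, 1:7])), tab$phi)
    expect_error(acc(c(5, 0, 0, 0, 0, 0, 0)), "not present")
    bad <- tab; bad$phi[1] <- 1.7
    expect_error(accuracyFromTable(bad), "phi")
})

test_that("goodness equals the hand-summed objective with overrun penalty", {
    fams <- data.frame(focal = c("x1", "x2"), sire = c("s1", "s2"),
                       dam = c("d1", NA), gp1 = NA, gp2 = NA, gp3 = NA,
                       gp4 = NA, pF = c(0.3, 0.1), stringsAsFactors = FALSE)
    cov <- c(x1 = 10, s1 = 5, d1 = 2, x2 = 2, s2 = 0)
    phi1 <- defaultAccuracy(c(10, 5, 2, 0, 0, 0, 0))
    phi2 <- defaultAccuracy(c(2, 0, 0, 0, 0, 0, 0))
    cost <- scenarioCost(cov)
    g <- goodness(cov, fams, budget = 10000, lambda = 10)
    expect_equal(g$objective, 0.3 * phi1 + 0.1 * phi2)   # under budget
    expect_equal(g$cost, cost)
    gTight <- goodness(cov, fams, budget = 1000, lambda = 10)
    expect_equal(gTight$objective,
                 0.3 * phi1 + 0.1 * phi2 - 10 * (cost - 1000) / 1000)
    # all-zero assignment scores 0
    zero <- setNames(rep(0, 5), names(cov))
    expect_equal(goodness(zero, fams, budget = 1000)$objective, 0)
    expect_error(goodness(cov, fams, budget = 0), "budget")
})

test_that("scenario sampling follows softmax probabilities and saturates", {
    set.seed(1)
    # one huge logit -> that coverage picked essentially always
    logits <- matrix(0, nrow = 1, ncol = 6)
    logits[1, 4] <- 50
    draws <- replicate(200, sampleScenario(logits))
    expect_true(all(draws == DEFAULT_COVERAGES[4]))
    # equal logits -> uniform over levels (chi-square)
    eq <- matrix(0, nrow = 1, ncol = 6)
    draws <- replicate(6000, sampleScenario(eq))
    tabl <- table(factor(draws, levels = DEFAULT_COVERAGES))
    expect_gt(chisq.test(tabl)$p.value, 0.001)
    # temperature 0 is the argmax; seeded draws are reproducible
    expect_equal(sampleScenario(logits, temperature = 0),
                 DEFAULT_COVERAGES[4])
    set.seed(9); a <- replicate(20, sampleScenario(eq))
    set.seed(9); b <- replicate(20, sampleScenario(eq))
    expect_identical(a, b)
})

test_that("a lavish budget saturates all family members at maximum coverage", {
    fams <- data.frame(focal = c("x1", "x2"), sire = c("s1", "s2"),
                       dam = c("d1", "d2"), gp1 = NA, gp2 = NA, gp3 = NA,
                       gp4 = NA, pF = c(0.2, 0.1), stringsAsFactors = FALSE)
    res <- allocateBudget(fams, budget = 1e6,
                          deConfig = DEConfig(popSize = 20, nRounds = 400,
                                              seed = 4))
    expect_true(all(res@assignments$coverage == 20))
    expect_true(res@feasible)
})

test_that("DE is deterministic under a fixed seed and its elite trace is monotone", {
    fams <- data.frame(focal = "x", sire = "s", dam = "d", gp1 = "g1",
                       gp2 = "g2", gp3 = NA, gp4 = NA, pF = 0.25,
                       stringsAsFactors = FALSE)
    r1 <- allocateBudget(fams, budget = 2000,
                         deConfig = DEConfig(popSize = 15, nRounds = 150,
                                             seed = 11))
    r2 <- allocateBudget(fams, budget = 2000,
                         deConfig = DEConfig(popSize = 15, nRounds = 150,
                                             seed = 11))
    expect_identical(r1@assignments, r2@assignments)
    expect_identical(r1@objective, r2@objective)
    expect_true(all(diff(r1@trace) >= -1e-12))
    expect_lte(r1@totalCost, 2000)
})

test_that("prior sequence data reduces cost and feeds the effective coverage", {
    fams <- data.frame(focal = "x", sire = "s", dam = "d", gp1 = NA,
                       gp2 = NA, gp3 = NA, gp4 = NA, pF = 0.5,
                       stringsAsFactors = FALSE)
    prior <- data.frame(id = "x", coverage = 2, hasLibrary = TRUE)
    res <- allocateBudget(fams, budget = 1e6, prior = prior,
                          deConfig = DEConfig(popSize = 15, nRounds = 300,
                                              seed = 5))
    a <- res@assignments
    x <- a[a$id == "x", ]
    expect_equal(x$cost, 85 * (x$coverage - 2))   # library waived, 2x credited
    expect_equal(x$effectiveCoverage, max(x$coverage, 2))
})

test_that("achieved objective is non-decreasing in the budget on matched instances", {
    fams <- data.frame(focal = c("x1", "x2"), sire = c("s1", "s2"),
                       dam = c("d1", "d2"), gp1 = NA, gp2 = NA, gp3 = NA,
                       gp4 = NA, pF = c(0.3, 0.15), stringsAsFactors = FALSE)
    for (seed in 1:5) {
        lo <- allocateBudget(fams, budget = 1500,
                             deConfig = DEConfig(popSize = 20, nRounds = 250,
                                                 seed = seed))
        hi <- allocateBudget(fams, budget = 3000,
                             deConfig = DEConfig(popSize = 20, nRounds = 250,
                                                 seed = seed))
        expect_gte(hi@objective, lo@objective - 1e-9)
        expect_lte(lo@totalCost, 1500)
        expect_lte(hi@totalCost, 3000)
    }
})

test_that("families with more frequent haplotypes attract more coverage", {
    fams <- data.frame(focal = c("x1", "x2"), sire = c("s1", "s2"),
                       dam = c("d1", "d2"), gp1 = NA, gp2 = NA, gp3 = NA,
                       gp4 = NA, pF = c(0.4, 0.02), stringsAsFactors = FALSE)
    for (seed in 1:5) {
        res <- allocateBudget(fams, budget = 4000,
                              deConfig = DEConfig(popSize = 20, nRounds = 400,
                                                  seed = 100 + seed))
        tot <- function(f) sum(res@families[f, grepl("^cov_",
                                                     names(res@families))])
        expect_gte(tot(1), tot(2))
    }
})
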