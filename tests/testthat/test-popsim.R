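test_that("base haplotypes segregate, have the requested shape and are seeded", {
    cfg <- SimConfig(nChromosomes = 3, nSnpsPerChr = 40, nBaseHaplotypes = 12,
                     nQtn = 6, seed = 42)
    b <- simulateBaseHaplotypes(cfg)
    expect_length(b$haplotypes, 3)
    for (h in b$haplotypes) {
        expect_equal(dim(h), c(12, 40))
        cs <- colSums(h)
        expect_true(all(cs >= 1 & cs <= 11))   # every marker segregating
    }
    b2 <- simulateBaseHaplotypes(cfg)
    expect_identical(b$haplotypes, b2$haplotypes)

    # minimal segregation case
    tiny <- simulateBaseHaplotypes(SimConfig(nChromosomes = 1, nSnpsPerChr = 4,
                                             nBaseHaplotypes = 2, nQtn = 1,
                                             seed = 1))
    expect_equal(dim(tiny$haplotypes[[1]]), c(2, 4))
    expect_true(all(colSums(tiny$haplotypes[[1]]) == 1))

    expect_error(simulateBaseHaplotypes(
        SimConfig(nBaseHaplotypes = 2, nQtn = 10)), NA)
    expect_error(SimConfig(nBaseHaplotypes = 1))
})

test_that("config invariants are enforced", {
    expect_error(SimConfig(nQtn = 7, nChromosomes = 10), "divisible")
    expect_error(SimConfig(nSiresSelected = 600, nPerGeneration = 1000),
                 "males")
})

test_that("pedigree population has the stated cohort structure", {
    cfg <- SimConfig(nChromosomes = 2, nSnpsPerChr = 30, nBaseHaplotypes = 10,
                     nGenerations = 3, nPerGeneration = 20,
                     nSiresSelected = 3, nDams = 10, nQtn = 10, seed = 5)
    pop <- simulatePedigreePopulation(cfg)
    ped <- pop$pedigree
    expect_equal(nIndividuals(ped), 20 * 4)          # founders + 3 generations
    tab <- asTable(ped)
    expect_equal(as.vector(table(tab$generation)), rep(20, 4))
    expect_equal(sum(tab$sex == 1), sum(tab$sex == 2))   # exact sex ratio
    # parents precede offspring and generations increment
    idx <- seq_len(nrow(tab))
    expect_true(all(ped@sire < idx & ped@dam < idx))
    known <- ped@sire > 0
    expect_equal(tab$generation[known],
                 tab$generation[ped@sire[known]] + 1L)
    # panel fully phased by construction
    expect_true(all(!is.na(pop$panel@alleles)))
})

test_that("a single selected sire fathers all offspring and has top TBV", {
    cfg <- SimConfig(nChromosomes = 1, nSnpsPerChr = 30, nBaseHaplotypes = 10,
                     nGenerations = 1, nPerGeneration = 30,
                     nSiresSelected = 1, nDams = 15, nQtn = 5, seed = 9)
    pop <- simulatePedigreePopulation(cfg)
    off <- which(pop$pedigree@generation == 1L)
    sires <- unique(pop$pedigree@sire[off])
    expect_length(sires, 1)
    males <- which(pop$pedigree@generation == 0L & pop$pedigree@sex == 1L)
    expect_equal(pop$trait$tbv[sires], max(pop$trait$tbv[males]))
})

test_that("every transmitted gamete is a legal mosaic of its parent's chromosomes", {
    cfg <- SimConfig(nChromosomes = 2, nSnpsPerChr = 40, nBaseHaplotypes = 8,
                     nGenerations = 2, nPerGeneration = 16,
                     nSiresSelected = 2, nDams = 8, nQtn = 4, seed = 13)
    pop <- simulatePedigreePopulation(cfg)
    a <- pop$panel@alleles
    ped <- pop$pedigree
    for (i in which(ped@sire > 0)) {
        for (side in 1:2) {
            p <- if (side == 1) ped@sire[i] else ped@dam[i]
            gam <- a[2 * i - 2 + side, ]
            h1 <- a[2 * p - 1, ]; h2 <- a[2 * p, ]
            expect_true(all(gam == h1 | gam == h2))
        }
    }
})

test_that("mean TBV responds to truncation selection across generations", {
    reps <- 20
    means <- sapply(seq_len(reps), function(r) {
        cfg <- SimConfig(nChromosomes = 1, nSnpsPerChr = 40,
                         nBaseHaplotypes = 20, nGenerations = 5,
                         nPerGeneration = 60, nSiresSelected = 5,
                         nDams = 30, nQtn = 20, seed = 1000 + r)
        pop <- simulatePedigreePopulation(cfg)
        tapply(pop$trait$tbv, pop$pedigree@generation, mean)
    })
    avg <- rowMeans(means)
    expect_true(all(diff(avg) > -1e-8))
})

test_that("allele frequencies drift neutrally when selection is disabled", {
    reps <- 30
    diffs <- sapply(seq_len(reps), function(r) {
        cfg <- SimConfig(nChromosomes = 1, nSnpsPerChr = 20,
                         nBaseHaplotypes = 20, nGenerations = 3,
                         nPerGeneration = 40, nSiresSelected = 5,
                         nDams = 20, nQtn = 4, seed = 7000 + r)
        pop <- simulatePedigreePopulation(cfg, selection = FALSE)
        g <- pop$pedigree@generation
        rowsOf <- function(gen) {
            i <- which(g == gen)
            sort(c(2 * i - 1, 2 * i))
        }
        mean(pop$panel@alleles[rowsOf(3L), 1]) -
            mean(pop$panel@alleles[rowsOf(0L), 1])
    })
    z <- mean(diffs) / (sd(diffs) / sqrt(reps))
    expect_lt(abs(z), qnorm(0.995))
})

test_that("unrelated population draws chromosomes directly from base haplotypes", {
    cfg <- SimConfig(nChromosomes = 1, nSnpsPerChr = 25, nBaseHaplotypes = 2,
                     nQtn = 5, nUnrelated = 400, seed = 21)
    base <- simulateBaseHaplotypes(cfg)
    pop <- simulateUnrelatedPopulation(cfg, base)
    expect_equal(nIndividuals(pop$pedigree), 400)
    expect_true(all(pop$pedigree@sire == 0L & pop$pedigree@dam == 0L))
    # with 2 base haplotypes, copy frequencies ~ 1/2 within binomial error
    h1 <- base$haplotypes[[1]][1, ]
    isH1 <- apply(pop$panel@alleles, 1, function(x) all(x == h1))
    phat <- mean(isH1)
    se <- sqrt(0.5 * 0.5 / length(isH1))
    expect_lt(abs(phat - 0.5), qnorm(0.995) * se)

    one <- simulateUnrelatedPopulation(
        SimConfig(nChromosomes = 1, nSnpsPerChr = 10, nBaseHaplotypes = 4,
                  nQtn = 2, nUnrelated = 1, seed = 2))
    expect_equal(nIndividuals(one$panel), 1)
})

test_that("identical seeds reproduce identical populations", {
    cfg <- SimConfig(nChromosomes = 1, nSnpsPerChr = 20, nBaseHaplotypes = 8,
                     nGenerations = 2, nPerGeneration = 10,
                     nSiresSelected = 2, nDams = 5, nQtn = 4, seed = 77)
    p1 <- simulatePedigreePopulation(cfg)
    p2 <- simulatePedigreePopulation(cfg)
    expect_identical(p1$panel@alleles, p2$panel@alleles)
    expect_identical(asTable(p1$pedigree), asTable(p2$pedigree))
})
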