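test_that("candidate scores match exhaustive enumeration on toy libraries", {
    p <- makePanel(i1 = c("0011", "0011"),   # double-carried haplotype
                   i2 = c("0011", "1100"),
                   i3 = c("1100", "1111"))
    lib <- buildHaplotypeLibrary(p, windowLength = 4)
    # copy counts: 0011 x3, 1100 x2, 1111 x1
    expect_equal(candidateScore("i1", lib), 3)       # counts its hap once
    expect_equal(candidateScore("i2", lib), 5)
    expect_equal(candidateScore("i3", lib), 3)
    # all haplotypes of i2 masked -> 0
    i2haps <- na.omit(as.vector(lib@hapAssign[3:4, ]))
    expect_equal(candidateScore("i2", lib, maskedHaps = i2haps), 0)
    expect_error(candidateScore("nobody", lib), "unknown")

    single <- buildHaplotypeLibrary(makePanel(i1 = c("01", "10")),
                                    windowLength = 2)
    expect_equal(candidateScore("i1", single), single@totalCopies)
})

test_that("greedy selection replays a brute-force oracle on toy instances", {
    p <- makePanel(i1 = c("0011", "0110"), i2 = c("0011", "0011"),
                   i3 = c("1100", "0110"), i4 = c("1111", "0011"),
                   i5 = c("1100", "1100"))
    lib <- buildHaplotypeLibrary(p, windowLength = 2)   # 2 windows
    r <- selectFocalIndividuals(lib, k = 5)
    o <- oracleGreedy(p, starts = c(0, 2), len = 2, k = 5)
    expect_equal(r@ids, o$picks)
    expect_equal(r@marginalCopies, unname(o$marginal))
    expect_equal(r@totalCopies, o$total)
})

test_that("greedy pick attains the maximum marginal at every step (random instances)", {
    for (seed in 1:25) {
        nInd <- sample(3:8, 1)
        nWin <- sample(1:3, 1)
        p <- randomPanel(nInd, nWin * 3, seed = 500 + seed)
        lib <- buildHaplotypeLibrary(p, windowLength = 3)
        r <- selectFocalIndividuals(lib, k = nInd)
        o <- oracleGreedy(p, starts = (seq_len(nWin) - 1) * 3, len = 3,
                          k = nInd)
        expect_equal(r@ids, o$picks)
        expect_equal(r@marginalCopies, unname(o$marginal))
    }
})

test_that("identical individuals: first pick covers everything", {
    p <- makePanel(i1 = c("0101", "0101"), i2 = c("0101", "0101"),
                   i3 = c("0101", "0101"))
    lib <- buildHaplotypeLibrary(p, windowLength = 4)
    r <- selectFocalIndividuals(lib, k = 3)
    expect_equal(r@cumulativeProportion[1], 1)
    expect_length(r@ids, 1)   # later marginals are 0, selection stops
})

test_that("selecting the whole population exhausts the haplotype mass", {
    for (seed in 1:5) {
        p <- randomPanel(6, 9, seed = 900 + seed)
        lib <- buildHaplotypeLibrary(p, windowLength = 3)
        r <- selectFocalIndividuals(lib, k = 6)
        expect_equal(max(r@cumulativeProportion), 1)
        expect_true(all(diff(r@marginalCopies) <= 1e-9))   # submodularity
    }
})

test_that("k larger than the population truncates with a warning", {
    p <- makePanel(i1 = c("01", "10"), i2 = c("00", "11"))
    lib <- buildHaplotypeLibrary(p, windowLength = 2)
    expect_warning(r <- selectFocalIndividuals(lib, k = 10), "truncat")
    expect_lte(length(r@ids), 2)
})

test_that("already-sequenced individuals are pre-masked; excluded ones still count", {
    p <- makePanel(i1 = c("0011", "0011"), i2 = c("0011", "1100"),
                   i3 = c("1111", "1111"))
    lib <- buildHaplotypeLibrary(p, windowLength = 4)
    # pre-masking i1 removes haplotype 0011 from all scores:
    # i2 drops to 1 (its 1100 copy), i3 keeps 2 (1111 twice)
    r <- selectFocalIndividuals(lib, k = 2, alreadySequenced = "i1")
    expect_false("i1" %in% r@ids)
    expect_equal(r@ids[1], "i3")
    expect_equal(r@marginalCopies[1], 2)
    # excluding i2 keeps its copies in others' scores
    r2 <- selectFocalIndividuals(lib, k = 2, doNotSequence = "i2")
    expect_false("i2" %in% r2@ids)
    expect_equal(r2@ids[1], "i1")      # 0011 still counts 3 copies
    expect_equal(r2@marginalCopies[1], 3)
})

test_that("coverage curve is the running cumulative sum and is monotone", {
    p <- randomPanel(5, 8, seed = 31)
    lib <- buildHaplotypeLibrary(p, windowLength = 4)
    r <- selectFocalIndividuals(lib, k = 5)
    cc <- coverageCurve(r)
    expect_equal(cc$cumulativeProportion, cumsum(r@marginalProportion))
    expect_true(all(diff(cc$cumulativeProportion) >= -1e-12))
    one <- selectFocalIndividuals(lib, k = 1)
    expect_equal(nrow(coverageCurve(one)), 1)
    f <- tempfile(fileext = ".csv")
    coverageCurve(r, f)
    expect_equal(read.csv(f)$cumulativeProportion, cc$cumulativeProportion,
                 tolerance = 1e-12)
})
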