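# Run expr under a fixed seed, restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
    if (is.null(seed) || (length(seed) == 1L && is.na(seed)))
        return(force(expr))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

# Order ids numerically when they all parse as numbers, lexically otherwise;
# used for reproducible smallest-id tie-breaking.
idRank <- function(ids) {
    num <- suppressWarnings(as.numeric(ids))
    if (!anyNA(num)) rank(num, ties.method = "first") else
        rank(ids, ties.method = "first")
}
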