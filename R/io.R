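#' Read a phased panel
#'
#' Two on-disk dialects are supported.  The default text dialect has two
#' space-delimited rows per individual (paternal gamete then maternal), each
#' starting with the individual id followed by one allele code per marker;
#' the missing/unphased allele code is 9.  Phased VCF is read through the
#' vcfR package when installed: \code{GT} fields separated by \code{|} are
#' phased, while a \code{/} separator or missing genotype marks both alleles
#' unphased (NA) at that marker.
#'
#' @param path file path.
#' @param format "haplotypes" (two-rows-per-individual text) or "vcf".
#' @param chr chromosome index per marker for the text dialect (defaults to a
#'   single chromosome); ignored for VCF, where chromosomes come from the
#'   CHROM column.
#' @return A \linkS4class{PhasedPanel}.
#' @export
readPhasedPanel <- function(path, format = c("haplotypes", "vcf"),
                            chr = NULL) {
    format <- match.arg(format)
    if (format == "vcf") return(.readVcfPanel(path))
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty phased panel file: ", path)
    if (length(lines) %% 2L != 0L)
        stop("phased panel file must have two lines per individual; got ",
             length(lines), " lines")
    fields <- strsplit(trimws(lines), "\\s+")
    nf <- lengths(fields)
    if (length(unique(nf)) != 1L)
        stop("ragged rows in phased panel file (",
             paste(unique(nf), collapse = ", "), " fields)")
    idsTwice <- vapply(fields, `[`, "", 1L)
    odd <- seq(1L, length(lines), by = 2L)
    if (!identical(idsTwice[odd], idsTwice[odd + 1L]))
        stop("paternal/maternal row ids do not pair up")
    if (anyDuplicated(idsTwice[odd]))
        stop("duplicate individual ids in phased panel file")
    a <- matrix(as.integer(unlist(lapply(fields, `[`, -1L))),
                nrow = length(lines), byrow = TRUE)
    a[a == 9L] <- NA_integer_
    if (!all(a[!is.na(a)] %in% c(0L, 1L)))
        stop("allele codes must be 0, 1 or 9 (missing)")
    if (is.null(chr)) chr <- rep(1L, ncol(a))
    PhasedPanel(idsTwice[odd], a, chr)
}

.readVcfPanel <- function(path) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    ids <- colnames(gt)
    chrNames <- vcfR::getCHROM(v)
    chr <- as.integer(factor(chrNames, levels = unique(chrNames)))
    m <- nrow(gt); n <- length(ids)
    a <- matrix(NA_integer_, nrow = 2L * n, ncol = m)
    for (j in seq_len(n)) {
        g <- gt[, j]
        phased <- !is.na(g) & grepl("|", g, fixed = TRUE) &
            !grepl("/", g, fixed = TRUE) & !grepl(".", g, fixed = TRUE)
        parts <- matrix(NA_integer_, nrow = m, ncol = 2L)
        sp <- strsplit(g[phased], "|", fixed = TRUE)
        parts[phased, ] <- matrix(as.integer(unlist(sp)), ncol = 2L,
                                  byrow = TRUE)
        a[2L * j - 1L, ] <- parts[, 1L]
        a[2L * j, ] <- parts[, 2L]
    }
    PhasedPanel(ids, a, chr)
}

#' Write a phased panel
#'
#' Writes the two-rows-per-individual text dialect read by
#' \code{\link{readPhasedPanel}}: paternal gamete then maternal, id first,
#' alleles space-delimited, missing coded 9.
#'
#' @param panel a \linkS4class{PhasedPanel}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writePhasedPanel <- function(panel, path) {
    a <- panel@alleles
    a[is.na(a)] <- 9L
    idCol <- rep(panel@ids, each = 2L)
    lines <- paste(idCol, apply(a, 1L, paste, collapse = " "))
    writeLines(lines, path)
    invisible(path)
}

#' Read a pedigree file
#'
#' Whitespace- or comma-delimited columns \code{id sire dam [sex]
#' [generation]}; 0 denotes an unknown parent.  Rows may be in any order;
#' records are topologically sorted and a cycle is an error.
#'
#' @param path file path.
#' @return A \linkS4class{Pedigree}.
#' @export
readPedigree <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    if (!length(lines)) stop("empty pedigree file: ", path)
    fields <- strsplit(trimws(gsub(",", " ", lines)), "\\s+")
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("pedigree rows need at least id, sire and dam")
    get <- function(k) vapply(fields, function(f)
        if (length(f) >= k) f[k] else NA_character_, "")
    Pedigree(id = get(1L), sire = get(2L), dam = get(3L),
             sex = if (max(nf) >= 4L) get(4L) else NULL,
             generation = if (max(nf) >= 5L)
                 suppressWarnings(as.integer(get(5L))) else NULL)
}

#' Write a pedigree file
#'
#' Whitespace-delimited \code{id sire dam sex generation} with 0 for unknown
#' parents, readable by \code{\link{readPedigree}}.
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writePedigree <- function(pedigree, path) {
    tab <- asTable(pedigree)
    tab$sex[is.na(tab$sex)] <- 0L
    tab$generation[is.na(tab$generation)] <- -1L
    writeLines(do.call(paste, tab), path)
    invisible(path)
}

#' Read a prior-sequencing file
#'
#' CSV with columns \code{id}, \code{coverage} (existing x) and
#' \code{hasLibrary} (0/1 or TRUE/FALSE).
#'
#' @param path file path.
#' @return data.frame suitable for \code{\link{allocateBudget}}.
#' @export
readPriorSequencing <- function(path) {
    p <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("id", "coverage") %in% names(p)))
        stop("prior-sequencing file needs columns id, coverage[, hasLibrary]")
    if (any(p$coverage < 0)) stop("prior coverage must be non-negative")
    if (!is.null(p$hasLibrary)) p$hasLibrary <- as.logical(p$hasLibrary)
    p$id <- as.character(p$id)
    p
}
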