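#' Default family phasing-accuracy surrogate
#'
#' A smooth surrogate for the expected accuracy of phasing a focal
#' individual's haplotypes at the sequence level given the coverages chosen
#' for the seven members of its focal family.  With the saturating response
#' \eqn{s(c) = 1 - \exp(-c/5)}, the accuracy is
#' \deqn{\phi = s(c_{focal}) [0.5 + 0.3 s(c_{sire} + c_{dam}) +
#'       0.2 s(\sum c_{grandparents})],}
#' clipped to [0, 1].  It is zero when the focal individual is unsequenced,
#' monotone non-decreasing in every member's coverage, and saturates at high
#' investment, mirroring the qualitative behaviour of family-based phasing:
#' parental data contributes more than grandparental data, and extra coverage
#' has diminishing returns.  Any user-supplied accuracy model (e.g. a lookup
#' table estimated with a family-based phasing tool) can be used instead; see
#' \code{\link{accuracyFromTable}}.
#'
#' @param scenario numeric vector of 7 coverages (focal, sire, dam, four
#'   grandparents), or a matrix with 7 columns for vectorized evaluation.
#' @return numeric accuracy value(s) in [0, 1].
#' @examples
#' defaultAccuracy(c(10, 10, 2, 5, 1, 1, 0))
#' defaultAccuracy(rep(0, 7))   # nothing sequenced, nothing phased
#' @export
defaultAccuracy <- function(scenario) {
    if (is.null(dim(scenario)))
        scenario <- matrix(scenario, nrow = 1L)
    stopifnot(ncol(scenario) == 7L, all(scenario >= 0))
    s <- function(c) 1 - exp(-c / 5)
    phi <- s(scenario[, 1L]) *
        (0.5 + 0.3 * s(scenario[, 2L] + scenario[, 3L]) +
         0.2 * s(rowSums(scenario[, 4:7, drop = FALSE])))
    pmin(pmax(phi, 0), 1)
}
attr(defaultAccuracy, "vectorized") <- TRUE

#' Table-backed phasing-accuracy model
#'
#' Builds an accuracy model from a lookup table keyed by the seven member
#' coverages, as produced by an external family-based phasing simulation.
#' The returned function gives exactly the tabulated value for a listed
#' scenario and errors on an unlisted one.
#'
#' @param table data.frame with columns \code{focal}, \code{sire},
#'   \code{dam}, \code{gp1}, \code{gp2}, \code{gp3}, \code{gp4} (coverages)
#'   and \code{phi} in [0, 1]; or a path to such a CSV file.
#' @return A vectorized accuracy function usable wherever
#'   \code{\link{defaultAccuracy}} is.
#' @examples
#' tab <- expand.grid(focal = c(0, 20), sire = 0, dam = 0, gp1 = 0,
#'                    gp2 = 0, gp3 = 0, gp4 = 0)
#' tab$phi <- ifelse(tab$focal > 0, 0.9, 0)
#' acc <- accuracyFromTable(tab)
#' acc(c(20, 0, 0, 0, 0, 0, 0))
#' @export
accuracyFromTable <- function(table) {
    if (is.character(table))
        table <- utils::read.csv(table)
    cols <- c("focal", "sire", "dam", "gp1", "gp2", "gp3", "gp4")
    if (!all(c(cols, "phi") %in% names(table)))
        stop("accuracy table must have columns ",
             paste(c(cols, "phi"), collapse = ", "))
    if (any(table$phi < 0 | table$phi > 1))
        stop("accuracy table: phi values must lie in [0, 1]")
    keys <- do.call(paste, c(table[cols], sep = "/"))
    if (anyDuplicated(keys))
        stop("accuracy table: duplicated scenarios")
    phi <- table$phi
    f <- function(scenario) {
        if (is.null(dim(scenario)))
            scenario <- matrix(scenario, nrow = 1L)
        k <- do.call(paste, c(as.data.frame(scenario), sep = "/"))
        i <- match(k, keys)
        if (anyNA(i))
            stop("scenario not present in accuracy table: ",
                 paste(k[is.na(i)], collapse = "; "))
        phi[i]
    }
    attr(f, "vectorized") <- TRUE
    f
}

# Evaluate any accuracy model on a matrix of scenarios (rows).
.evalAccuracy <- function(accuracy, scenarios) {
    if (isTRUE(attr(accuracy, "vectorized")))
        accuracy(scenarios)
    else
        apply(scenarios, 1L, accuracy)
}
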