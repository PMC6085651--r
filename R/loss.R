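#' Core gene set across autotroph references
#'
#' The unbiased background for loss comparisons: genes that have a 1-1
#' ortholog in the reference proteome and are present in every autotrophic
#' species.
#'
#' @param presence logical matrix, genes x species, `TRUE` = gene recovered.
#' @param groups character vector (one per column) with values
#'   `"heterotroph"` / `"autotroph"`.
#' @param hasReferenceOrtholog logical vector, one per gene row.
#' @return character vector of core gene ids.
#' @export
coreGeneSet <- function(presence, groups, hasReferenceOrtholog) {
    if (is.null(rownames(presence)))
        stop("input error: 'presence' must have gene row names", call. = FALSE)
    if (anyDuplicated(rownames(presence)) || anyDuplicated(colnames(presence)))
        stop("input error: duplicated gene or species ids", call. = FALSE)
    if (length(groups) != ncol(presence) ||
        length(hasReferenceOrtholog) != nrow(presence))
        stop("input error: 'groups'/'hasReferenceOrtholog' lengths must ",
             "match the matrix", call. = FALSE)
    autoCols <- which(groups == "autotroph")
    if (!length(autoCols))
        stop("input error: no autotroph species in presence matrix",
             call. = FALSE)
    keep <- hasReferenceOrtholog &
        rowSums(presence[, autoCols, drop = FALSE]) == length(autoCols)
    rownames(presence)[keep]
}

#' Loss sets per heterotroph species relative to a core set
#'
#' @param presence logical gene x species matrix.
#' @param core character vector of core gene ids.
#' @param heteroSpecies character vector of heterotroph column names.
#' @return named list: species -> character vector of core genes absent in it.
#' @export
lossSets <- function(presence, core, heteroSpecies) {
    lapply(stats::setNames(heteroSpecies, heteroSpecies), function(s)
        core[!presence[core, s]])
}

#' Overlap statistics between two loss sets
#'
#' The overlap percentage uses the larger loss set as denominator:
#' `100 * |A intersect B| / max(|A|, |B|)`. The expectation under independent
#' losses is `100 * (|A| * |B| / N) / max(|A|, |B|)`, i.e.
#' `100 * min(|A|, |B|) / N`. The null of uncorrelated losses is tested with
#' the upper-tail hypergeometric probability of seeing at least the observed
#' number of shared losses.
#'
#' @param core character vector (or its size) of core genes.
#' @param lostA,lostB character vectors of lost genes, subsets of the core.
#' @return list with `n_core`, `n_lost_a`, `n_lost_b`, `n_shared`,
#'   `overlap_pct`, `expected_pct`, `p_hypergeom`, `log10_p`.
#' @examples
#' lossOverlap(paste0("g", 1:20), paste0("g", 1:8), paste0("g", 5:10))
#' @export
lossOverlap <- function(core, lostA, lostB) {
    N <- if (is.character(core)) length(core) else as.integer(core)
    if (is.character(core)) {
        if (length(setdiff(lostA, core)) || length(setdiff(lostB, core)))
            stop("input error: loss sets must be subsets of the core set",
                 call. = FALSE)
    }
    nA <- length(lostA); nB <- length(lostB)
    if (nA == 0L || nB == 0L)
        stop("input error: overlap undefined for an empty loss set",
             call. = FALSE)
    nShared <- length(intersect(lostA, lostB))
    hp <- hypergeometricUpperTail(N, nA, nB, nShared)
    list(n_core = N, n_lost_a = nA, n_lost_b = nB, n_shared = nShared,
         overlap_pct = 100 * nShared / max(nA, nB),
         expected_pct = 100 * (nA * nB / N) / max(nA, nB),
         p_hypergeom = hp$p, log10_p = hp$log10_p)
}

#' Upper-tail hypergeometric probability, accurate in log space
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (population `N`, `K`
#' successes, draw of size `n`), computed via the log-space tail of the
#' hypergeometric distribution so that `log10 p` is accurate down to at least
#' -500.
#'
#' @param N population size; `K` successes in the population; `n` draw size;
#'   `k` observed successes.
#' @param K,n,k see above.
#' @return list with `p` (underflows to 0 below ~1e-308) and `log10_p`.
#' @examples
#' hypergeometricUpperTail(10, 5, 5, 5) # p = 1/252
#' @export
hypergeometricUpperTail <- function(N, K, n, k) {
    if (any(c(N, K, n, k) != round(c(N, K, n, k))))
        stop("input error: counts must be integers", call. = FALSE)
    if (k < 0 || K > N || n > N || k > min(K, n))
        stop("input error: need 0 <= k <= min(K, n) <= N", call. = FALSE)
    lp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
    list(p = exp(lp), log10_p = lp / log(10))
}

#' Three-way Venn region counts of loss sets
#'
#' @param lossList named list of exactly three loss-gene character vectors.
#' @return named integer vector of the seven region counts
#'   (`a_only`, `b_only`, `c_only`, `ab`, `ac`, `bc`, `abc`).
#' @export
vennCounts3 <- function(lossList) {
    if (length(lossList) != 3L)
        stop("input error: exactly three loss sets required", call. = FALSE)
    a <- lossList[[1L]]; b <- lossList[[2L]]; cc <- lossList[[3L]]
    inAB <- intersect(a, b); inAC <- intersect(a, cc); inBC <- intersect(b, cc)
    abc <- length(intersect(inAB, cc))
    c(a_only = length(setdiff(a, union(b, cc))),
      b_only = length(setdiff(b, union(a, cc))),
      c_only = length(setdiff(cc, union(a, b))),
      ab = length(inAB) - abc, ac = length(inAC) - abc,
      bc = length(inBC) - abc, abc = abc)
}

#' Pairwise loss-overlap table for all heterotroph pairs
#'
#' @param presence logical gene x species matrix.
#' @param groups group label per column.
#' @param hasReferenceOrtholog logical per gene row.
#' @return data.frame, one row per unordered heterotroph pair, with the
#'   fields of [lossOverlap()].
#' @export
lossOverlapTable <- function(presence, groups, hasReferenceOrtholog) {
    core <- coreGeneSet(presence, groups, hasReferenceOrtholog)
    hets <- colnames(presence)[groups == "heterotroph"]
    losses <- lossSets(presence, core, hets)
    if (length(hets) < 2L)
        stop("input error: need >=2 heterotroph species for overlaps",
             call. = FALSE)
    pairs <- utils::combn(hets, 2L)
    out <- lapply(seq_len(ncol(pairs)), function(i) {
        r <- lossOverlap(core, losses[[pairs[1L, i]]], losses[[pairs[2L, i]]])
        data.frame(species_a = pairs[1L, i], species_b = pairs[2L, i],
                   as.data.frame(r), stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}
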