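#' Likelihood-ratio test between nested branch models
#'
#' Compares a constrained codon model (one dN/dS shared by heterotroph and
#' autotroph branches) with a free model (separate dN/dS for heterotroph
#' branches). The statistic `2 * (lnL_free - lnL_constrained)` is referred to
#' a chi-square with `df` degrees of freedom; a slightly negative difference
#' (optimizer artifact) is clamped to 0 with a warning.
#'
#' @param lnLConstrained,lnLFree log-likelihoods of the nested fits.
#' @param df degrees of freedom (>= 1); the study's two-ratio vs one-ratio
#'   contrasts differ by one parameter.
#' @return list with `statistic` and `p` (floored at 1e-300).
#' @examples
#' likelihoodRatioTest(-1000, -1000 + 3.841459 / 2, df = 1) # p ~ 0.05
#' @export
likelihoodRatioTest <- function(lnLConstrained, lnLFree, df = 1L) {
    if (df < 1L) stop("input error: df must be >= 1", call. = FALSE)
    delta <- lnLFree - lnLConstrained
    if (delta < -1e-6)
        warning("lnL_free < lnL_constrained (optimizer artifact); ",
                "statistic clamped to 0")
    statistic <- max(0, 2 * delta)
    p <- stats::pchisq(statistic, df = df, lower.tail = FALSE)
    list(statistic = statistic, p = max(p, 1e-300))
}

#' Bonferroni adjustment
#'
#' @param p p-value(s).
#' @param m number of tests.
#' @return `min(1, p * m)`, vectorised.
#' @export
bonferroniAdjust <- function(p, m) pmin(1, p * m)

#' Classify a selection shift on heterotroph branches
#'
#' A significant difference with a higher heterotroph dN/dS is labelled
#' `"relaxed"` (selection pressure weakened after the loss of photosynthesis),
#' a significantly lower one `"intensified"`; anything else is `"none"`.
#'
#' @param dndsHetero,dndsAuto branch dN/dS estimates.
#' @param pAdjusted multiplicity-adjusted LRT p-value.
#' @param alpha significance level (default 0.05).
#' @return one of `"relaxed"`, `"intensified"`, `"none"`.
#' @examples
#' classifySelectionShift(0.27, 0.11, 0.02) # "relaxed"
#' @export
classifySelectionShift <- function(dndsHetero, dndsAuto, pAdjusted,
                                   alpha = 0.05) {
    if (pAdjusted > alpha || dndsHetero == dndsAuto) return("none")
    if (dndsHetero > dndsAuto) "relaxed" else "intensified"
}

#' Per-gene LRT table from branch-model fits
#'
#' Consumes precomputed likelihood fits (two rows per gene: `constrained` and
#' `free`), runs the LRT with Bonferroni correction across the gene set, and
#' classifies selection shifts. Fits with a synonymous-rate column `ds`
#' above 0.5 are flagged as saturated (reported, not corrected).
#'
#' @param fits data.frame with columns `gene_id`, `model_label`
#'   (`"constrained"`/`"free"`), `lnL`, `n_params`, `dnds_hetero`,
#'   `dnds_auto`, optionally `ds`.
#' @param m Bonferroni denominator; defaults to the number of genes.
#' @param alpha significance level.
#' @return data.frame with `gene_id`, `statistic`, `df`, `p`, `p_adjusted`,
#'   `shift`, `ds_saturated`.
#' @export
selectionTestTable <- function(fits, m = NULL, alpha = 0.05) {
    need <- c("gene_id", "model_label", "lnL", "n_params",
              "dnds_hetero", "dnds_auto")
    if (!all(need %in% names(fits)))
        stop("input error: fits table must have columns ",
             paste(need, collapse = ", "), call. = FALSE)
    genes <- unique(fits$gene_id)
    if (is.null(m)) m <- length(genes)
    rows <- lapply(genes, function(g) {
        sub <- fits[fits$gene_id == g, ]
        con <- sub[sub$model_label == "constrained", ]
        fre <- sub[sub$model_label == "free", ]
        if (nrow(con) != 1L || nrow(fre) != 1L)
            stop("input error: gene ", g,
                 " needs exactly one constrained and one free fit",
                 call. = FALSE)
        df <- fre$n_params - con$n_params
        if (is.na(df) || df < 1L) df <- 1L
        lrt <- likelihoodRatioTest(con$lnL, fre$lnL, df = df)
        padj <- bonferroniAdjust(lrt$p, m)
        data.frame(
            gene_id = g, statistic = lrt$statistic, df = df, p = lrt$p,
            p_adjusted = padj,
            shift = classifySelectionShift(fre$dnds_hetero, fre$dnds_auto,
                                           padj, alpha),
            ds_saturated = if ("ds" %in% names(fits))
                isTRUE(any(sub$ds > 0.5)) else FALSE,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
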