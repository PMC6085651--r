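#' Ancestor closure for every term of a DAG
#'
#' @param dag a [GoDag-class].
#' @return named list: term id -> character vector of ancestor ids (the term
#'   itself excluded).
#' @export
termAncestors <- function(dag) {
    ord <- dagTopologicalOrder(dag@parents) # roots first
    anc <- vector("list", length(dag@terms))
    names(anc) <- dag@terms
    for (t in ord) {
        ps <- dag@parents[[t]]
        anc[[t]] <-
            if (!length(ps)) character(0)
            else unique(c(ps, unlist(anc[ps], use.names = FALSE)))
    }
    anc
}

#' Propagate gene annotations up the ontology
#'
#' Each gene's term set is replaced by its closure under ancestry: the direct
#' terms plus every term reachable through `is_a` edges ("paternal" terms).
#'
#' @param direct named list: gene id -> character vector of directly assigned
#'   term ids.
#' @param dag a [GoDag-class]; every annotated term must exist in it.
#' @return named list of the same genes with propagated term sets (always a
#'   superset of the input).
#' @examples
#' dag <- buildSyntheticDag(simulationConfig(seed = 1, n_genes = 10,
#'                                           n_terms = 20, planted_terms = 2))
#' propagateAnnotations(list(g1 = dagTerms(dag)[5]), dag)
#' @export
propagateAnnotations <- function(direct, dag) {
    used <- unique(unlist(direct, use.names = FALSE))
    unknown <- setdiff(used, dag@terms)
    if (length(unknown))
        stop("unknown term id(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
    anc <- termAncestors(dag)
    lapply(direct, function(ts) {
        if (!length(ts)) return(character(0))
        unique(c(ts, unlist(anc[ts], use.names = FALSE)))
    })
}

#' Remove organelle-encoded genes from a profile
#'
#' Genes that are 1-1 orthologs of plastid- or mitochondrion-encoded genes are
#' excluded before enrichment so that only nuclear gene content is compared;
#' `nTotal` is recomputed.
#'
#' @param profile a [SpeciesProfile-class].
#' @param exclusionList character vector of gene ids to drop.
#' @return the filtered [SpeciesProfile-class].
#' @export
excludeOrganellar <- function(profile, exclusionList) {
    keep <- !(names(profile@geneTerms) %in% exclusionList)
    speciesProfile(profile@species, profile@clade, profile@group,
                   profile@geneTerms[keep])
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The p-value is the sum of hypergeometric point probabilities of all tables
#' with the observed margins whose probability does not exceed the observed
#' table's (with relative tolerance 1e-7 for ties), the convention of
#' mainstream implementations.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return p-value in (0, 1].
#' @examples
#' fisherExactTwoSided(matrix(c(3, 1, 1, 3), 2)) # 17/35
#' @export
fisherExactTwoSided <- function(table) {
    if (!is.matrix(table) || !all(dim(table) == c(2L, 2L)))
        stop("input error: 'table' must be a 2x2 matrix", call. = FALSE)
    if (any(is.na(table)) || any(table < 0) || any(table != round(table)))
        stop("input error: counts must be non-negative integers",
             call. = FALSE)
    a <- table[1, 1]
    m <- a + table[2, 1]          # column 1 total
    n <- table[1, 2] + table[2, 2] # column 2 total
    k <- a + table[1, 2]          # row 1 total
    if (m + n == 0L || k == 0L || k == m + n) return(1)
    support <- max(0L, k - n):min(k, m)
    d <- stats::dhyper(support, m, n, k)
    min(1, sum(d[d <= d[support == a] * (1 + 1e-7)]))
}

#' Per-term Fisher tests for every heterotroph x autotroph species pair
#'
#' For each ontology term and each heterotroph/autotroph pair within a clade,
#' builds the 2x2 table (genes with the term vs without, per species) and
#' computes the two-sided Fisher p-value. A term is skipped for a pair when
#' neither species of the pair has any gene with the term.
#'
#' @param profiles list of [SpeciesProfile-class] from one clade, containing
#'   at least one heterotroph and one autotroph.
#' @return data.frame with columns `term`, `hetero`, `auto`, `count_h`,
#'   `count_a`, `n_h`, `n_a`, `p`, `delta` (heterotroph fraction minus
#'   autotroph fraction).
#' @export
pairwiseTermTests <- function(profiles) {
    groups <- vapply(profiles, profileGroup, character(1))
    het <- profiles[groups == "heterotroph"]
    aut <- profiles[groups == "autotroph"]
    if (!length(het) || !length(aut))
        stop("input error: need >=1 heterotroph and >=1 autotroph profile",
             call. = FALSE)
    counts <- lapply(profiles, function(p)
        table(unlist(p@geneTerms, use.names = FALSE)))
    names(counts) <- vapply(profiles, function(p) p@species, character(1))
    ntot <- vapply(profiles, nTotal, numeric(1))
    names(ntot) <- names(counts)
    termCount <- function(sp, terms) {
        out <- as.integer(counts[[sp]][terms])
        out[is.na(out)] <- 0L
        out
    }
    res <- list()
    for (h in vapply(het, function(p) p@species, character(1))) {
        for (a in vapply(aut, function(p) p@species, character(1))) {
            terms <- union(names(counts[[h]]), names(counts[[a]]))
            if (!length(terms)) next
            ch <- termCount(h, terms)
            ca <- termCount(a, terms)
            nh <- ntot[[h]]; na <- ntot[[a]]
            p <- vapply(seq_along(terms), function(i)
                fisherExactTwoSided(matrix(c(ch[i], nh - ch[i],
                                             ca[i], na - ca[i]), 2L)),
                numeric(1))
            res[[length(res) + 1L]] <- data.frame(
                term = terms, hetero = h, auto = a,
                count_h = ch, count_a = ca, n_h = nh, n_a = na, p = p,
                delta = ch / nh - ca / na,
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, res)
}

#' Bonferroni aggregation of pairwise tests for one term
#'
#' A term is called group-wise significant only when every heterotroph x
#' autotroph pair shifts in the same direction; the group p-value is then the
#' Bonferroni bound `n_pairs * max(pairwise p)`. Pairs with equal fractions
#' are compatible with either direction. If pairs disagree, the direction is
#' `"mixed"` and the group p-value is 1.
#'
#' @param tests data.frame of rows from [pairwiseTermTests()] for a single
#'   term (columns `p` and `delta`).
#' @param aggregate `"max"` (default, intersection-style) or `"min"`
#'   (`n_pairs * min p`).
#' @return list with `p_group` and `direction` (`"under"`, `"over"`, or
#'   `"mixed"`).
#' @export
groupSignificance <- function(tests, aggregate = c("max", "min")) {
    aggregate <- match.arg(aggregate)
    if (nrow(tests) < 1L)
        stop("input error: no tests supplied", call. = FALSE)
    s <- sign(tests$delta)
    if (any(s > 0) && any(s < 0))
        return(list(p_group = 1, direction = "mixed"))
    direction <- if (any(s < 0)) "under" else if (any(s > 0)) "over"
                 else "mixed"
    agg <- if (aggregate == "max") max(tests$p) else min(tests$p)
    list(p_group = min(1, nrow(tests) * agg), direction = direction)
}

#' Benjamini-Yekutieli adjusted p-values
#'
#' Step-up FDR control valid under arbitrary dependence: with `m` p-values and
#' `c(m) = sum(1/k, k = 1..m)`, the sorted p-value `p_(j)` is inflated to
#' `m * c(m) * p_(j) / j` before the step-up minimisation.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @examples
#' benjaminiYekutieli(c(0.01, 0.04)) # 0.03 0.06
#' @export
benjaminiYekutieli <- function(p) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("input error: p-values must lie in [0, 1]", call. = FALSE)
    stats::p.adjust(p, method = "BY")
}

#' Median ratio of annotated-gene fractions for one term
#'
#' For every heterotroph x autotroph pair the ratio of per-species fractions
#' `(count_h / n_h) / (count_a / n_a)` is formed; pairs where both species
#' have zero genes with the term are skipped, and a zero autotroph fraction
#' against a positive heterotroph fraction yields `Inf`. The statistic is the
#' median of the remaining ratios (even count: mean of the central two;
#' reported as `Inf` when either central element is infinite).
#'
#' @param tests data.frame of rows from [pairwiseTermTests()] for one term.
#' @return numeric scalar (possibly `Inf`), or `NA_real_` when no pair is
#'   eligible.
#' @export
medianRatioOfFractions <- function(tests) {
    keep <- !(tests$count_h == 0L & tests$count_a == 0L)
    tests <- tests[keep, , drop = FALSE]
    if (!nrow(tests)) return(NA_real_)
    fh <- tests$count_h / tests$n_h
    fa <- tests$count_a / tests$n_a
    r <- ifelse(fa == 0, ifelse(fh > 0, Inf, NaN), fh / fa)
    r <- r[!is.nan(r)]
    if (!length(r)) return(NA_real_)
    r <- sort(r)
    n <- length(r)
    if (n %% 2L == 1L) return(r[(n + 1L) %/% 2L])
    lo <- r[n %/% 2L]; hi <- r[n %/% 2L + 1L]
    if (is.infinite(hi)) Inf else (lo + hi) / 2
}

#' Group-wise enrichment table for one clade
#'
#' Runs the whole group comparison: per-term pairwise Fisher tests, Bonferroni
#' aggregation across pairs, Benjamini-Yekutieli correction across terms, and
#' the median ratio of fractions. Organelle-encoded genes are removed first.
#'
#' @param profiles list of [SpeciesProfile-class] for one clade.
#' @param alpha significance level on the q-value (default 0.05).
#' @param organellarExclusion character vector of gene ids to exclude before
#'   testing (default none).
#' @param aggregate passed to [groupSignificance()].
#' @return data.frame with one row per tested term: per-species counts
#'   (columns `count.<species>`), `n_pairs`, `p_group`, `q`, `median_ratio`,
#'   `direction`, `significant`; sorted by `q` then `median_ratio`.
#' @export
enrichmentTable <- function(profiles, alpha = 0.05,
                            organellarExclusion = character(0),
                            aggregate = "max") {
    if (length(organellarExclusion))
        profiles <- lapply(profiles, excludeOrganellar, organellarExclusion)
    if (any(vapply(profiles, nTotal, numeric(1)) == 0L))
        stop("input error: a species has no annotated genes left after ",
             "exclusion; clade skipped", call. = FALSE)
    tests <- pairwiseTermTests(profiles)
    spp <- unique(c(tests$hetero, tests$auto))
    byTerm <- split(tests, tests$term)
    rows <- lapply(byTerm, function(tt) {
        g <- groupSignificance(tt, aggregate = aggregate)
        cnt <- vapply(spp, function(s) {
            i <- which(tt$hetero == s | tt$auto == s)[1L]
            if (is.na(i)) NA_integer_
            else if (tt$hetero[i] == s) tt$count_h[i] else tt$count_a[i]
        }, integer(1))
        out <- data.frame(term = tt$term[1L], n_pairs = nrow(tt),
                          p_group = g$p_group,
                          median_ratio = medianRatioOfFractions(tt),
                          direction = g$direction, stringsAsFactors = FALSE)
        for (s in spp) out[[paste0("count.", s)]] <- cnt[[s]]
        out
    })
    out <- do.call(rbind, rows)
    out$q <- benjaminiYekutieli(out$p_group)
    out$significant <- out$q <= alpha
    out <- out[order(out$q, out$median_ratio, out$term), ]
    rownames(out) <- NULL
    out[, c("term", grep("^count\\.", names(out), value = TRUE), "n_pairs",
            "p_group", "q", "median_ratio", "direction", "significant")]
}
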