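chainDag <- function() {
    # root <- t2 <- t3; t4 also child of t2 (two leaves)
    new("GoDag", terms = c("r", "t2", "t3", "t4"),
        termName = paste("term", 1:4), namespace = rep("bp", 4),
        parents = list(r = character(0), t2 = "r", t3 = "t2", t4 = "t2"),
        obsolete = rep(FALSE, 4), planted = rep(FALSE, 4))
}

test_that("annotation propagation closes term sets under ancestry", {
    dag <- chainDag()
    expect_identical(propagateAnnotations(list(g = "r"), dag)$g, "r")
    got <- propagateAnnotations(list(g = "t3"), dag)$g
    expect_setequal(got, c("t3", bfsAncestors("t3", dagEdges(dag))))
    expect_error(propagateAnnotations(list(g = "nope"), dag), "nope")
    # closure against the BFS oracle on a random DAG
    dag2 <- buildSyntheticDag(simulationConfig(seed = 4, n_genes = 10,
                                               n_terms = 40, dag_depth = 5,
                                               planted_terms = 2))
    edges <- dagEdges(dag2)
    for (t in sample(dagTerms(dag2), 10))
        expect_setequal(propagateAnnotations(list(g = t), dag2)$g,
                        c(t, bfsAncestors(t, edges)))
    # propagated sets are supersets, independent of annotation order
    direct <- list(g1 = sample(dagTerms(dag2), 3), g2 = dagTerms(dag2)[1])
    prop <- propagateAnnotations(direct, dag2)
    expect_true(all(direct$g1 %in% prop$g1))
})

test_that("organellar exclusion removes genes and recomputes totals", {
    gt <- list(g1 = c("t2", "r"), g2 = "t3", g3 = character(0))
    pr <- speciesProfile("S", "cl", "autotroph", gt)
    expect_equal(nTotal(pr), 2L)
    expect_identical(excludeOrganellar(pr, character(0))@geneTerms, gt)
    ex <- excludeOrganellar(pr, c("g1", "g3"))
    expect_equal(nTotal(ex), 1L)
    expect_identical(names(ex@geneTerms), "g2")
    allEx <- excludeOrganellar(pr, c("g1", "g2", "g3"))
    expect_equal(nTotal(allEx), 0L)
    expect_error(enrichmentTable(list(allEx, allEx)), "no annotated genes")
})

test_that("two-sided Fisher matches closed forms and stats::fisher.test", {
    expect_equal(fisherExactTwoSided(matrix(c(0, 0, 5, 5), 2)), 1.0)
    expect_equal(fisherExactTwoSided(matrix(c(3, 1, 1, 3), 2)), 17 / 35)
    expect_error(fisherExactTwoSided(matrix(c(-1, 1, 1, 1), 2)),
                 "non-negative")
    set.seed(9)
    for (i in 1:25) {
        tab <- matrix(rpois(4, 8), 2)
        expect_equal(fisherExactTwoSided(tab),
                     stats::fisher.test(tab)$p.value, tolerance = 1e-10)
    }
})

test_that("pairwise tests cover exactly the heterotroph x autotroph grid", {
    dag <- chainDag()
    mk <- function(sp, grp, terms) {
        gt <- setNames(as.list(terms), paste0(sp, seq_along(terms)))
        speciesProfile(sp, "cl", grp, propagateAnnotations(gt, dag))
    }
    h1 <- mk("h1", "heterotroph", c("t3", "t4"))
    h2 <- mk("h2", "heterotroph", c("t3", "t4"))
    a1 <- mk("a1", "autotroph", c("t3", "t4"))
    a2 <- mk("a2", "autotroph", c("t3", "t4"))
    a3 <- mk("a3", "autotroph", c("t3", "t4"))
    tt <- pairwiseTermTests(list(h1, h2, a1, a2, a3))
    # 2 het x 3 auto = 6 tests per term; identical profiles give p = 1
    expect_true(all(table(tt$term) == 6L))
    expect_equal(tt$p, rep(1, nrow(tt)))
    # a term carried by no species is never tested
    expect_false("t9" %in% tt$term)
    expect_error(pairwiseTermTests(list(h1, h2)), "autotroph")
})

test_that("group aggregation: agreement, mixing and the Bonferroni bound", {
    und <- data.frame(p = c(.001, .002, .004, .02, .03, .04), delta = -0.1)
    g <- groupSignificance(und)
    expect_equal(g$p_group, 6 * 0.04)
    expect_identical(g$direction, "under")
    one <- groupSignificance(data.frame(p = 0.01, delta = 0.2))
    expect_equal(one$p_group, 0.01)
    expect_identical(one$direction, "over")
    mix <- groupSignificance(data.frame(p = c(.001, .001),
                                        delta = c(-1, 1) * 0.1))
    expect_equal(mix$p_group, 1)
    expect_identical(mix$direction, "mixed")
    expect_error(groupSignificance(und[0, ]), "no tests")
})

test_that("Benjamini-Yekutieli equals the direct formula and dominates BH", {
    expect_equal(benjaminiYekutieli(0.2), 0.2)
    expect_equal(benjaminiYekutieli(c(0.01, 0.04)), c(0.03, 0.06))
    expect_error(benjaminiYekutieli(c(0.1, 1.2)), "\\[0, 1\\]")
    set.seed(13)
    for (i in 1:20) {
        p <- runif(sample(1:40, 1))
        q <- benjaminiYekutieli(p)
        expect_equal(q, directBY(p), tolerance = 1e-12)
        expect_true(all(q >= p.adjust(p, "BH") - 1e-12))
        expect_true(all(diff(sort(q)[order(order(p))][order(p)]) >= -1e-12))
    }
})

test_that("median ratio of fractions handles zeros and infinities", {
    mk <- function(ch, ca, nh = 100, na = 100)
        data.frame(count_h = ch, count_a = ca, n_h = nh, n_a = na)
    expect_equal(medianRatioOfFractions(mk(c(5, 5), c(5, 5))), 1.0)
    # hetero fractions {0.01, 0.02} vs auto {0.04, 0.05, 0.04}
    tt <- mk(ch = rep(c(1, 2), each = 3), ca = rep(c(4, 5, 4), 2))
    expect_equal(medianRatioOfFractions(tt), 0.325)
    expect_equal(medianRatioOfFractions(mk(c(0, 0), c(10, 10))), 0.0)
    expect_equal(medianRatioOfFractions(mk(5, 0)), Inf)
    # both-zero pairs are skipped; no eligible pair -> NA
    expect_true(is.na(medianRatioOfFractions(mk(0, 0))))
})

test_that("planted depletion ranks planted terms at the top of the table", {
    cfg <- simulationConfig(seed = 21)
    dag <- buildSyntheticDag(cfg)
    inv <- simulateInventories(cfg, dag)
    prof <- speciesProfilesFromInventories(inv, dag)
    tab <- enrichmentTable(prof, organellarExclusion = inv$organellar)
    expect_equal(nrow(tab), length(unique(pairwiseTermTests(
        lapply(prof, excludeOrganellar, inv$organellar))$term)))
    planted <- plantedTerms(dag)
    # propagation makes the planted terms' ancestors depleted as well, so
    # the top of the table is planted terms plus their ancestry
    anc <- termAncestors(dag)
    depleted <- unique(c(planted, unlist(anc[planted], use.names = FALSE)))
    top <- tab$term[seq_along(planted)]
    expect_true(all(top %in% depleted))
    sub <- tab[tab$term %in% planted, ]
    expect_true(all(sub$direction == "under"))
    expect_true(all(sub$q >= sub$p_group))
})
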