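smallCfg <- function(seed = 1, ...) {
    simulationConfig(seed = seed, n_genes = 120, n_terms = 30,
                     dag_depth = 4, planted_terms = 3, ...)
}

test_that("DAG construction: degenerate, deterministic, acyclic, rooted", {
    one <- simulationConfig(seed = 1, n_genes = 5, n_terms = 1,
                            dag_depth = 1, planted_terms = 0)
    dag1 <- buildSyntheticDag(one)
    expect_equal(length(dag1), 1L)
    expect_equal(nrow(dagEdges(dag1)), 0L)

    cfg <- simulationConfig(seed = 1)
    expect_identical(dagEdges(buildSyntheticDag(cfg)),
                     dagEdges(buildSyntheticDag(cfg)))

    # acyclicity by explicit depth-first search on the edge list
    for (s in 1:5) {
        dag <- buildSyntheticDag(smallCfg(seed = s))
        edges <- dagEdges(dag)
        state <- setNames(integer(length(dag)), dagTerms(dag))
        dfs <- function(v) {
            if (state[[v]] == 1L) return(FALSE) # back edge = cycle
            if (state[[v]] == 2L) return(TRUE)
            state[[v]] <<- 1L
            for (p in edges$parent[edges$child == v])
                if (!dfs(p)) return(FALSE)
            state[[v]] <<- 2L
            TRUE
        }
        expect_true(all(vapply(dagTerms(dag), dfs, logical(1))))
        # every non-root term has >=1 parent; planted terms are leaves
        expect_equal(sum(!dagTerms(dag) %in% edges$child), 1L)
        expect_length(plantedTerms(dag), 3L)
        expect_false(any(plantedTerms(dag) %in% edges$parent))
    }
})

test_that("invalid configurations are rejected with the field named", {
    expect_error(simulationConfig(seed = 1, loss_p_planted = 1.5),
                 "loss_p_planted")
    expect_error(simulationConfig(seed = 1, n_auto = 1), "n_auto")
    expect_error(simulationConfig(seed = 1, n_terms = 3, dag_depth = 5),
                 "n_terms")
    expect_error(simulationConfig(seed = 1.5), "seed")
})

test_that("inventory limits: no loss and forced loss", {
    cfg <- smallCfg(loss_p_planted = 0, loss_p_background = 0)
    inv <- simulateInventories(cfg, buildSyntheticDag(cfg))
    auto <- inv$species$species[inv$species$group == "autotroph"][1]
    for (h in inv$species$species[inv$species$group == "heterotroph"])
        expect_setequal(inv$inventories[[h]], inv$inventories[[auto]])

    cfg2 <- smallCfg(loss_p_planted = 1, shared_loss_frac = 1)
    inv2 <- simulateInventories(cfg2, buildSyntheticDag(cfg2))
    for (h in inv2$species$species[inv2$species$group == "heterotroph"])
        expect_length(intersect(inv2$plantedGenes, inv2$inventories[[h]]), 0L)
})

test_that("shared-loss fraction controls pairwise loss overlap", {
    overlapAt <- function(c, seed) {
        cfg <- simulationConfig(seed = seed, n_genes = 200, n_terms = 10,
                                dag_depth = 3, planted_terms = 2,
                                loss_p_planted = 0.3,
                                loss_p_background = 0.3,
                                shared_loss_frac = c)
        inv <- simulateInventories(cfg, buildSyntheticDag(cfg))
        hets <- inv$species$species[inv$species$group == "heterotroph"]
        all <- sprintf("g%05d", 1:200)
        la <- setdiff(all, inv$inventories[[hets[1]]])
        lb <- setdiff(all, inv$inventories[[hets[2]]])
        if (!length(la) || !length(lb)) return(NA_real_)
        100 * length(intersect(la, lb)) / max(length(la), length(lb))
    }
    m0 <- mean(vapply(1:50, function(s) overlapAt(0, s), numeric(1)),
               na.rm = TRUE)
    m1 <- mean(vapply(1:50, function(s) overlapAt(1, s), numeric(1)),
               na.rm = TRUE)
    expect_gt(m1, m0)
})

test_that("transcript tables honour contamination and isoform settings", {
    cfg <- smallCfg(contamination_frac = 0, isoform_lambda = 0)
    inv <- simulateInventories(cfg, buildSyntheticDag(cfg))
    tr <- simulateTranscripts(cfg, inv)
    expect_false(any(tr$records$is_contaminant))
    expect_true(all(table(tr$records$gene_id, tr$records$species) <= 1))
    # every plant source taxon is Streptophyta
    tax <- tr$taxonomy
    lin <- setNames(tax$lineage, tax$taxon)
    expect_true(all(grepl("Streptophyta", lin[tr$records$source_taxon])))
})

test_that("FASTA and transcript table agree on identifiers", {
    cfg <- smallCfg()
    inv <- simulateInventories(cfg, buildSyntheticDag(cfg))
    tr <- simulateTranscripts(cfg, inv)
    tmp <- withr::local_tempdir()
    fa <- file.path(tmp, "t.fasta")
    writeTranscriptFasta(tr$records, fa)
    seqs <- Biostrings::readDNAStringSet(fa)
    expect_setequal(names(seqs), tr$records$transcript_id)
    expect_identical(unname(as.character(seqs[tr$records$transcript_id])),
                     tr$records$sequence)
})

test_that("noise-free hit tables carry the planted truth", {
    cfg <- smallCfg(hit_noise = 0, rbh_corruption = 0)
    inv <- simulateInventories(cfg, buildSyntheticDag(cfg))
    tr <- simulateTranscripts(cfg, inv)
    hits <- simulateHitTables(cfg, tr)
    # contamination classifier recovers labels exactly
    cls <- vapply(tr$records$transcript_id, function(id)
        classifyTaxonomy(hits$contamination[
            hits$contamination$query == id, , drop = FALSE]), character(1))
    expect_identical(unname(cls == "CONTAMINANT"), tr$records$is_contaminant)
    # RBH recovers all true pairs
    h1 <- hits$ortholog[[1]]
    rbh <- reciprocalBestHits(h1$ab, h1$ba)
    expect_setequal(paste(rbh$gene_a, rbh$gene_b),
                    paste(h1$truth$gene, h1$truth$ref))
})

test_that("best-hit corruption reduces RBH recall below 1", {
    cfg <- smallCfg(rbh_corruption = 0.2)
    inv <- simulateInventories(cfg, buildSyntheticDag(cfg))
    tr <- simulateTranscripts(cfg, inv)
    hits <- simulateHitTables(cfg, tr)
    h1 <- hits$ortholog[[1]]
    rbh <- reciprocalBestHits(h1$ab, h1$ba)
    recall <- sum(paste(rbh$gene_a, rbh$gene_b) %in%
                  paste(h1$truth$gene, h1$truth$ref)) / nrow(h1$truth)
    expect_lt(recall, 1)
    expect_gt(recall, 0.5)
})

test_that("targeting predictions reflect planted signals", {
    cfg <- smallCfg(frac_dual = 1, frac_plastid_signal = 0,
                    frac_mito_signal = 0)
    targ <- simulateTargeting(cfg, sprintf("p%03d", 1:100))
    scores <- targ$predictions$dual_score[
        targ$predictions$tool == "classB"]
    expect_true(all(scores >= 0.5))

    cfg2 <- smallCfg(frac_plastid_signal = 1, frac_mito_signal = 0,
                     frac_dual = 0)
    targ2 <- simulateTargeting(cfg2, sprintf("p%03d", 1:50))
    v <- targetingVerdicts(targ2$predictions)
    expect_true(all(v$verdict == "plastid"))
})

test_that("reliability-class mixture matches its configuration within 3 sigma", {
    cfg <- simulationConfig(seed = 3, frac_plastid_signal = 1,
                            frac_mito_signal = 0, frac_dual = 0)
    targ <- simulateTargeting(cfg, sprintf("p%04d", 1:2000))
    rc <- targ$predictions$reliability[
        targ$predictions$tool == "classA" &
        targ$predictions$variant == "full"]
    n <- length(rc)
    probs <- c(0.4, 0.3, 0.2, 0.1)
    for (k in 1:4) {
        se <- sqrt(probs[k] * (1 - probs[k]) / n)
        expect_lt(abs(mean(rc == k) - probs[k]), 3 * se)
    }
})

test_that("one seed fixes every written output byte for byte", {
    cfg <- smallCfg(seed = 11)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    writeSyntheticData(simulateStudy(cfg), d1)
    writeSyntheticData(simulateStudy(cfg), d2)
    files <- list.files(d1)
    expect_true(length(files) > 5)
    for (f in files)
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)),
                         label = f)
})

test_that("OBO writer and parser round-trip the DAG", {
    dag <- buildSyntheticDag(smallCfg())
    tmp <- withr::local_tempfile(fileext = ".obo")
    writeObo(dag, tmp)
    back <- readObo(tmp)
    expect_identical(dagTerms(back), dagTerms(dag))
    expect_identical(dagEdges(back), dagEdges(dag))
})
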