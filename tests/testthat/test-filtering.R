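recTable <- function(...) {
    data.frame(..., stringsAsFactors = FALSE)
}

test_that("major isoform selection follows the max-reads rule with a
           deterministic tie-break", {
    rec <- recTable(transcript_id = c("i1", "i2"), gene_id = "g",
                    mapped_reads = c(100, 50))
    expect_identical(unname(selectMajorIsoforms(rec)), "i1")
    tie <- recTable(transcript_id = c("i2", "i1"), gene_id = "g",
                    mapped_reads = c(100, 100))
    expect_identical(unname(selectMajorIsoforms(tie)), "i1")
    expect_error(selectMajorIsoforms(
        recTable(transcript_id = c("i1", "i1"), gene_id = c("g1", "g2"),
                 mapped_reads = 1:2)), "duplicated")
    # one selected isoform per simulated gene
    cfg <- simulationConfig(seed = 2, n_genes = 500, n_terms = 10,
                            dag_depth = 3, planted_terms = 2,
                            contamination_frac = 0)
    inv <- simulateInventories(cfg, buildSyntheticDag(cfg))
    tr <- simulateTranscripts(cfg, inv)
    sub <- tr$records[tr$records$species == "AUT1", ]
    expect_length(selectMajorIsoforms(sub), 500L)
})

test_that("coverage filter is inclusive at the threshold", {
    rec <- recTable(transcript_id = c("a", "b", "c"), gene_id = "g",
                    mean_coverage = c(3.0, 2.999, 10))
    kept <- filterLowCoverage(rec)
    expect_setequal(kept$transcript_id, c("a", "c"))
    expect_identical(nrow(filterLowCoverage(rec[0, ])), 0L)
    # idempotent and order-invariant
    expect_identical(filterLowCoverage(kept), kept)
    shuf <- rec[c(3, 1, 2), ]
    expect_setequal(filterLowCoverage(shuf)$transcript_id,
                    kept$transcript_id)
})

test_that("CDS selection: boundary length, stop-only input, strand/coords", {
    # CTA codons read as stops (TAG) on the reverse strand, so the forward
    # 30-codon frame is the only qualifying stretch
    s30 <- paste0("ATG", strrep("CTA", 29), "TAA")
    orf <- findCandidateOrfs(s30)
    expect_equal(orf$aa_length, 30)
    expect_equal(orf$start, 1)
    expect_equal(orf$end, 90)
    expect_identical(orf$strand, "+")
    expect_equal(orf$aa_length, floor((orf$end - orf$start + 1) / 3))
    # one codon short of the threshold: rejected
    expect_null(findCandidateOrfs(paste0("ATG", strrep("CTA", 28), "TAA")))
    # stop codons everywhere: nothing at the default threshold
    expect_null(findCandidateOrfs(strrep("TAA", 10)))
    expect_error(findCandidateOrfs("ATGU"), "illegal")
    # a sub-threshold stretch qualifies when it carries a domain hit
    dom <- findCandidateOrfs(paste0("ATG", strrep("CTA", 10), "TAA"),
                             domainHits = data.frame(start = 5, end = 20))
    expect_false(is.null(dom))
    expect_true(dom$has_domain)
    expect_lt(dom$aa_length, 30)
})

test_that("selected CDS length equals the brute-force six-frame oracle", {
    set.seed(42)
    for (i in 1:15) {
        seq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                     collapse = "")
        orf <- findCandidateOrfs(seq, minCdsAa = 1)
        expect_equal(orf$aa_length, bruteLongestOrf(seq))
        # the reported interval is stop-free in the reported frame
        cds <- substr(seq, orf$start, orf$end)
        if (orf$strand == "-")
            cds <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(cds)))
        aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
        expect_false(grepl("*", aa, fixed = TRUE))
    }
})

test_that("five_prime_complete requires an ATG start with upstream context", {
    # a fixed 35-codon sense body whose reverse strand is stop-rich and
    # whose codon-aligned reading contains no ATG
    body <- paste0("GGGAGCATTAGTTCTAATGTGGATATTAAATTAGTTAAGAGTAGGCGGAAC",
                   "GCTCAGGCCCATTCAGACCTTAGTGTCTTGCTATGTCGACCGTTTGGGCGTGCT")
    # ATG at position 4 (3 nt of UTR): complete
    hit <- findCandidateOrfs(paste0("CCC", "ATG", body, "TAA"))
    expect_identical(hit$strand, "+")
    expect_true(hit$five_prime_complete)
    # ATG flush with the transcript edge: possible truncation artifact
    edge <- findCandidateOrfs(paste0("ATG", body, "TAA"))
    expect_false(edge$five_prime_complete)
    # an upstream in-frame stop also certifies the start
    stopped <- findCandidateOrfs(paste0("TGA", "ATG", body, "TAA"))
    expect_true(stopped$five_prime_complete)
    # no ATG anywhere in the stretch: never complete
    noatg <- findCandidateOrfs(paste0("CCC", body, "TAA"))
    expect_false(noatg$five_prime_complete)
})

test_that("taxonomy classification follows the best bit score", {
    cfgF <- filterConfig()
    fung <- "cellular organisms;Eukaryota;Fungi;Basidiomycota"
    plant <- "cellular organisms;Eukaryota;Viridiplantae;Streptophyta"
    hits <- data.frame(bit_score = c(200, 150), lineage = c(fung, plant))
    expect_identical(classifyTaxonomy(hits, cfgF), "CONTAMINANT")
    expect_identical(classifyTaxonomy(hits[c(2, 1), ], cfgF), "CONTAMINANT")
    expect_identical(classifyTaxonomy(NULL, cfgF), "PLANT")
    expect_identical(classifyTaxonomy(hits[0, ], cfgF), "PLANT")
    tie <- data.frame(bit_score = c(200, 200), lineage = c(fung, plant))
    expect_identical(classifyTaxonomy(tie, cfgF), "PLANT")
})

test_that("reciprocal best hits: rules and brute-force equivalence", {
    ab <- data.frame(query = c("a1", "a2"), subject = c("b1", "b2"),
                     bit_score = c(100, 90))
    ba <- data.frame(query = c("b1", "b2"), subject = c("a1", "a2"),
                     bit_score = c(100, 90))
    expect_equal(nrow(reciprocalBestHits(ab, ba)), 2L)
    # a's best is b, but b's best is a different gene: no pair for a
    ba2 <- data.frame(query = c("b1", "b2"), subject = c("a9", "a2"),
                      bit_score = c(100, 90))
    expect_identical(reciprocalBestHits(ab, ba2)$gene_a, "a2")
    # a bit-score tie between two subjects voids the query
    abT <- data.frame(query = "a1", subject = c("b1", "b2"),
                      bit_score = c(50, 50))
    baT <- data.frame(query = c("b1", "b2"), subject = "a1",
                      bit_score = c(50, 40))
    expect_equal(nrow(reciprocalBestHits(abT, baT)), 0L)
    # random 50-gene tables equal the double-loop oracle
    set.seed(7)
    for (rep in 1:3) {
        g <- sprintf("a%02d", 1:50); r <- sprintf("b%02d", 1:50)
        ab <- data.frame(query = sample(g, 200, TRUE),
                         subject = sample(r, 200, TRUE),
                         bit_score = sample(50:500, 200, TRUE))
        ba <- data.frame(query = sample(r, 200, TRUE),
                         subject = sample(g, 200, TRUE),
                         bit_score = sample(50:500, 200, TRUE))
        got <- reciprocalBestHits(ab, ba)
        expect_identical(sort(paste(got$gene_a, got$gene_b, sep = "\t")),
                         bruteRbh(ab, ba))
    }
})

test_that("gene expression sums over isoforms and conserves totals", {
    rec <- recTable(gene_id = c("g1", "g1", "g2"), fpkm = c(1.5, 2.5, 7))
    s <- sumGeneExpression(rec)
    expect_equal(s[["g1"]], 4.0)
    expect_equal(s[["g2"]], 7)
    expect_equal(sum(s), sum(rec$fpkm))
    expect_length(sumGeneExpression(rec[0, ]), 0L)
})

test_that("full filtering run reports per-step counts and is order-invariant", {
    cfg <- simulationConfig(seed = 5, n_genes = 80, n_terms = 10,
                            dag_depth = 3, planted_terms = 2, cov_sigma = 0)
    inv <- simulateInventories(cfg, buildSyntheticDag(cfg))
    tr <- simulateTranscripts(cfg, inv)
    hits <- simulateHitTables(cfg, tr)
    sub <- tr$records[tr$records$species == "HET1", ]
    out <- filterTranscriptome(sub, hits$contamination)
    expect_identical(out$report$step,
                     c("input", "major_isoform", "coverage", "cds",
                       "taxonomy"))
    expect_true(all(diff(out$report$transcripts) <= 0))
    shuffled <- filterTranscriptome(sub[sample(nrow(sub)), ],
                                    hits$contamination)
    expect_setequal(shuffled$genes, out$genes)
})
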