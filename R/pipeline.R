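#' Species profiles from simulated (or observed) inventories
#'
#' Builds one [SpeciesProfile-class] per species: each present gene keeps its
#' direct terms, propagated up the DAG.
#'
#' @param inventories list as returned by [simulateInventories()] (components
#'   `species`, `inventories`, `direct`).
#' @param dag a [GoDag-class].
#' @return named list of [SpeciesProfile-class] objects.
#' @export
speciesProfilesFromInventories <- function(inventories, dag) {
    propagated <- propagateAnnotations(inventories$direct, dag)
    out <- lapply(seq_len(nrow(inventories$species)), function(i) {
        sp <- inventories$species$species[i]
        genes <- inventories$inventories[[sp]]
        speciesProfile(sp, inventories$species$clade[i],
                       inventories$species$group[i], propagated[genes])
    })
    stats::setNames(out, inventories$species$species)
}

#' Run the whole comparative pipeline on synthetic data
#'
#' Executes simulate -> filter -> enrich -> loss -> targeting -> selection
#' under a single seed and writes per-stage TSVs, a machine-readable JSON
#' summary, and a short human-readable summary into `outDir`. Every random
#' draw derives from `config@seed`, so a rerun with the same config
#' reproduces every output byte for byte.
#'
#' @param config a [simulationConfig()].
#' @param outDir output directory.
#' @param filterCfg a [filterConfig()].
#' @param alpha q-value significance level for the enrichment (default 0.05).
#' @return invisibly, the summary list.
#' @export
runPipeline <- function(config, outDir, filterCfg = filterConfig(),
                        alpha = 0.05) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    p <- function(...) file.path(outDir, ...)
    stage <- function(name, expr) {
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch(expr, error = function(e)
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
        message(sprintf("[%s] done in %.1fs", name,
                        proc.time()[["elapsed"]] - t0))
        res
    }

    sim <- stage("simulate", {
        s <- simulateStudy(config)
        writeSyntheticData(s, p("inputs"))
        s
    })

    filt <- stage("filter", {
        rec <- sim$transcripts$records
        out <- lapply(split(rec, rec$species), function(sub)
            filterTranscriptome(sub, sim$hits$contamination, filterCfg))
        rep <- do.call(rbind, lapply(names(out), function(sp)
            cbind(species = sp, out[[sp]]$report)))
        writeTsv(rep, p("filtering_report.tsv"),
                 meta = "transcripts surviving each filter step")
        out
    })

    orth <- stage("orthology", {
        pairs <- lapply(sim$hits$ortholog, function(h)
            reciprocalBestHits(h$ab, h$ba))
        for (sp in names(pairs))
            writeTsv(pairs[[sp]], p(sprintf("orthologs_%s.tsv", sp)))
        pairs
    })

    enr <- stage("enrich", {
        profiles <- speciesProfilesFromInventories(sim$inventories, sim$dag)
        # restrict each profile to the genes that survived filtering
        profiles <- lapply(profiles, function(pr) {
            genes <- intersect(names(pr@geneTerms),
                               filt[[pr@species]]$genes)
            speciesProfile(pr@species, pr@clade, pr@group,
                           pr@geneTerms[genes])
        })
        tab <- enrichmentTable(profiles, alpha = alpha,
                               organellarExclusion =
                                   sim$inventories$organellar)
        writeTsv(tab, p("enrichment.tsv"),
                 meta = "group-wise GO enrichment (q = Benjamini-Yekutieli)")
        tab
    })

    loss <- stage("loss", {
        species <- sim$inventories$species$species
        allGenes <- sprintf("g%05d", seq_len(config@n_genes))
        presence <- vapply(species, function(sp)
            allGenes %in% filt[[sp]]$genes, logical(length(allGenes)))
        rownames(presence) <- allGenes
        hasRef <- allGenes %in% unlist(lapply(orth, function(o) o$gene_a),
                                       use.names = FALSE)
        groups <- sim$inventories$species$group
        hets <- species[groups == "heterotroph"]
        if (length(hets) >= 2L) {
            tab <- lossOverlapTable(presence, groups, hasRef)
            writeTsv(tab, p("loss_overlap.tsv"),
                     meta = paste("gene absence is transcriptome-based and",
                                  "should be interpreted with caution"))
            if (length(hets) == 3L) {
                core <- coreGeneSet(presence, groups, hasRef)
                venn <- vennCounts3(lossSets(presence, core, hets))
                writeTsv(data.frame(region = names(venn),
                                    n = as.integer(venn)),
                         p("loss_venn.tsv"))
            }
            tab
        } else NULL
    })

    targ <- stage("targeting", {
        v <- targetingVerdicts(sim$targeting$predictions)
        writeTsv(v, p("targeting_verdicts.tsv"))
        v
    })

    sel <- stage("selection", {
        tab <- selectionTestTable(sim$fits)
        writeTsv(tab, p("selection_lrt.tsv"))
        tab
    })

    summary <- list(
        seed = config@seed,
        filtering = lapply(filt, function(f)
            stats::setNames(as.list(f$report$transcripts), f$report$step)),
        significant_terms = enr$term[enr$significant],
        n_significant = sum(enr$significant),
        loss_overlap = if (!is.null(loss))
            lapply(seq_len(nrow(loss)), function(i) as.list(loss[i, ])),
        verdict_tally = as.list(table(targ$verdict)),
        selection_shift_tally = as.list(table(sel$shift)))
    jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    writeLines(c(
        sprintf("MycoLoss pipeline (seed %d)", config@seed),
        sprintf("Significant terms (q <= %.2f): %d", alpha,
                sum(enr$significant)),
        if (!is.null(loss))
            sprintf("Loss overlap %s/%s: %.1f%% (expected %.1f%%, log10 p %.1f)",
                    loss$species_a, loss$species_b, loss$overlap_pct,
                    loss$expected_pct, loss$log10_p),
        sprintf("Targeting verdicts: %s",
                paste(names(table(targ$verdict)), table(targ$verdict),
                      sep = "=", collapse = ", "))),
        p("summary.txt"))
    invisible(summary)
}
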