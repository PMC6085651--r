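## Synthetic-data generator. Every operation derives its RNG stream from the
## single config seed (plus a fixed per-stage offset), so one seed fixes all
## outputs byte for byte.

.seedOffsets <- c(dag = 0L, inventories = 1L, transcripts = 2L, hits = 3L,
                  targeting = 4L, fits = 5L)

.stageSeed <- function(config, stage) {
    set.seed((config@seed + .seedOffsets[[stage]]) %% .Machine$integer.max)
}

# reliability-class mixture for accepted transit-peptide calls (classes 1-4)
.rcProbs <- c(0.4, 0.3, 0.2, 0.1)

.senseCodons <- local({
    bases <- c("A", "C", "G", "T")
    all3 <- as.vector(outer(as.vector(outer(bases, bases, paste0)), bases,
                            paste0))
    setdiff(all3, c("TAA", "TAG", "TGA"))
})

#' Build a synthetic GO-like DAG
#'
#' Constructs a rooted acyclic `is_a` hierarchy with `n_terms` terms and depth
#' `dag_depth`; every non-root term has one or two parents at the level above.
#' `planted_terms` leaf terms (preferring the deepest level) are flagged
#' photosynthesis-like; these are the terms whose annotated genes the
#' heterotroph loss model depletes.
#'
#' @param config a [simulationConfig()].
#' @return a [GoDag-class].
#' @export
buildSyntheticDag <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    .stageSeed(config, "dag")
    n <- config@n_terms
    depth <- config@dag_depth
    ids <- sprintf("SYN:%07d", seq_len(n))
    level <- integer(n)
    parents <- vector("list", n)
    names(parents) <- ids
    level[1L] <- 1L
    parents[[1L]] <- character(0)
    # a backbone chain guarantees every level up to `depth` is populated
    chainLen <- min(depth, n)
    for (i in seq_len(chainLen)[-1L]) {
        level[i] <- i
        parents[[i]] <- ids[i - 1L]
    }
    if (n > chainLen) {
        for (i in (chainLen + 1L):n) {
            lv <- if (depth > 1L) sample(2:depth, 1L) else 1L
            pool <- which(level == lv - 1L & seq_len(n) < i)
            np <- min(length(pool), sample(1:2, 1L))
            parents[[i]] <- ids[sort(sample(pool, np))]
            level[i] <- lv
        }
    }
    hasChild <- ids %in% unlist(parents, use.names = FALSE)
    planted <- logical(n)
    if (config@planted_terms > 0L) {
        leaves <- which(!hasChild & seq_len(n) > 1L)
        if (length(leaves) < config@planted_terms)
            stop("configuration error: planted_terms exceeds the number ",
                 "of leaf terms", call. = FALSE)
        deep <- leaves[order(-level[leaves])]
        planted[deep[seq_len(config@planted_terms)]] <- TRUE
    }
    nm <- ifelse(planted,
                 paste0("photosynthesis-like process ", seq_len(n)),
                 paste0("synthetic process ", seq_len(n)))
    new("GoDag", terms = ids, termName = nm,
        namespace = rep("biological_process", n),
        parents = parents, obsolete = logical(n), planted = planted)
}

#' Simulate per-species gene inventories and annotation
#'
#' Every autotroph carries all `n_genes` genes. Each gene is directly
#' annotated to 1-4 non-root terms; genes annotated to a planted
#' (photosynthesis-like) term are lost in each heterotroph with probability
#' `loss_p_planted`, other genes with `loss_p_background`. With probability
#' `shared_loss_frac` a gene's loss indicator is drawn once and shared by all
#' heterotrophs (correlated loss); otherwise it is drawn independently per
#' heterotroph. A small organellar-gene list (2% of genes) is emitted for
#' exclusion testing.
#'
#' @param config a [simulationConfig()].
#' @param dag the [GoDag-class] from [buildSyntheticDag()].
#' @return list with `species` (data.frame `species`, `clade`, `group`),
#'   `inventories` (named list species -> present gene ids), `direct` (named
#'   list gene -> direct term ids), `plantedGenes`, `organellar`.
#' @export
simulateInventories <- function(config, dag) {
    stopifnot(is(config, "SimulationConfig"), is(dag, "GoDag"))
    .stageSeed(config, "inventories")
    nG <- config@n_genes
    genes <- sprintf("g%05d", seq_len(nG))
    pool <- dag@terms[-1L] # root excluded from direct annotation
    if (!length(pool)) pool <- dag@terms
    # photosynthesis-like categories are large gene sets in real plant
    # annotations; planted leaf terms get 3x the sampling weight
    w <- ifelse(pool %in% plantedTerms(dag), 3, 1)
    kTerms <- sample(1:4, nG, replace = TRUE)
    direct <- lapply(kTerms, function(k)
        sample(pool, min(k, length(pool)), prob = w))
    names(direct) <- genes
    plantedSet <- plantedTerms(dag)
    plantedGene <- vapply(direct, function(ts) any(ts %in% plantedSet),
                          logical(1))
    species <- data.frame(
        species = c(sprintf("HET%d", seq_len(config@n_hetero)),
                    sprintf("AUT%d", seq_len(config@n_auto))),
        clade = "cladeA",
        group = rep(c("heterotroph", "autotroph"),
                    c(config@n_hetero, config@n_auto)),
        stringsAsFactors = FALSE)
    pLoss <- ifelse(plantedGene, config@loss_p_planted,
                    config@loss_p_background)
    shared <- stats::runif(nG) < config@shared_loss_frac
    sharedLost <- stats::runif(nG) < pLoss
    hets <- species$species[species$group == "heterotroph"]
    inventories <- list()
    for (h in hets) {
        indep <- stats::runif(nG) < pLoss
        lost <- ifelse(shared, sharedLost, indep)
        inventories[[h]] <- genes[!lost]
    }
    for (a in species$species[species$group == "autotroph"])
        inventories[[a]] <- genes
    norg <- max(1L, ceiling(0.02 * nG))
    list(species = species, inventories = inventories, direct = direct,
         plantedGenes = genes[plantedGene],
         organellar = sort(sample(genes, norg)))
}

.randomOrfSequence <- function(nCodons) {
    paste0("ATG",
           paste(sample(.senseCodons, nCodons - 1L, replace = TRUE),
                 collapse = ""),
           sample(c("TAA", "TAG", "TGA"), 1L))
}

.randomUtr <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Simulate transcript tables and sequences
#'
#' Each gene present in a species receives `1 + Poisson(isoform_lambda)`
#' isoforms with negative-binomial mapped-read counts and log-normal mean
#' coverage; each transcript carries a planted open reading frame of at least
#' 30 codons flanked by short UTRs. A `contamination_frac` fraction of each
#' species' transcripts are contaminants from non-Streptophyta taxa (drawn
#' from the toy taxonomy shipped with the package). FPKM is computed per
#' species from the simulated reads and transcript lengths.
#'
#' @param config a [simulationConfig()].
#' @param inventories output of [simulateInventories()].
#' @return list with `records` (data.frame: `transcript_id`, `gene_id`,
#'   `species`, `mapped_reads`, `mean_coverage`, `fpkm`, `sequence`,
#'   `source_taxon`, `is_contaminant`) and `taxonomy` (the toy taxonomy
#'   table).
#' @export
simulateTranscripts <- function(config, inventories) {
    stopifnot(is(config, "SimulationConfig"))
    .stageSeed(config, "transcripts")
    tax <- toyTaxonomy()
    plantTaxa <- tax$taxon[grepl("Streptophyta", tax$lineage, fixed = TRUE)]
    contamTaxa <- setdiff(tax$taxon, plantTaxa)
    allRows <- list()
    for (sp in names(inventories$inventories)) {
        genes <- inventories$inventories[[sp]]
        nIso <- 1L + stats::rpois(length(genes), config@isoform_lambda)
        gene <- rep(genes, nIso)
        iso <- sequence(nIso)
        nPlant <- length(gene)
        nContam <- if (config@contamination_frac > 0 &&
                       config@contamination_frac < 1)
            round(config@contamination_frac /
                  (1 - config@contamination_frac) * nPlant)
        else if (config@contamination_frac >= 1) nPlant else 0L
        ctmGene <- if (nContam > 0L) sprintf("%s_ctm%04d", sp,
                                             seq_len(nContam))
                   else character(0)
        gene <- c(gene, ctmGene)
        iso <- c(iso, rep(1L, nContam))
        isCtm <- c(rep(FALSE, nPlant), rep(TRUE, nContam))
        n <- length(gene)
        reads <- stats::rnbinom(n, mu = config@nb_mean,
                                size = config@nb_dispersion)
        cov <- stats::rlnorm(n, meanlog = config@cov_mu,
                             sdlog = config@cov_sigma)
        nCod <- sample(40:80, n, replace = TRUE)
        seqs <- vapply(seq_len(n), function(i)
            paste0(.randomUtr(sample(10:40, 1L)),
                   .randomOrfSequence(nCod[i]),
                   .randomUtr(sample(10:40, 1L))), character(1))
        src <- character(n)
        src[!isCtm] <- sample(plantTaxa, sum(!isCtm), replace = TRUE)
        if (any(isCtm))
            src[isCtm] <- sample(contamTaxa, sum(isCtm), replace = TRUE)
        len <- nchar(seqs)
        lib <- sum(reads)
        fpkm <- if (lib > 0) reads / (len / 1000) / (lib / 1e6) else
            rep(0, n)
        allRows[[sp]] <- data.frame(
            transcript_id = sprintf("%s|%s|i%d", sp, gene, iso),
            gene_id = gene, species = sp, mapped_reads = reads,
            mean_coverage = cov, fpkm = fpkm, sequence = seqs,
            source_taxon = src, is_contaminant = isCtm,
            stringsAsFactors = FALSE)
    }
    list(records = do.call(rbind, c(allRows, make.row.names = FALSE)),
         taxonomy = tax)
}

#' The toy taxonomy fixture
#'
#' A small fixed taxonomy (Streptophyta vs fungal and bacterial lineages)
#' used to label the source of simulated transcripts and their best hits.
#'
#' @return data.frame with columns `taxon` and `lineage`
#'   (semicolon-separated).
#' @export
toyTaxonomy <- function() {
    path <- system.file("extdata", "toy_taxonomy.tsv", package = "MycoLoss",
                        mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Simulate BLAST-style hit tables
#'
#' Produces (i) a contamination hit table in which each transcript's best hit
#' carries the lineage of its true source kingdom (flipped with probability
#' `hit_noise`; a small fraction of plant transcripts receive no hit at all),
#' and (ii) two directional ortholog hit tables between each species' genes
#' and a reference proteome (`REF_<gene>`), constructed so true gene pairs
#' are mutual best hits except a `rbh_corruption` fraction whose forward best
#' hit is redirected to a wrong subject.
#'
#' @param config a [simulationConfig()].
#' @param transcripts output of [simulateTranscripts()].
#' @return list with `contamination` (data.frame `query`, `subject`,
#'   `bit_score`, `e_value`, `lineage`) and `ortholog` (named list:
#'   species -> list(`ab`, `ba`, `truth`) of directional hit tables and the
#'   true pairing).
#' @export
simulateHitTables <- function(config, transcripts) {
    stopifnot(is(config, "SimulationConfig"))
    .stageSeed(config, "hits")
    rec <- transcripts$records
    tax <- transcripts$taxonomy
    lin <- stats::setNames(tax$lineage, tax$taxon)
    plantTaxa <- tax$taxon[grepl("Streptophyta", tax$lineage, fixed = TRUE)]
    contamTaxa <- setdiff(tax$taxon, plantTaxa)
    n <- nrow(rec)
    flip <- stats::runif(n) < config@hit_noise
    wrongKingdom <- xor(rec$is_contaminant, flip)
    taxon <- ifelse(wrongKingdom,
                    sample(contamTaxa, n, replace = TRUE),
                    sample(plantTaxa, n, replace = TRUE))
    noHit <- !rec$is_contaminant & !flip & stats::runif(n) < 0.05
    contam <- data.frame(
        query = rec$transcript_id, subject = paste0("db|", taxon),
        bit_score = round(stats::runif(n, 100, 500), 1),
        e_value = 10^-stats::runif(n, 6, 50),
        lineage = unname(lin[taxon]), stringsAsFactors = FALSE)[!noHit, ]
    rownames(contam) <- NULL
    ortho <- list()
    bySp <- split(rec[!rec$is_contaminant, ], rec$species[!rec$is_contaminant])
    for (sp in names(bySp)) {
        genes <- unique(bySp[[sp]]$gene_id)
        refs <- paste0("REF_", genes)
        ng <- length(genes)
        bitTrue <- round(stats::runif(ng, 300, 500), 1)
        corrupted <- stats::runif(ng) < config@rbh_corruption & ng > 1L
        fwdSubject <- refs
        for (i in which(corrupted))
            fwdSubject[i] <- sample(refs[-i], 1L)
        decoy <- function(q, true, bits) {
            # one lower-scoring decoy per query
            d <- vapply(seq_along(q), function(i)
                if (ng > 1L) sample(setdiff(refs, true[i]), 1L) else true[i],
                character(1))
            data.frame(query = q, subject = d,
                       bit_score = round(bits * stats::runif(length(q),
                                                             0.3, 0.8), 1),
                       stringsAsFactors = FALSE)
        }
        ab <- rbind(
            data.frame(query = genes, subject = fwdSubject,
                       bit_score = bitTrue, stringsAsFactors = FALSE),
            if (ng > 1L) decoy(genes, fwdSubject, bitTrue))
        ba <- rbind(
            data.frame(query = refs, subject = genes, bit_score = bitTrue,
                       stringsAsFactors = FALSE),
            if (ng > 1L) {
                d <- decoy(refs, genes, bitTrue)
                d$subject <- sub("^REF_", "", d$subject)
                d
            })
        ortho[[sp]] <- list(ab = ab, ba = ba,
                            truth = data.frame(gene = genes, ref = refs,
                                               stringsAsFactors = FALSE))
    }
    list(contamination = contam, ortholog = ortho)
}

#' Simulate organellar-targeting predictions
#'
#' Each protein is assigned a planted signal (plastid / mitochondrion / dual
#' / none with the configured probabilities). Every protein gets a full-
#' length variant; 30% also get a truncated variant and 20% an alternative
#' isoform, all consistent with the planted signal. For each variant both
#' predictor styles are emitted: a classA (TargetP-like) row with a
#' localization and a reliability class (1-4 for supported signals, drawn
#' from a fixed mixture 0.4/0.3/0.2/0.1; class 5 otherwise) and a classB
#' (DualPred-like) row with a dual score (>= 0.5 iff the signal is dual) and
#' a single-compartment call. With probability `targeting_noise` a variant's
#' rows are scrambled.
#'
#' @param config a [simulationConfig()].
#' @param proteinIds character vector of protein ids.
#' @return list with `predictions` (long data.frame: `protein_id`, `variant`,
#'   `tool`, `localization`, `reliability`, `dual_score`, `single_call`) and
#'   `truth` (data.frame `protein_id`, `signal`).
#' @export
simulateTargeting <- function(config, proteinIds) {
    stopifnot(is(config, "SimulationConfig"))
    .stageSeed(config, "targeting")
    n <- length(proteinIds)
    pNone <- 1 - config@frac_plastid_signal - config@frac_mito_signal -
        config@frac_dual
    signal <- sample(c("plastid", "mitochondrion", "dual", "none"), n,
                     replace = TRUE,
                     prob = c(config@frac_plastid_signal,
                              config@frac_mito_signal, config@frac_dual,
                              pNone))
    hasTrunc <- stats::runif(n) < 0.3
    hasIso <- stats::runif(n) < 0.2
    rows <- list()
    emit <- function(id, variant, sig) {
        noisy <- stats::runif(1) < config@targeting_noise
        if (noisy)
            sig <- sample(setdiff(c("plastid", "mitochondrion", "dual",
                                    "none"), sig), 1L)
        if (sig == "none") {
            locA <- "other"; rc <- 5L
            callB <- "other"; score <- stats::runif(1, 0, 0.45)
        } else if (sig == "dual") {
            locA <- sample(c("plastid", "mitochondrion"), 1L)
            rc <- sample(1:4, 1L, prob = .rcProbs)
            callB <- locA; score <- stats::runif(1, 0.5, 1)
        } else {
            locA <- sig; rc <- sample(1:4, 1L, prob = .rcProbs)
            callB <- sig; score <- stats::runif(1, 0, 0.45)
        }
        rbind(
            data.frame(protein_id = id, variant = variant, tool = "classA",
                       localization = locA, reliability = rc,
                       dual_score = NA_real_, single_call = NA_character_,
                       stringsAsFactors = FALSE),
            data.frame(protein_id = id, variant = variant, tool = "classB",
                       localization = NA_character_,
                       reliability = NA_integer_, dual_score = score,
                       single_call = callB, stringsAsFactors = FALSE))
    }
    for (i in seq_len(n)) {
        rows[[length(rows) + 1L]] <- emit(proteinIds[i], "full", signal[i])
        if (hasTrunc[i])
            rows[[length(rows) + 1L]] <- emit(proteinIds[i], "truncated",
                                              signal[i])
        if (hasIso[i])
            rows[[length(rows) + 1L]] <- emit(proteinIds[i], "isoform:i2",
                                              signal[i])
    }
    list(predictions = do.call(rbind, c(rows, make.row.names = FALSE)),
         truth = data.frame(protein_id = proteinIds, signal = signal,
                            stringsAsFactors = FALSE))
}

#' Simulate branch-model likelihood fits
#'
#' Emulates the output of nested codon-model fits for a set of genes: a
#' constrained fit (one dN/dS for all branches) and a free fit (separate
#' heterotroph dN/dS). Under the null the doubled log-likelihood gain is a
#' central chi-square(1) draw; a `fracRelaxed` fraction of genes gets a
#' noncentral gain and an elevated heterotroph dN/dS.
#'
#' @param config a [simulationConfig()].
#' @param nGenes number of genes (default 100).
#' @param fracRelaxed fraction with a genuine selection shift (default 0.1).
#' @return data.frame in the fits-table layout of [selectionTestTable()],
#'   plus a `true_shift` truth column.
#' @export
simulateSelectionFits <- function(config, nGenes = 100L, fracRelaxed = 0.1) {
    stopifnot(is(config, "SimulationConfig"))
    .stageSeed(config, "fits")
    genes <- sprintf("sel%04d", seq_len(nGenes))
    relaxed <- stats::runif(nGenes) < fracRelaxed
    lnLc <- -stats::runif(nGenes, 1000, 5000)
    gain <- ifelse(relaxed,
                   stats::rchisq(nGenes, df = 1, ncp = 25) / 2,
                   stats::rchisq(nGenes, df = 1) / 2)
    dndsAuto <- stats::runif(nGenes, 0.05, 0.2)
    dndsHet <- ifelse(relaxed, dndsAuto * stats::runif(nGenes, 2.5, 5),
                      dndsAuto * exp(stats::rnorm(nGenes, 0, 0.05)))
    ds <- stats::runif(nGenes, 0.05, 0.8)
    out <- rbind(
        data.frame(gene_id = genes, model_label = "constrained", lnL = lnLc,
                   n_params = 2L, dnds_hetero = dndsAuto,
                   dnds_auto = dndsAuto, ds = ds,
                   true_shift = ifelse(relaxed, "relaxed", "none"),
                   stringsAsFactors = FALSE),
        data.frame(gene_id = genes, model_label = "free", lnL = lnLc + gain,
                   n_params = 3L, dnds_hetero = dndsHet,
                   dnds_auto = dndsAuto, ds = ds,
                   true_shift = ifelse(relaxed, "relaxed", "none"),
                   stringsAsFactors = FALSE))
    out[order(out$gene_id, out$model_label), ]
}

#' Simulate a complete study
#'
#' Runs every generator stage under one seed: DAG, inventories and
#' annotation, transcripts, hit tables, targeting predictions (for the
#' heterotroph-present genes of the first heterotroph), and selection fits.
#'
#' @param config a [simulationConfig()].
#' @return list with components `config`, `dag`, `inventories`,
#'   `transcripts`, `hits`, `targeting`, `fits`.
#' @export
simulateStudy <- function(config) {
    dag <- buildSyntheticDag(config)
    inv <- simulateInventories(config, dag)
    tr <- simulateTranscripts(config, inv)
    hits <- simulateHitTables(config, tr)
    het1 <- inv$species$species[inv$species$group == "heterotroph"][1L]
    prot <- paste0("p_", inv$inventories[[het1]])
    targ <- simulateTargeting(config, prot)
    fits <- simulateSelectionFits(config)
    list(config = config, dag = dag, inventories = inv, transcripts = tr,
         hits = hits, targeting = targ, fits = fits)
}
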