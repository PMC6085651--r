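
#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The generator emulates the
#' inputs of a comparative transcriptome study: a clade with several
#' photosynthetic reference species and one or more fully mycoheterotrophic
#' species, a GO-like ontology DAG in which a small set of leaf terms is
#' "photosynthesis-like", gene losses in the heterotrophs that are enriched in
#' those planted terms and partially shared between heterotroph species,
#' isoform/read-count/coverage structure per transcript, contaminant
#' transcripts from non-plant taxa, BLAST-like hit tables, organellar-targeting
#' predictions, and branch-model likelihood fits.
#'
#' @slot seed integer seed controlling every random stream.
#' @slot n_genes number of nuclear genes in the reference inventory.
#' @slot n_terms number of ontology terms (including the root).
#' @slot dag_depth maximum depth of the term DAG.
#' @slot n_auto number of autotrophic (photosynthetic) species.
#' @slot n_hetero number of heterotrophic species.
#' @slot planted_terms number of leaf terms flagged photosynthesis-like.
#' @slot loss_p_planted probability that a gene annotated to a planted term is
#'   lost in a heterotroph.
#' @slot loss_p_background loss probability for all other genes.
#' @slot shared_loss_frac probability that a gene's loss indicator is drawn
#'   once and shared by all heterotrophs (correlated loss), rather than drawn
#'   independently per heterotroph.
#' @slot contamination_frac fraction of each species' transcripts that
#'   originate from non-plant (fungal/bacterial) taxa.
#' @slot isoform_lambda Poisson mean of extra isoforms per gene.
#' @slot nb_mean,nb_dispersion negative-binomial mean and size for per-isoform
#'   mapped read counts.
#' @slot cov_mu,cov_sigma log-scale mean and sd of per-transcript mean
#'   coverage (log-normal).
#' @slot frac_plastid_signal,frac_mito_signal,frac_dual probabilities that a
#'   protein carries a plastid, mitochondrial, or dual targeting signal.
#' @slot hit_noise probability that a contamination best hit points to the
#'   wrong kingdom.
#' @slot rbh_corruption fraction of true ortholog pairs whose directional best
#'   hits are corrupted so they are no longer mutual.
#' @slot targeting_noise probability that a targeting prediction row
#'   contradicts the planted signal.
#'
#' @export
setClass("SimulationConfig",
    representation(
        seed = "integer",
        n_genes = "integer",
        n_terms = "integer",
        dag_depth = "integer",
        n_auto = "integer",
        n_hetero = "integer",
        planted_terms = "integer",
        loss_p_planted = "numeric",
        loss_p_background = "numeric",
        shared_loss_frac = "numeric",
        contamination_frac = "numeric",
        isoform_lambda = "numeric",
        nb_mean = "numeric",
        nb_dispersion = "numeric",
        cov_mu = "numeric",
        cov_sigma = "numeric",
        frac_plastid_signal = "numeric",
        frac_mito_signal = "numeric",
        frac_dual = "numeric",
        hit_noise = "numeric",
        rbh_corruption = "numeric",
        targeting_noise = "numeric"
    )
)

setValidity("SimulationConfig", function(object) {
    probs <- c(
        loss_p_planted = object@loss_p_planted,
        loss_p_background = object@loss_p_background,
        shared_loss_frac = object@shared_loss_frac,
        contamination_frac = object@contamination_frac,
        frac_plastid_signal = object@frac_plastid_signal,
        frac_mito_signal = object@frac_mito_signal,
        frac_dual = object@frac_dual,
        hit_noise = object@hit_noise,
        rbh_corruption = object@rbh_corruption,
        targeting_noise = object@targeting_noise
    )
    bad <- names(probs)[is.na(probs) | probs < 0 | probs > 1]
    if (length(bad))
        return(sprintf("probability field(s) outside [0,1]: %s",
                       paste(bad, collapse = ", ")))
    if (object@frac_plastid_signal + object@frac_mito_signal +
        object@frac_dual > 1)
        return("frac_plastid_signal + frac_mito_signal + frac_dual must be <= 1")
    if (object@n_hetero < 1L) return("n_hetero must be >= 1")
    if (object@n_auto < 2L) return("n_auto must be >= 2")
    if (object@n_genes < 1L) return("n_genes must be >= 1")
    if (object@n_terms < 1L) return("n_terms must be >= 1")
    if (object@dag_depth < 1L) return("dag_depth must be >= 1")
    if (object@n_terms < object@dag_depth)
        return("n_terms must be >= dag_depth")
    if (object@planted_terms < 0L || object@planted_terms >= object@n_terms)
        return("planted_terms must be in [0, n_terms)")
    if (object@isoform_lambda < 0) return("isoform_lambda must be >= 0")
    if (object@nb_mean <= 0 || object@nb_dispersion <= 0)
        return("nb_mean and nb_dispersion must be positive")
    if (object@cov_sigma < 0) return("cov_sigma must be >= 0")
    TRUE
})

#' Create a simulation configuration
#'
#' Defaults correspond to the study design the generator emulates: one clade
#' with 2 heterotrophs and 3 autotroph references, 2000 genes, a 150-term DAG
#' with 8 planted photosynthesis-like leaf terms, planted-gene loss
#' probability 0.9 against a 0.1 background, and 60% of losses shared across
#' heterotrophs.
#'
#' @param seed integer seed.
#' @param n_genes,n_terms,dag_depth,n_auto,n_hetero,planted_terms see
#'   [SimulationConfig-class].
#' @param loss_p_planted,loss_p_background,shared_loss_frac loss model.
#' @param contamination_frac,isoform_lambda,nb_mean,nb_dispersion,cov_mu,cov_sigma
#'   transcript model.
#' @param frac_plastid_signal,frac_mito_signal,frac_dual targeting signals.
#' @param hit_noise,rbh_corruption,targeting_noise noise knobs (0 = clean).
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(seed = 1, n_genes = 200)
#' cfg
#' @export
simulationConfig <- function(seed = 1L, n_genes = 2000L, n_terms = 150L,
                             dag_depth = 5L, n_auto = 3L, n_hetero = 2L,
                             planted_terms = 8L,
                             loss_p_planted = 0.9, loss_p_background = 0.1,
                             shared_loss_frac = 0.6,
                             contamination_frac = 0.2, isoform_lambda = 0.7,
                             nb_mean = 200, nb_dispersion = 5,
                             cov_mu = log(20), cov_sigma = 1,
                             frac_plastid_signal = 0.15,
                             frac_mito_signal = 0.10, frac_dual = 0.05,
                             hit_noise = 0, rbh_corruption = 0,
                             targeting_noise = 0) {
    asInt <- function(x, what) {
        if (length(x) != 1L || is.na(x) || x != as.integer(x))
            stop(sprintf("configuration error: '%s' must be a single integer",
                         what), call. = FALSE)
        as.integer(x)
    }
    obj <- new("SimulationConfig",
        seed = asInt(seed, "seed"),
        n_genes = asInt(n_genes, "n_genes"),
        n_terms = asInt(n_terms, "n_terms"),
        dag_depth = asInt(dag_depth, "dag_depth"),
        n_auto = asInt(n_auto, "n_auto"),
        n_hetero = asInt(n_hetero, "n_hetero"),
        planted_terms = asInt(planted_terms, "planted_terms"),
        loss_p_planted = loss_p_planted,
        loss_p_background = loss_p_background,
        shared_loss_frac = shared_loss_frac,
        contamination_frac = contamination_frac,
        isoform_lambda = isoform_lambda,
        nb_mean = nb_mean, nb_dispersion = nb_dispersion,
        cov_mu = cov_mu, cov_sigma = cov_sigma,
        frac_plastid_signal = frac_plastid_signal,
        frac_mito_signal = frac_mito_signal, frac_dual = frac_dual,
        hit_noise = hit_noise, rbh_corruption = rbh_corruption,
        targeting_noise = targeting_noise)
    err <- validObject(obj, test = TRUE)
    if (is.character(err))
        stop("configuration error: ", err, call. = FALSE)
    obj
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat("  seed:", object@seed, " genes:", object@n_genes,
        " terms:", object@n_terms, "(", object@planted_terms, "planted )\n")
    cat("  species:", object@n_hetero, "heterotroph +",
        object@n_auto, "autotroph\n")
    cat("  loss p:", object@loss_p_planted, "planted /",
        object@loss_p_background, "background, shared frac",
        object@shared_loss_frac, "\n")
})

#' Ontology DAG of GO-like terms
#'
#' A rooted directed acyclic graph of terms connected by `is_a` edges
#' (child to parent). Annotation propagation closes each gene's term set
#' under ancestry on this graph.
#'
#' @slot terms character vector of term ids (first element is the root).
#' @slot termName character vector of term names, parallel to `terms`.
#' @slot namespace character vector of namespaces, parallel to `terms`.
#' @slot parents named list: term id -> character vector of parent ids
#'   (empty for the root).
#' @slot obsolete logical vector, parallel to `terms`.
#' @slot planted logical vector flagging photosynthesis-like terms (all
#'   `FALSE` for DAGs parsed from real ontology files).
#' @export
setClass("GoDag",
    representation(
        terms = "character",
        termName = "character",
        namespace = "character",
        parents = "list",
        obsolete = "logical",
        planted = "logical"
    )
)

setValidity("GoDag", function(object) {
    n <- length(object@terms)
    if (anyDuplicated(object@terms)) return("duplicated term ids")
    if (length(object@termName) != n || length(object@namespace) != n ||
        length(object@obsolete) != n || length(object@planted) != n ||
        length(object@parents) != n)
        return("all slots must be parallel to 'terms'")
    if (!identical(names(object@parents), object@terms))
        return("'parents' must be named by 'terms'")
    unknown <- setdiff(unlist(object@parents, use.names = FALSE), object@terms)
    if (length(unknown))
        return(sprintf("parent id(s) not in term set: %s",
                       paste(utils::head(unknown, 3), collapse = ", ")))
    # acyclicity + rootedness by topological elimination
    if (n > 0L) {
        npar <- lengths(object@parents)
        if (sum(npar == 0L) < 1L) return("DAG has no root")
        ord <- dagTopologicalOrder(object@parents)
        if (is.null(ord)) return("term graph contains a cycle")
    }
    TRUE
})

# Kahn's algorithm on child->parents lists; NULL if a cycle exists.
dagTopologicalOrder <- function(parents) {
    n <- length(parents)
    ids <- names(parents)
    idx <- seq_len(n)
    names(idx) <- ids
    npar <- lengths(parents)
    children <- vector("list", n)
    for (i in idx) {
        for (p in parents[[i]]) {
            j <- idx[[p]]
            children[[j]] <- c(children[[j]], i)
        }
    }
    queue <- which(npar == 0L)
    out <- integer(0)
    remaining <- npar
    while (length(queue)) {
        v <- queue[[1L]]; queue <- queue[-1L]
        out <- c(out, v)
        for (ch in children[[v]]) {
            remaining[[ch]] <- remaining[[ch]] - 1L
            if (remaining[[ch]] == 0L) queue <- c(queue, ch)
        }
    }
    if (length(out) != n) NULL else ids[out]
}

setMethod("show", "GoDag", function(object) {
    cat("GoDag with", length(object@terms), "terms,",
        sum(lengths(object@parents)), "is_a edges")
    if (any(object@planted))
        cat(",", sum(object@planted), "photosynthesis-like")
    cat("\n")
})

#' @describeIn GoDag-class number of terms.
#' @param x,object a `GoDag`.
#' @export
setMethod("length", "GoDag", function(x) length(x@terms))

#' Term ids of a DAG
#' @param dag a [GoDag-class].
#' @return character vector of term ids.
#' @export
dagTerms <- function(dag) dag@terms

#' Child-to-parent edge list of a DAG
#' @param dag a [GoDag-class].
#' @return data.frame with columns `child`, `parent`.
#' @export
dagEdges <- function(dag) {
    np <- lengths(dag@parents)
    data.frame(child = rep(dag@terms, np),
               parent = unlist(dag@parents, use.names = FALSE),
               stringsAsFactors = FALSE)
}

#' Photosynthesis-like (planted) term ids
#' @param dag a [GoDag-class].
#' @return character vector.
#' @export
plantedTerms <- function(dag) dag@terms[dag@planted]

#' Per-species annotation profile
#'
#' A species' propagated gene-to-term assignments together with its group
#' label. `nTotal` is the number of genes with at least one term; per-term
#' fractions in the enrichment use it as the denominator.
#'
#' @slot species species identifier.
#' @slot clade clade label (enrichment compares within a clade).
#' @slot group `"heterotroph"` or `"autotroph"`.
#' @slot geneTerms named list: gene id -> character vector of (propagated)
#'   term ids.
#' @slot nTotal integer, number of genes with a nonempty term set.
#' @export
setClass("SpeciesProfile",
    representation(
        species = "character",
        clade = "character",
        group = "character",
        geneTerms = "list",
        nTotal = "integer"
    )
)

setValidity("SpeciesProfile", function(object) {
    if (length(object@species) != 1L) return("'species' must be length 1")
    if (!object@group %in% c("heterotroph", "autotroph"))
        return("'group' must be 'heterotroph' or 'autotroph'")
    if (is.null(names(object@geneTerms)) && length(object@geneTerms))
        return("'geneTerms' must be named by gene id")
    nt <- sum(lengths(object@geneTerms) > 0L)
    if (object@nTotal != nt)
        return(sprintf("nTotal (%d) != genes with >=1 term (%d)",
                       object@nTotal, nt))
    TRUE
})

#' Construct a species profile
#' @param species,clade,group identifiers; `group` is `"heterotroph"` or
#'   `"autotroph"`.
#' @param geneTerms named list gene -> term ids (typically propagated).
#' @return A [SpeciesProfile-class].
#' @export
speciesProfile <- function(species, clade, group, geneTerms) {
    new("SpeciesProfile", species = species, clade = clade, group = group,
        geneTerms = geneTerms,
        nTotal = sum(lengths(geneTerms) > 0L))
}

setMethod("show", "SpeciesProfile", function(object) {
    cat(sprintf("SpeciesProfile %s (%s, %s): %d genes, %d with terms\n",
                object@species, object@clade, object@group,
                length(object@geneTerms), object@nTotal))
})

#' @describeIn SpeciesProfile-class number of annotated genes (genes with at
#'   least one term).
#' @param object a `SpeciesProfile`.
#' @export
nTotal <- function(object) object@nTotal

#' Group label of a profile
#' @param object a [SpeciesProfile-class].
#' @export
profileGroup <- function(object) object@group
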