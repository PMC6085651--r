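#' Truncate a protein at its first alternative start
#'
#' Dual organellar targeting sometimes arises from alternative translation
#' starts that expose a second transit peptide. The candidate alternative
#' start is the first methionine occurring after the first `offset` (default
#' 25) amino acids; the returned suffix starts at that methionine (1-based
#' position `>= offset + 1`), which becomes the new initiator.
#'
#' @param proteinSeq protein sequence over the 20-letter alphabet (plus `X`).
#' @param offset number of leading residues to skip (default 25).
#' @return the truncated sequence, or `NULL` when no methionine occurs after
#'   position `offset`.
#' @examples
#' truncateAtAltStart(paste0("M", strrep("A", 24), "LLMKKK")) # "MKKK"
#' @export
truncateAtAltStart <- function(proteinSeq, offset = 25L) {
    if (!is.character(proteinSeq) || length(proteinSeq) != 1L ||
        !nzchar(proteinSeq))
        stop("input error: empty protein sequence", call. = FALSE)
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", proteinSeq))
        stop("input error: illegal residue in protein sequence",
             call. = FALSE)
    chars <- strsplit(proteinSeq, "", fixed = TRUE)[[1L]]
    hit <- which(chars == "M" & seq_along(chars) >= offset + 1L)
    if (!length(hit)) return(NULL)
    substr(proteinSeq, hit[1L], nchar(proteinSeq))
}

#' Reconcile the two targeting predictors for one sequence variant
#'
#' Combines a TargetP-style call (`localization` in plastid / mitochondrion /
#' secretory / other with a reliability class 1-5, 1 most confident) with a
#' DualPred-style call (dual-targeting score in \[0,1\] plus a single-
#' compartment call). The TargetP-style call is accepted when its reliability
#' class is at most `maxReliability` (default 4) and it names a compartment;
#' the DualPred-style call indicates dual targeting when its score is at
#' least `dualThreshold` (default 0.5).
#'
#' Rules: an accepted plastid/mitochondrial call plus a dual call is a
#' non-contradictory prediction of dual targeting; agreement on a single
#' compartment returns that compartment (a secretory call agrees with a
#' DualPred `"other"`); an accepted call contradicted by the other tool, or a
#' compartment supported by only one tool, is `"contradictory"`; no support
#' from either tool is `"none"`.
#'
#' @param classA list or one-row data.frame with `localization` and
#'   `reliability`.
#' @param classB list or one-row data.frame with `dual_score` and
#'   `single_call` (plastid / mitochondrion / other).
#' @param maxReliability,dualThreshold acceptance thresholds.
#' @return one of `"dual"`, `"plastid"`, `"mitochondrion"`, `"secretory"`,
#'   `"contradictory"`, `"none"`.
#' @export
reconcilePredictions <- function(classA, classB, maxReliability = 4L,
                                 dualThreshold = 0.5) {
    if (is.null(classA) || is.null(classB))
        stop("input error: both predictor rows are required", call. = FALSE)
    locA <- as.character(classA$localization)
    rc <- as.integer(classA$reliability)
    score <- as.numeric(classB$dual_score)
    callB <- as.character(classB$single_call)
    if (!locA %in% c("plastid", "mitochondrion", "secretory", "other") ||
        is.na(rc) || rc < 1L || rc > 5L)
        stop("input error: malformed classA row", call. = FALSE)
    if (!callB %in% c("plastid", "mitochondrion", "other") ||
        is.na(score) || score < 0 || score > 1)
        stop("input error: malformed classB row", call. = FALSE)
    acceptedA <- rc <= maxReliability && locA != "other"
    dualB <- score >= dualThreshold
    if (acceptedA) {
        if (locA %in% c("plastid", "mitochondrion") && dualB) return("dual")
        agrees <- (locA == callB) || (locA == "secretory" && callB == "other")
        if (agrees && !dualB) return(locA)
        return("contradictory")
    }
    # TargetP-style tool sees no transit peptide
    if (dualB || callB == "plastid") return("contradictory")
    "none"
}

#' Aggregate variant verdicts into one per-protein verdict
#'
#' Full-length, truncated, and alternative-isoform variants of one protein
#' are reconciled separately; the protein-level verdict is the highest-
#' precedence variant verdict, with precedence
#' dual > plastid > mitochondrion > secretory > contradictory > none
#' (dual ranks highest because it subsumes plastid import capability).
#'
#' @param verdicts named character vector: variant label -> variant verdict.
#' @return list with `verdict` and `supporting_variant` (the first variant,
#'   in input order, attaining the winning verdict).
#' @export
aggregateProteinVerdict <- function(verdicts) {
    if (!length(verdicts))
        stop("input error: no variant verdicts supplied", call. = FALSE)
    precedence <- c("dual", "plastid", "mitochondrion", "secretory",
                    "contradictory", "none")
    unknown <- setdiff(verdicts, precedence)
    if (length(unknown))
        stop("input error: unknown verdict(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
    best <- precedence[min(match(verdicts, precedence))]
    i <- which(verdicts == best)[1L]
    list(verdict = best,
         supporting_variant = if (is.null(names(verdicts))) as.character(i)
                              else names(verdicts)[i])
}

#' Per-protein verdicts from a long prediction table
#'
#' @param predictions data.frame with columns `protein_id`, `variant`,
#'   `tool` (`"classA"`/`"classB"`), `localization`, `reliability`,
#'   `dual_score`, `single_call` (classA rows carry the first two, classB
#'   rows the last two).
#' @param maxReliability,dualThreshold passed to [reconcilePredictions()].
#' @return data.frame with `protein_id`, `verdict`, `supporting_variant`.
#' @export
targetingVerdicts <- function(predictions, maxReliability = 4L,
                              dualThreshold = 0.5) {
    need <- c("protein_id", "variant", "tool")
    if (!all(need %in% names(predictions)))
        stop("input error: prediction table must have columns ",
             paste(need, collapse = ", "), call. = FALSE)
    byProt <- split(predictions, predictions$protein_id)
    rows <- lapply(byProt, function(sub) {
        vars <- sort(unique(sub$variant)) # order-invariant aggregation
        vv <- vapply(vars, function(v) {
            a <- sub[sub$variant == v & sub$tool == "classA", ]
            b <- sub[sub$variant == v & sub$tool == "classB", ]
            if (nrow(a) != 1L || nrow(b) != 1L)
                stop("input error: protein ", sub$protein_id[1L],
                     " variant ", v, " needs one classA and one classB row",
                     call. = FALSE)
            reconcilePredictions(a, b, maxReliability, dualThreshold)
        }, character(1))
        agg <- aggregateProteinVerdict(vv)
        data.frame(protein_id = sub$protein_id[1L], verdict = agg$verdict,
                   supporting_variant = agg$supporting_variant,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Nominate nuclear substitutes for plastome-lost ribosomal genes
#'
#' For each ribosomal gene lost from the plastid genome, lists proteins that
#' hit the gene's protein family (HMM search) at or below the e-value
#' threshold, excluding the 1-1 orthologs of the plastid gene itself, and
#' annotates each candidate with its organellar-import verdict. Candidates
#' whose verdict is plastid or dual are flagged `import_capable`; a
#' contradictory verdict (one-tool-only support) is flagged `single_tool`.
#'
#' @param hmmHits data.frame with `protein_id`, `family`, `e_value`.
#' @param familyMap data.frame with `family`, `lost_gene` mapping protein
#'   families to plastome-lost genes.
#' @param plastomeLostGenes character vector of lost plastid gene ids.
#' @param verdicts data.frame from [targetingVerdicts()].
#' @param excludeOrthologs character vector of protein ids that are 1-1
#'   orthologs of the plastid genes themselves.
#' @param evalueMax significance threshold (default 1e-5).
#' @return data.frame with `lost_gene`, `protein_id`, `e_value`, `verdict`,
#'   `flag`.
#' @export
findCandidateSubstitutes <- function(hmmHits, familyMap, plastomeLostGenes,
                                     verdicts,
                                     excludeOrthologs = character(0),
                                     evalueMax = 1e-5) {
    if (!length(plastomeLostGenes))
        return(data.frame(lost_gene = character(0), protein_id = character(0),
                          e_value = numeric(0), verdict = character(0),
                          flag = character(0), stringsAsFactors = FALSE))
    vmap <- stats::setNames(verdicts$verdict, verdicts$protein_id)
    rows <- lapply(plastomeLostGenes, function(g) {
        fams <- familyMap$family[familyMap$lost_gene == g]
        if (!length(fams)) {
            warning("no family mapping for lost gene ", g, "; skipped")
            return(NULL)
        }
        hits <- hmmHits[hmmHits$family %in% fams &
                        hmmHits$e_value <= evalueMax &
                        !(hmmHits$protein_id %in% excludeOrthologs), ,
                        drop = FALSE]
        if (!nrow(hits)) return(NULL)
        v <- unname(vmap[hits$protein_id])
        v[is.na(v)] <- "none"
        data.frame(lost_gene = g, protein_id = hits$protein_id,
                   e_value = hits$e_value, verdict = v,
                   flag = ifelse(v %in% c("plastid", "dual"),
                                 "import_capable",
                                 ifelse(v == "contradictory", "single_tool",
                                        "no_signal")),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(lost_gene = character(0), protein_id = character(0),
                          e_value = numeric(0), verdict = character(0),
                          flag = character(0), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}
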