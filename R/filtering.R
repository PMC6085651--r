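#' Filtering configuration
#'
#' Thresholds of the post-assembly filters. Defaults: coverage filter at 3
#' reads per position (inclusive), minimum CDS length 30 amino acids,
#' contamination-hit e-value ceiling 1e-5, and "Streptophyta" as the plant
#' clade for the taxonomy filter.
#'
#' @param min_mean_coverage,min_cds_aa,contamination_evalue_max,plant_clade_name
#'   thresholds; see Description.
#' @return a list of class `FilterConfig`.
#' @export
filterConfig <- function(min_mean_coverage = 3, min_cds_aa = 30L,
                         contamination_evalue_max = 1e-5,
                         plant_clade_name = "Streptophyta") {
    if (min_mean_coverage <= 0 || min_cds_aa <= 0 ||
        contamination_evalue_max <= 0)
        stop("configuration error: thresholds must be positive",
             call. = FALSE)
    structure(list(min_mean_coverage = min_mean_coverage,
                   min_cds_aa = as.integer(min_cds_aa),
                   contamination_evalue_max = contamination_evalue_max,
                   plant_clade_name = plant_clade_name),
              class = "FilterConfig")
}

#' Select the major isoform of every gene
#'
#' The major isoform is the isoform to which the highest number of reads was
#' mapped; ties are broken towards the lexicographically smallest
#' transcript id.
#'
#' @param records data.frame with columns `transcript_id`, `gene_id`,
#'   `mapped_reads`.
#' @return character vector of selected transcript ids, named by gene id
#'   (exactly one per gene).
#' @export
selectMajorIsoforms <- function(records) {
    if (anyDuplicated(records$transcript_id))
        stop("input error: duplicated transcript_id", call. = FALSE)
    ord <- order(records$gene_id, -records$mapped_reads,
                 records$transcript_id)
    records <- records[ord, ]
    keep <- !duplicated(records$gene_id)
    stats::setNames(records$transcript_id[keep], records$gene_id[keep])
}

#' Coverage filter
#'
#' Retains transcripts whose mean read coverage is at least the threshold
#' (inclusive: a coverage of exactly 3 is retained under the default).
#'
#' @param records data.frame with a `mean_coverage` column.
#' @param config a [filterConfig()].
#' @return the retained rows.
#' @export
filterLowCoverage <- function(records, config = filterConfig()) {
    records[records$mean_coverage >= config$min_mean_coverage, ,
            drop = FALSE]
}

# Stop-free codon runs for one working-strand sequence; returns a data.frame
# of runs in working-strand coordinates.
.orfRunsOneStrand <- function(chars, frame) {
    L <- length(chars)
    ncod <- (L - frame) %/% 3L
    if (ncod < 1L)
        return(NULL)
    starts <- frame + 1L + 3L * (seq_len(ncod) - 1L)
    cod <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    isStop <- cod %in% c("TAA", "TAG", "TGA")
    r <- rle(isStop)
    ends <- cumsum(r$lengths)
    begins <- ends - r$lengths + 1L
    keep <- !r$values
    if (!any(keep)) return(NULL)
    b <- begins[keep]; e <- ends[keep]
    # first in-frame ATG of each stretch (position on the working strand)
    atg_w <- vapply(seq_along(b), function(i) {
        hit <- which(cod[b[i]:e[i]] == "ATG")
        if (!length(hit)) NA_integer_ else starts[b[i] + hit[1L] - 1L]
    }, integer(1))
    data.frame(
        start_w = starts[b], end_w = starts[e] + 2L,
        aa_length = e - b + 1L,
        atg_w = atg_w,
        preceded_by_stop = b > 1L,
        frame = frame,
        stringsAsFactors = FALSE)
}

#' Select the candidate coding sequence of a transcript
#'
#' Scans all six reading frames for stop-free codon stretches (5'-partial
#' stretches running from the frame start to the first stop are allowed). A
#' stretch qualifies when its length is at least `minCdsAa` amino acids, or
#' when it overlaps a supplied protein-domain hit; among qualifying
#' stretches the longest is returned (ties broken deterministically: plus
#' strand first, then lower frame, then smaller start). Coordinates are
#' 1-based inclusive on the forward transcript and exclude the stop codon;
#' minus-strand stretches are reported in forward coordinates with
#' `strand == "-"`. `five_prime_complete` is `TRUE` when the stretch
#' contains an in-frame ATG initiator whose upstream context is credible:
#' the stretch begins after an in-frame stop, or at least 3 nt of transcript
#' precede the ATG (an ATG flush with the transcript edge may be a
#' truncation artifact).
#'
#' @param sequence nucleotide string over A/C/G/T/N (codons containing N are
#'   treated as non-stop).
#' @param minCdsAa minimum qualifying length in amino acids (default 30).
#' @param domainHits optional data.frame of Pfam-style hit intervals with
#'   columns `start`, `end` in forward transcript coordinates; a stretch
#'   overlapping any interval qualifies regardless of length.
#' @return one-row data.frame with `start`, `end`, `strand`, `frame`,
#'   `aa_length`, `has_domain`, `five_prime_complete`, or `NULL` when no
#'   stretch qualifies.
#' @export
findCandidateOrfs <- function(sequence, minCdsAa = 30L, domainHits = NULL) {
    if (!is.character(sequence) || length(sequence) != 1L)
        stop("input error: 'sequence' must be a single string", call. = FALSE)
    sequence <- toupper(sequence)
    if (grepl("[^ACGTN]", sequence))
        stop("input error: illegal character in nucleotide sequence",
             call. = FALSE)
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    L <- length(chars)
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    rcChars <- rev(unname(comp[chars]))
    runs <- list()
    for (frame in 0:2) {
        f <- .orfRunsOneStrand(chars, frame)
        if (!is.null(f)) { f$strand <- "+"; runs[[length(runs) + 1L]] <- f }
        r <- .orfRunsOneStrand(rcChars, frame)
        if (!is.null(r)) { r$strand <- "-"; runs[[length(runs) + 1L]] <- r }
    }
    if (!length(runs)) return(NULL)
    runs <- do.call(rbind, runs)
    # forward-coordinate interval of each run
    runs$start <- ifelse(runs$strand == "+", runs$start_w,
                         L - runs$end_w + 1L)
    runs$end <- ifelse(runs$strand == "+", runs$end_w, L - runs$start_w + 1L)
    runs$has_domain <- FALSE
    if (!is.null(domainHits) && nrow(domainHits))
        runs$has_domain <- vapply(seq_len(nrow(runs)), function(i)
            any(domainHits$start <= runs$end[i] &
                domainHits$end >= runs$start[i]), logical(1))
    qual <- runs$aa_length >= minCdsAa | runs$has_domain
    if (!any(qual)) return(NULL)
    runs <- runs[qual, , drop = FALSE]
    ord <- order(-runs$aa_length, runs$strand != "+", runs$frame, runs$start)
    best <- runs[ord[1L], , drop = FALSE]
    data.frame(
        start = best$start, end = best$end, strand = best$strand,
        frame = best$frame, aa_length = best$aa_length,
        has_domain = best$has_domain,
        five_prime_complete = !is.na(best$atg_w) &&
            (best$preceded_by_stop || best$atg_w >= 4L),
        stringsAsFactors = FALSE)
}

#' Classify a CDS as plant or contaminant from its best hits
#'
#' The hit with the highest bit score decides: if its lineage contains the
#' plant clade the CDS is plant, otherwise contaminant. A CDS with no hits is
#' considered plant (absence of a database match is not evidence of
#' contamination). If several hits tie at the top bit score and at least one
#' is plant, the CDS is classified plant.
#'
#' @param hits data.frame with columns `bit_score` and `lineage`
#'   (semicolon-separated taxon names), pre-filtered to the e-value ceiling;
#'   zero rows allowed.
#' @param config a [filterConfig()].
#' @return `"PLANT"` or `"CONTAMINANT"`.
#' @export
classifyTaxonomy <- function(hits, config = filterConfig()) {
    if (is.null(hits) || nrow(hits) == 0L) return("PLANT")
    top <- hits[hits$bit_score == max(hits$bit_score), , drop = FALSE]
    plant <- grepl(config$plant_clade_name, top$lineage, fixed = TRUE)
    if (any(plant)) "PLANT" else "CONTAMINANT"
}

# Unique best subject per query; queries with a bit-score tie between
# distinct subjects yield no best (1-1 semantics).
.uniqueBest <- function(hits) {
    best <- list()
    sp <- split(hits, hits$query)
    for (q in names(sp)) {
        sub <- sp[[q]]
        top <- sub[sub$bit_score == max(sub$bit_score), , drop = FALSE]
        if (length(unique(top$subject)) == 1L)
            best[[q]] <- list(subject = top$subject[1L],
                              bit = top$bit_score[1L])
    }
    best
}

#' Reciprocal-best-hit 1-1 ortholog pairs
#'
#' A pair (a, b) is emitted iff b is a's unique best subject in the a-to-b
#' table and a is b's unique best subject in the b-to-a table. A query whose
#' top bit score is shared by two distinct subjects yields no pair.
#'
#' @param hitsAB,hitsBA data.frames with columns `query`, `subject`,
#'   `bit_score`.
#' @return data.frame with `gene_a`, `gene_b`, `bit_ab`, `bit_ba`, sorted by
#'   `gene_a`.
#' @export
reciprocalBestHits <- function(hitsAB, hitsBA) {
    bestAB <- .uniqueBest(hitsAB)
    bestBA <- .uniqueBest(hitsBA)
    rows <- list()
    for (a in names(bestAB)) {
        b <- bestAB[[a]]$subject
        back <- bestBA[[b]]
        if (!is.null(back) && identical(back$subject, a))
            rows[[length(rows) + 1L]] <- data.frame(
                gene_a = a, gene_b = b, bit_ab = bestAB[[a]]$bit,
                bit_ba = back$bit, stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(gene_a = character(0), gene_b = character(0),
                           bit_ab = numeric(0), bit_ba = numeric(0),
                           stringsAsFactors = FALSE)
    out <- out[order(out$gene_a), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Gene-level expression as the sum over isoforms
#'
#' @param records data.frame with columns `gene_id` and `fpkm`.
#' @return named numeric vector gene id -> summed FPKM (genes with no
#'   isoforms absent).
#' @export
sumGeneExpression <- function(records) {
    if (!nrow(records)) return(stats::setNames(numeric(0), character(0)))
    s <- tapply(records$fpkm, records$gene_id, sum)
    stats::setNames(as.numeric(s), names(s))
}

#' Run the full post-assembly filtering for one species
#'
#' Applies, in order: major-isoform selection, the coverage filter, CDS
#' selection (six-frame scan), and best-hit taxonomy contamination removal;
#' then sums gene-level FPKM over all isoforms of the retained genes.
#'
#' @param records transcript table (`transcript_id`, `gene_id`,
#'   `mapped_reads`, `mean_coverage`, `fpkm`, `sequence`).
#' @param taxHits contamination hit table (`query`, `bit_score`, `e_value`,
#'   `lineage`); hits above the e-value ceiling are ignored.
#' @param config a [filterConfig()].
#' @return list with `retained` (transcript rows surviving all filters,
#'   with ORF columns), `genes` (retained gene ids), `gene_fpkm`, and
#'   `report` (data.frame of per-step transcript counts).
#' @export
filterTranscriptome <- function(records, taxHits, config = filterConfig()) {
    n0 <- nrow(records)
    major <- selectMajorIsoforms(records)
    rec <- records[records$transcript_id %in% major, , drop = FALSE]
    n1 <- nrow(rec)
    rec <- filterLowCoverage(rec, config)
    n2 <- nrow(rec)
    orfs <- lapply(rec$sequence, findCandidateOrfs,
                   minCdsAa = config$min_cds_aa)
    hasOrf <- !vapply(orfs, is.null, logical(1))
    rec <- rec[hasOrf, , drop = FALSE]
    rec <- cbind(rec, do.call(rbind, orfs[hasOrf]))
    n3 <- nrow(rec)
    taxHits <- taxHits[taxHits$e_value <= config$contamination_evalue_max, ,
                       drop = FALSE]
    cls <- vapply(rec$transcript_id, function(id)
        classifyTaxonomy(taxHits[taxHits$query == id, , drop = FALSE],
                         config), character(1))
    rec <- rec[cls == "PLANT", , drop = FALSE]
    n4 <- nrow(rec)
    genes <- unique(rec$gene_id)
    fpkm <- sumGeneExpression(
        records[records$gene_id %in% genes, , drop = FALSE])
    list(retained = rec, genes = genes, gene_fpkm = fpkm,
         report = data.frame(
             step = c("input", "major_isoform", "coverage", "cds",
                      "taxonomy"),
             transcripts = c(n0, n1, n2, n3, n4),
             stringsAsFactors = FALSE))
}
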