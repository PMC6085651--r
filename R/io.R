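#' Write a DAG as a minimal OBO file
#'
#' Emits one `[Term]` stanza per term with `id`, `name`, `namespace`,
#' `is_a`, and `is_obsolete` where set.
#'
#' @param dag a [GoDag-class].
#' @param path output file.
#' @export
writeObo <- function(dag, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("format-version: 1.2", ""), con)
    for (i in seq_along(dag@terms)) {
        lines <- c("[Term]",
                   paste0("id: ", dag@terms[i]),
                   paste0("name: ", dag@termName[i]),
                   paste0("namespace: ", dag@namespace[i]))
        for (p in dag@parents[[i]])
            lines <- c(lines, paste0("is_a: ", p))
        if (dag@obsolete[i]) lines <- c(lines, "is_obsolete: true")
        writeLines(c(lines, ""), con)
    }
    invisible(path)
}

#' Parse a minimal OBO file
#'
#' Reads `[Term]` stanzas, honouring `id`, `name`, `namespace`, `is_a`
#' (target id before any `!` comment) and `is_obsolete`; everything else is
#' ignored.
#'
#' @param path an OBO file.
#' @return a [GoDag-class] (with no planted flags).
#' @export
readObo <- function(path) {
    lines <- readLines(path)
    termStarts <- which(lines == "[Term]")
    if (!length(termStarts)) stop("input error: no [Term] stanzas in ", path,
                                  call. = FALSE)
    bounds <- c(termStarts, length(lines) + 1L)
    ids <- character(0); nms <- character(0); nss <- character(0)
    obs <- logical(0); parents <- list()
    for (i in seq_along(termStarts)) {
        chunk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
        chunk <- chunk[nzchar(chunk) & !startsWith(chunk, "[")]
        getv <- function(key) {
            v <- chunk[startsWith(chunk, paste0(key, ": "))]
            sub(paste0("^", key, ": "), "", v)
        }
        id <- getv("id")[1L]
        if (is.na(id)) next
        ids <- c(ids, id)
        nms <- c(nms, if (length(getv("name"))) getv("name")[1L] else "")
        nss <- c(nss, if (length(getv("namespace")))
            getv("namespace")[1L] else "")
        obs <- c(obs, identical(getv("is_obsolete")[1L], "true"))
        pa <- getv("is_a")
        parents[[id]] <- trimws(sub("!.*$", "", pa))
    }
    new("GoDag", terms = ids, termName = nms, namespace = nss,
        parents = parents[ids], obsolete = obs,
        planted = logical(length(ids)))
}

#' Write a table as TSV with optional '#' metadata lines
#' @param df data.frame.
#' @param path output file.
#' @param meta optional character vector written as `#`-prefixed lines.
#' @export
writeTsv <- function(df, path, meta = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(meta)) writeLines(paste0("# ", meta), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a TSV written by [writeTsv()]
#' @param path input file.
#' @return data.frame.
#' @export
readTsv <- function(path) {
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write transcript sequences as FASTA
#' @param records transcript table with `transcript_id` and `sequence`.
#' @param path output file.
#' @export
writeTranscriptFasta <- function(records, path) {
    x <- Biostrings::DNAStringSet(stats::setNames(records$sequence,
                                                  records$transcript_id))
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Read a gene-to-term annotation TSV
#'
#' Expects columns `gene` and `term` (extra columns ignored).
#'
#' @param path input file.
#' @return named list gene -> character vector of term ids.
#' @export
readAnnotationTsv <- function(path) {
    df <- readTsv(path)
    lapply(split(df$term, df$gene), unique)
}

#' Convert a simulation config to a plain list (and back)
#' @param config a [SimulationConfig-class].
#' @return named list of all slots.
#' @export
configAsList <- function(config) {
    sl <- slotNames("SimulationConfig")
    stats::setNames(lapply(sl, function(s) slot(config, s)), sl)
}

#' @rdname configAsList
#' @param x named list as produced by [configAsList()] (or parsed from the
#'   manifest JSON).
#' @export
configFromList <- function(x) do.call(simulationConfig, x)

#' Write every synthetic input to disk
#'
#' Serialises a [simulateStudy()] result in the formats the pipeline reads:
#' transcript FASTA and TSV, direct-annotation TSV, the DAG as minimal OBO,
#' contamination and directional ortholog hit TSVs, targeting-prediction TSV,
#' branch-model fits TSV, the organellar exclusion list, and a JSON manifest
#' recording the full configuration. File contents are a pure function of
#' the config (identical seed, identical bytes).
#'
#' @param sim output of [simulateStudy()].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
writeSyntheticData <- function(sim, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p <- function(...) file.path(dir, ...)
    rec <- sim$transcripts$records
    writeTranscriptFasta(rec, p("transcripts.fasta"))
    writeTsv(rec[, setdiff(names(rec), "sequence")], p("transcripts.tsv"),
             meta = "synthetic transcript table")
    ann <- data.frame(
        gene = rep(names(sim$inventories$direct),
                   lengths(sim$inventories$direct)),
        term = unlist(sim$inventories$direct, use.names = FALSE),
        stringsAsFactors = FALSE)
    writeTsv(ann, p("annotation.tsv"), meta = "direct gene-to-term annotation")
    writeObo(sim$dag, p("dag.obo"))
    writeTsv(sim$hits$contamination, p("contamination_hits.tsv"))
    for (sp in names(sim$hits$ortholog)) {
        writeTsv(sim$hits$ortholog[[sp]]$ab,
                 p(sprintf("ortholog_hits_%s_ab.tsv", sp)))
        writeTsv(sim$hits$ortholog[[sp]]$ba,
                 p(sprintf("ortholog_hits_%s_ba.tsv", sp)))
    }
    writeTsv(sim$targeting$predictions, p("targeting.tsv"))
    writeTsv(sim$fits, p("fits.tsv"))
    writeLines(sim$inventories$organellar, p("organellar_genes.txt"))
    writeTsv(sim$inventories$species, p("species.tsv"))
    manifest <- p("manifest.json")
    jsonlite::write_json(configAsList(sim$config), manifest,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
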