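#' Read and write the pipeline's file formats
#'
#' Plain-text interchange used between stages: TSV count matrices with a
#' sample sheet, GMT gene sets, a pathway edge table, gene lengths, the
#' autophagy gene list, the clinical/survival table, and the JSON planted
#' truth. All writers emit deterministic, diff-friendly files.
#'
#' @param path file path.
#' @param pheno optional sample sheet (`sample`, `group`, `batch`) to
#'   attach as `colData`.
#' @return `readCountsTsv` returns a
#'   [SummarizedExperiment::SummarizedExperiment] with a `counts` assay.
#' @name pagicross-io
NULL

#' @rdname pagicross-io
#' @export
readCountsTsv <- function(path, pheno = NULL) {
    df <- read.delim(path, check.names = FALSE, row.names = 1)
    m <- as.matrix(df)
    storage.mode(m) <- "integer"
    cd <- if (!is.null(pheno)) {
        stopifnot(all(colnames(m) %in% pheno$sample))
        S4Vectors::DataFrame(pheno[match(colnames(m), pheno$sample), , drop = FALSE])
    } else S4Vectors::DataFrame(row.names = colnames(m))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = m), colData = cd)
}

#' @rdname pagicross-io
#' @param se a `SummarizedExperiment` with a `counts` assay.
#' @export
writeCountsTsv <- function(se, path) {
    m <- countsOf(se)
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname pagicross-io
#' @export
readPheno <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' @rdname pagicross-io
#' @export
readGeneLengths <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    setNames(df$length, df$gene)
}

#' @rdname pagicross-io
#' @export
readSurvivalTsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' @rdname pagicross-io
#' @param collection a [PathwayCollection-class].
#' @export
writeGmt <- function(collection, path) {
    lines <- vapply(seq_along(collection@ids), function(i) {
        paste(c(collection@ids[i], collection@pathwayNames[i],
                collection@genes[[i]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname pagicross-io
#' @param edgePath path of the within-pathway edge table (written and read
#'   alongside the GMT; the GMT alone carries membership only).
#' @export
readPathwayCollection <- function(path, edgePath = NULL) {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ids <- vapply(parts, `[`, character(1), 1)
    nms <- vapply(parts, `[`, character(1), 2)
    genes <- lapply(parts, function(p) p[-(1:2)])
    edges <- if (!is.null(edgePath) && file.exists(edgePath))
        read.delim(edgePath, stringsAsFactors = FALSE)
    else data.frame(pathway = character(), from = character(),
                    to = character())
    PathwayCollection(ids, genes, nms, edges)
}

#' @rdname pagicross-io
#' @export
writePathwayEdges <- function(collection, path) {
    write.table(collection@edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Write a full synthetic study to a directory
#'
#' Emits `mrna_counts.tsv`, `lnc_counts.tsv`, `pheno.tsv`, `survival.tsv`,
#' `pathways.gmt`, `pathway_edges.tsv`, `gene_lengths.tsv`,
#' `autophagy_genes.txt` and `truth.json`.
#'
#' @param sim result of [simulateCrosstalkStudy()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fp <- function(f) file.path(dir, f)
    writeCountsTsv(sim$mrna, fp("mrna_counts.tsv"))
    writeCountsTsv(sim$lnc, fp("lnc_counts.tsv"))
    cd <- SummarizedExperiment::colData(sim$mrna)
    write.table(data.frame(sample = rownames(cd), group = cd$group,
                           batch = cd$batch),
                fp("pheno.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sim$survival, fp("survival.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeGmt(sim$pathways, fp("pathways.gmt"))
    writePathwayEdges(sim$pathways, fp("pathway_edges.tsv"))
    rd <- SummarizedExperiment::rowData(sim$mrna)
    lens <- data.frame(gene = rownames(sim$mrna), length = rd$length)
    rdl <- SummarizedExperiment::rowData(sim$lnc)
    lens <- rbind(lens, data.frame(gene = rownames(sim$lnc),
                                   length = rdl$length))
    write.table(lens, fp("gene_lengths.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines(sim$truth$autophagy_genes, fp("autophagy_genes.txt"))
    jsonlite::write_json(sim$truth, fp("truth.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(dir)
}

#' @rdname pagicross-io
#' @export
readTruth <- function(path) {
    tr <- jsonlite::read_json(path, simplifyVector = TRUE)
    tr$de_lnc <- setNames(as.numeric(tr$de_lnc), names(tr$de_lnc))
    tr$module_assignments <- setNames(as.character(tr$module_assignments),
                                      names(tr$module_assignments))
    tr
}
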