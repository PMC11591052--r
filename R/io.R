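## Plain-text readers/writers for the pipeline's tabular interfaces.

#' Read a count matrix and sample sheet into a DECountSet
#'
#' The counts TSV has `gene_id` as its first column and sample ids as the
#' remaining column headers; the sample sheet TSV maps `sample_id` to
#' `group` (`control`/`treated`). An optional gene-metadata TSV
#' (`gene_id`, `transcript_length_bp`) attaches transcript lengths.
#'
#' @param countsPath,samplesPath,geneMetaPath TSV file paths
#'   (`geneMetaPath` optional).
#' @return A [DECountSet-class].
#' @export
readCountMatrix <- function(countsPath, samplesPath, geneMetaPath = NULL) {
    cts <- read.delim(countsPath, check.names = FALSE)
    m <- as.matrix(cts[, -1, drop = FALSE])
    rownames(m) <- cts[[1]]
    ss <- read.delim(samplesPath)
    if (!all(c("sample_id", "group") %in% colnames(ss)))
        stop("sample sheet needs columns sample_id, group")
    i <- match(colnames(m), ss$sample_id)
    if (anyNA(i))
        stop("sample sheet is missing sample(s): ",
             paste(colnames(m)[is.na(i)], collapse = ", "))
    tl <- NULL
    if (!is.null(geneMetaPath)) {
        gm <- readGeneMeta(geneMetaPath)
        tl <- gm$transcript_length_bp[match(rownames(m), gm$gene_id)]
    }
    DECountSet(m, ss$group[i], transcriptLength = tl)
}

#' @rdname readCountMatrix
#' @param se a [DECountSet-class].
#' @param dir output directory; writes `counts.tsv`, `samples.tsv` and, if
#'   lengths are present, `gene_meta.tsv`.
#' @export
writeCountMatrix <- function(se, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cts <- data.frame(gene_id = rownames(se), counts(se), check.names = FALSE)
    write.table(cts, file.path(dir, "counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample_id = colnames(se),
                           group = as.character(sampleGroups(se))),
                file.path(dir, "samples.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tl <- geneLengths(se)
    if (!is.null(tl))
        write.table(data.frame(gene_id = rownames(se),
                               transcript_length_bp = tl),
                    file.path(dir, "gene_meta.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' Read a gene-metadata TSV
#'
#' @param path TSV with columns `gene_id`, `transcript_length_bp`.
#' @return data.frame.
#' @export
readGeneMeta <- function(path) {
    gm <- read.delim(path)
    if (!all(c("gene_id", "transcript_length_bp") %in% colnames(gm)))
        stop("gene metadata needs columns gene_id, transcript_length_bp")
    gm
}
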