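## Transcript-length fold-change bias correction: diagnose the dependence of
## LogFC on log2 transcript length, subtract the OLS line, reconcile initial
## and corrected estimates by the min-abs / sign-flip rule, and call DE genes.

#' Fit the LogFC ~ LogTL trend
#'
#' Ordinary least squares of the initial log2 fold change on log2 transcript
#' length (with intercept), plus Spearman (average ranks for ties) and
#' Pearson correlation diagnostics. Genes without a finite LogFC or a
#' positive length are excluded and counted.
#'
#' @param de DE table as returned by [runDE()] (needs `gene_id`, `logfc`).
#' @param geneMeta data.frame with `gene_id` and `transcript_length_bp`, or a
#'   [DECountSet-class] carrying lengths in its `rowData`.
#' @param genes optional character vector restricting the fit to a subset of
#'   gene ids (e.g. expressed genes); default all.
#' @return A [CorrectionModel-class].
#' @examples
#' de <- data.frame(gene_id = c("a", "b", "c"), logfc = c(1, 2, 2))
#' meta <- data.frame(gene_id = c("a", "b", "c"),
#'                    transcript_length_bp = 2^(1:3))
#' fitCorrection(de, meta)  # slope 0.5, intercept 2/3
#' @export
fitCorrection <- function(de, geneMeta, genes = NULL) {
    d <- .joinLengths(de, geneMeta)
    if (!is.null(genes)) d <- d[d$gene_id %in% genes, , drop = FALSE]
    usable <- is.finite(d$logfc) & !is.na(d$log2tl)
    nMissing <- sum(!usable)
    d <- d[usable, , drop = FALSE]
    if (nrow(d) < 3L)
        stop("fewer than 3 genes with finite LogFC and positive length")
    x <- d$log2tl; y <- d$logfc
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0)
        stop("degenerate regression: all transcript lengths identical")
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    intercept <- mean(y) - slope * mean(x)
    rho <- if (sd(y) == 0) {
        warning("LogFC constant across genes; Spearman rho set to 0")
        0
    } else cor(x, y, method = "spearman")
    r <- if (sd(y) == 0) 0 else cor(x, y)
    new("CorrectionModel", slope = slope, intercept = intercept,
        spearmanRho = rho, pearsonR = r, nGenes = nrow(d),
        nMissingLength = as.integer(nMissing))
}

## merge a DE table with gene lengths; accepts a DECountSet or a data.frame
.joinLengths <- function(de, geneMeta) {
    if (is(geneMeta, "DECountSet")) {
        tl <- geneLengths(geneMeta)
        if (is.null(tl)) stop("DECountSet carries no transcript lengths")
        geneMeta <- data.frame(gene_id = names(tl), transcript_length_bp = tl)
    }
    if (!all(c("gene_id", "transcript_length_bp") %in% colnames(geneMeta)))
        stop("geneMeta needs columns gene_id, transcript_length_bp")
    i <- match(de$gene_id, geneMeta$gene_id)
    tl <- geneMeta$transcript_length_bp[i]
    tl[!is.na(tl) & tl <= 0] <- NA
    data.frame(de, log2tl = log2(tl))
}

#' Reconcile initial and length-corrected log2 fold changes
#'
#' The conservative rule applied after subtracting the fitted length trend:
#' keep whichever of the initial and corrected LogFC has the smaller
#' absolute value (sign preserved), and set the result to zero when their
#' signs differ. A zero on either side counts as a sign disagreement, so the
#' result is 0 whenever `initial * corrected <= 0` (both-zero included).
#'
#' @param initial,corrected finite numeric vectors (recycled to a common
#'   length).
#' @return numeric vector of reconciled log2 fold changes with
#'   `|result| <= min(|initial|, |corrected|)`.
#' @examples
#' reconcileLogFC(c(0.8, 0.8, -0.5, 0), c(0.3, -0.2, -0.9, 0))
#' # 0.3, 0, -0.5, 0
#' @export
reconcileLogFC <- function(initial, corrected) {
    if (any(!is.finite(initial)) || any(!is.finite(corrected)))
        stop("initial and corrected LogFC must be finite")
    n <- max(length(initial), length(corrected))
    initial <- rep_len(initial, n)
    corrected <- rep_len(corrected, n)
    out <- ifelse(abs(corrected) < abs(initial), corrected, initial)
    out[initial * corrected <= 0] <- 0
    out
}

#' Length-bias-correct a DE table and call DE genes
#'
#' Fits the LogFC ~ LogTL line (on all usable genes, or a subset via
#' `fitGenes`), subtracts it (`corrected = initial - (intercept + slope *
#' LogTL)`), reconciles with [reconcileLogFC()], and calls each gene `up`,
#' `down` or `not_significant` against the FDR and |LogFC| thresholds.
#' P-values and FDR are not recomputed: the correction touches effect size
#' only, while significance derives from the counts. Genes without a usable
#' length keep their initial LogFC (flagged in `length_missing`).
#'
#' @param de DE table from [runDE()] (`gene_id`, `logfc`, `fdr`).
#' @param geneMeta gene lengths, as in [fitCorrection()].
#' @param fdrThreshold FDR gate, in (0, 1\] (default 0.05).
#' @param logfcThreshold minimum |final LogFC| (default 0.1), > 0.
#' @param fitGenes optional gene-id subset for the fit.
#' @return list with `table` (data.frame: `gene_id`, `initial_logfc`,
#'   `corrected_logfc`, `final_logfc`, `fdr`, `call`, `length_missing`) and
#'   `model` (the [CorrectionModel-class]).
#' @export
correctTable <- function(de, geneMeta, fdrThreshold = 0.05,
                         logfcThreshold = 0.1, fitGenes = NULL) {
    if (fdrThreshold <= 0 || fdrThreshold > 1)
        stop("fdrThreshold must lie in (0, 1]")
    if (logfcThreshold <= 0)
        stop("logfcThreshold must be > 0")
    if (!"fdr" %in% colnames(de))
        stop("DE table needs an fdr column")
    model <- fitCorrection(de, geneMeta, genes = fitGenes)
    d <- .joinLengths(de, geneMeta)
    miss <- is.na(d$log2tl)
    corrected <- d$logfc - (model@intercept + model@slope * d$log2tl)
    corrected[miss] <- d$logfc[miss]
    final <- reconcileLogFC(d$logfc, corrected)
    call <- rep("not_significant", nrow(d))
    call[d$fdr <= fdrThreshold & final >= logfcThreshold] <- "up"
    call[d$fdr <= fdrThreshold & final <= -logfcThreshold] <- "down"
    list(table = data.frame(
             gene_id = d$gene_id,
             initial_logfc = d$logfc,
             corrected_logfc = corrected,
             final_logfc = final,
             fdr = d$fdr,
             call = factor(call, levels = c("up", "down", "not_significant")),
             length_missing = miss,
             row.names = NULL),
         model = model)
}
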