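#' @import methods
#' @importFrom stats aggregate cor median pbinom pnorm pt qnorm rnbinom rnorm
#'   rpois runif sd setNames t.test uniroot var p.adjust
#' @importFrom utils combn read.csv write.csv read.delim write.table
#'   packageVersion head
#' @importFrom BiocGenerics counts sizeFactors
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.PHASES <- c("basal", "post_oligomycin", "post_rotaa")
.GROUPS <- c("control", "treated")

## ---------------------------------------------------------------------------
## DECountSet
## ---------------------------------------------------------------------------

#' Two-group RNA-seq count container
#'
#' `DECountSet` extends [SummarizedExperiment::SummarizedExperiment] with the
#' constraints the differential-expression engine relies on: a single integer
#' `"counts"` assay, a two-level `group` factor (`control`, `treated`) in
#' `colData`, and (optionally) a `transcript_length_bp` column in `rowData`
#' used by the length-bias correction.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @aliases DECountSet-class
#' @exportClass DECountSet
setClass("DECountSet", contains = "SummarizedExperiment")

setValidity("DECountSet", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
            msg <- c(msg, "counts must be finite nonnegative integers")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!"group" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'group' column")
    else {
        g <- cd$group
        if (!is.factor(g) || !identical(levels(g), .GROUPS))
            msg <- c(msg, "group must be a factor with levels control, treated")
        else if (any(table(g) == 0L))
            msg <- c(msg, "both groups must be non-empty")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicated gene ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicated sample ids")
    if ("transcript_length_bp" %in% colnames(SummarizedExperiment::rowData(object))) {
        tl <- SummarizedExperiment::rowData(object)$transcript_length_bp
        if (any(!is.na(tl) & tl <= 0))
            msg <- c(msg, "transcript_length_bp must be positive")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a DECountSet
#'
#' @param counts integer matrix, genes x samples, with row and column names.
#' @param group character or factor assigning each sample to `"control"` or
#'   `"treated"` (recycled against `colnames(counts)` by position).
#' @param transcriptLength optional numeric vector of transcript lengths in bp,
#'   one per gene (named or positional).
#'
#' @return A validated [DECountSet-class] object.
#' @examples
#' m <- matrix(rpois(24, 50), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
#' se <- DECountSet(m, rep(c("control", "treated"), each = 3))
#' @export
DECountSet <- function(counts, group, transcriptLength = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("sample%02d", seq_len(ncol(counts)))
    storage.mode(counts) <- "integer"
    group <- factor(as.character(group), levels = .GROUPS)
    if (anyNA(group))
        stop("every sample must be assigned to 'control' or 'treated'")
    cd <- S4Vectors::DataFrame(group = group, row.names = colnames(counts))
    rd <- S4Vectors::DataFrame(row.names = rownames(counts))
    if (!is.null(transcriptLength)) {
        if (!is.null(names(transcriptLength)))
            transcriptLength <- transcriptLength[rownames(counts)]
        rd$transcript_length_bp <- as.numeric(transcriptLength)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd, rowData = rd)
    new("DECountSet", se)
}

#' @describeIn DECountSet sample-to-group assignment (factor).
#' @param x,object a `DECountSet`.
#' @export
sampleGroups <- function(x) SummarizedExperiment::colData(x)$group

#' @describeIn DECountSet transcript lengths in bp (or `NULL` if absent).
#' @export
geneLengths <- function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if ("transcript_length_bp" %in% colnames(rd))
        setNames(rd$transcript_length_bp, rownames(x)) else NULL
}

#' @rdname DECountSet
#' @export
setMethod("counts", "DECountSet", function(object, ...) {
    SummarizedExperiment::assay(object, "counts")
})

setMethod("show", "DECountSet", function(object) {
    cat(sprintf("DECountSet: %d genes x %d samples (%d control, %d treated)\n",
                nrow(object), ncol(object),
                sum(sampleGroups(object) == "control"),
                sum(sampleGroups(object) == "treated")))
    if (!is.null(geneLengths(object)))
        cat("  rowData: transcript_length_bp present\n")
    md <- S4Vectors::metadata(object)
    if (!is.null(md$realized_spearman))
        cat(sprintf("  simulated; realized Spearman(LogFC, LogTL) = %.3f\n",
                    md$realized_spearman))
})

## ---------------------------------------------------------------------------
## CorrectionModel
## ---------------------------------------------------------------------------

#' Fitted LogFC ~ LogTL trend
#'
#' Ordinary-least-squares fit of per-gene log2 fold change on log2 transcript
#' length, with its rank and linear correlation diagnostics. Produced by
#' [fitCorrection()] and consumed by [correctTable()].
#'
#' @slot slope OLS slope, log2FC per log2 bp.
#' @slot intercept OLS intercept, log2FC.
#' @slot spearmanRho Spearman rank correlation (average ranks for ties).
#' @slot pearsonR Pearson correlation.
#' @slot nGenes number of genes used in the fit.
#' @slot nMissingLength genes dropped for missing/invalid length.
#' @aliases CorrectionModel-class
#' @exportClass CorrectionModel
setClass("CorrectionModel",
    representation(slope = "numeric", intercept = "numeric",
                   spearmanRho = "numeric", pearsonR = "numeric",
                   nGenes = "integer", nMissingLength = "integer"))

setValidity("CorrectionModel", function(object) {
    msg <- character()
    if (length(object@slope) != 1L || !is.finite(object@slope))
        msg <- c(msg, "slope must be a finite scalar")
    if (length(object@intercept) != 1L || !is.finite(object@intercept))
        msg <- c(msg, "intercept must be a finite scalar")
    if (abs(object@spearmanRho) > 1 + 1e-12)
        msg <- c(msg, "|spearmanRho| must be <= 1")
    if (abs(object@pearsonR) > 1 + 1e-12)
        msg <- c(msg, "|pearsonR| must be <= 1")
    if (object@nGenes < 3L)
        msg <- c(msg, "at least 3 genes are required")
    if (length(msg)) msg else TRUE
})

#' @describeIn CorrectionModel OLS slope (log2FC per log2 bp).
#' @param object a `CorrectionModel`.
#' @export
correctionSlope <- function(object) object@slope

#' @describeIn CorrectionModel OLS intercept (log2FC).
#' @export
correctionIntercept <- function(object) object@intercept

#' @describeIn CorrectionModel Spearman rank correlation of LogFC with LogTL.
#' @export
spearmanRho <- function(object) object@spearmanRho

#' @describeIn CorrectionModel Pearson correlation of LogFC with LogTL.
#' @export
pearsonR <- function(object) object@pearsonR

setMethod("show", "CorrectionModel", function(object) {
    cat("CorrectionModel (LogFC ~ LogTL)\n")
    cat(sprintf("  slope     %+.5f log2FC per log2 bp\n", object@slope))
    cat(sprintf("  intercept %+.5f log2FC\n", object@intercept))
    cat(sprintf("  Spearman rho %+.4f ; Pearson r %+.4f ; n = %d genes",
                object@spearmanRho, object@pearsonR, object@nGenes))
    if (object@nMissingLength > 0L)
        cat(sprintf(" (%d without length)", object@nMissingLength))
    cat("\n")
})

## ---------------------------------------------------------------------------
## SeahorseTraceSet
## ---------------------------------------------------------------------------

#' Three-phase extracellular-flux traces
#'
#' Per-well OCR/ECAR time series from a real-time ATP-rate assay: a basal
#' phase, a post-oligomycin phase (ATP-synthase inhibited) and a
#' post-rotenone/antimycin-A phase (electron transport abolished). Validity
#' enforces the assay structure: every well has at least one measurement in
#' each phase, phases appear in injection order, and time is strictly
#' increasing within a well.
#'
#' @slot traces data.frame with columns `well`, `group`, `phase`
#'   (`basal`/`post_oligomycin`/`post_rotaa`), `time_min`,
#'   `ocr_pmol_per_min`, `ecar_mpH_per_min`.
#' @aliases SeahorseTraceSet-class
#' @exportClass SeahorseTraceSet
setClass("SeahorseTraceSet", representation(traces = "data.frame"))

.TRACE_COLS <- c("well", "group", "phase", "time_min",
                 "ocr_pmol_per_min", "ecar_mpH_per_min")

setValidity("SeahorseTraceSet", function(object) {
    tr <- object@traces
    if (!all(.TRACE_COLS %in% colnames(tr)))
        return(paste("traces must have columns:",
                     paste(.TRACE_COLS, collapse = ", ")))
    if (!all(tr$phase %in% .PHASES))
        return("phase must be one of basal, post_oligomycin, post_rotaa")
    if (any(!is.finite(tr$ocr_pmol_per_min)) ||
        any(!is.finite(tr$ecar_mpH_per_min)) || any(!is.finite(tr$time_min)))
        return("OCR, ECAR and time must be finite")
    msg <- character()
    for (w in unique(tr$well)) {
        sub <- tr[tr$well == w, , drop = FALSE]
        sub <- sub[order(sub$time_min), , drop = FALSE]
        missing <- setdiff(.PHASES, sub$phase)
        if (length(missing))
            msg <- c(msg, sprintf("well %s is missing phase(s): %s",
                                  w, paste(missing, collapse = ", ")))
        if (any(diff(sub$time_min) <= 0))
            msg <- c(msg, sprintf("well %s: time is not strictly increasing", w))
        ph <- as.integer(factor(sub$phase, levels = .PHASES))
        if (is.unsorted(ph))
            msg <- c(msg, sprintf("well %s: phases out of injection order", w))
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a SeahorseTraceSet
#'
#' @param traces data.frame with the documented trace columns; rows are
#'   re-sorted by (well, time).
#' @return A validated [SeahorseTraceSet-class].
#' @seealso [readSeahorseTraces()], [simulateSeahorse()]
#' @export
SeahorseTraceSet <- function(traces) {
    traces <- as.data.frame(traces)
    if (!all(.TRACE_COLS %in% colnames(traces)))
        stop("trace table must have columns: ",
             paste(.TRACE_COLS, collapse = ", "))
    traces <- traces[order(traces$well, traces$time_min), .TRACE_COLS,
                     drop = FALSE]
    rownames(traces) <- NULL
    new("SeahorseTraceSet", traces = traces)
}

#' @describeIn SeahorseTraceSet the underlying trace data.frame.
#' @param x,object a `SeahorseTraceSet`.
#' @export
traces <- function(x) x@traces

#' @describeIn SeahorseTraceSet well identifiers.
#' @export
wells <- function(x) unique(x@traces$well)

setMethod("show", "SeahorseTraceSet", function(object) {
    tr <- object@traces
    cat(sprintf("SeahorseTraceSet: %d wells, %d groups, %d measurements\n",
                length(unique(tr$well)), length(unique(tr$group)), nrow(tr)))
    cat("  groups:", paste(unique(tr$group), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## ATPConstants
## ---------------------------------------------------------------------------

#' Constants of the real-time ATP-rate decomposition
#'
#' The vendor-defined constants of the extracellular-flux ATP calculation:
#' `poRatio` (pmol ATP per pmol atomic O, default 2.75), `oPerO2` (2 oxygen
#' atoms per O2), `ccf` (CO2 contribution factor, pmol H+ per pmol O2,
#' default 0.61), and the ECAR-to-proton-efflux conversion
#' `bufferFactor * chamberVolumeUl * kvol`. The conversion product defaults
#' to 1 so that ECAR is taken as an already-calibrated proton efflux rate;
#' set the instrument- and medium-specific values from the assay
#' configuration when absolute glycolytic rates are needed.
#'
#' @param poRatio,oPerO2,ccf,bufferFactor,chamberVolumeUl,kvol strictly
#'   positive scalars, see above.
#' @return An `ATPConstants` object for [atpRates()].
#' @aliases ATPConstants-class
#' @examples
#' atpConstants()
#' @export
atpConstants <- function(poRatio = 2.75, oPerO2 = 2, ccf = 0.61,
                         bufferFactor = 1, chamberVolumeUl = 1, kvol = 1) {
    new("ATPConstants", poRatio = poRatio, oPerO2 = oPerO2, ccf = ccf,
        bufferFactor = bufferFactor, chamberVolumeUl = chamberVolumeUl,
        kvol = kvol)
}

#' @exportClass ATPConstants
setClass("ATPConstants",
    representation(poRatio = "numeric", oPerO2 = "numeric", ccf = "numeric",
                   bufferFactor = "numeric", chamberVolumeUl = "numeric",
                   kvol = "numeric"))

setValidity("ATPConstants", function(object) {
    v <- c(object@poRatio, object@oPerO2, object@ccf, object@bufferFactor,
           object@chamberVolumeUl, object@kvol)
    if (length(v) != 6L || any(!is.finite(v)) || any(v <= 0))
        "all ATP-rate constants must be finite and strictly positive"
    else TRUE
})

setMethod("show", "ATPConstants", function(object) {
    cat(sprintf(paste0("ATPConstants: P/O = %.3g, O/O2 = %.3g, CCF = %.3g, ",
                       "ECAR->PER factor = %.3g\n"),
                object@poRatio, object@oPerO2, object@ccf,
                object@bufferFactor * object@chamberVolumeUl * object@kvol))
})
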