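## End-to-end orchestration (counts -> DE -> length-bias correction, plus the
## optional flux and bench-assay branches) and the dose-conversion utility.

#' Run the full analysis pipeline
#'
#' Runs the differential-expression engine and the transcript-length bias
#' correction on a count matrix, the ATP-rate decomposition on flux traces
#' when given, and percent-of-control plus the two-group test on bench-assay
#' tables when given. Inputs may be in-memory objects or file paths (TSV for
#' counts/sample sheet/gene metadata, CSV for traces). All results are
#' returned in a run report and, if `outDir` is set, written as TSV.
#'
#' @param counts a [DECountSet-class] or counts TSV path.
#' @param samples sample-sheet TSV path (only when `counts` is a path).
#' @param geneMeta gene-length table (data.frame or TSV path); defaults to
#'   lengths carried by `counts`.
#' @param traces a [SeahorseTraceSet-class] or traces CSV path (optional).
#' @param assays named list of assay tables (`sample`, `group`, `value`),
#'   optional.
#' @param fdrThreshold,logfcThreshold DE calling thresholds
#'   (defaults 0.05 and 0.1).
#' @param priorCount fold-change prior count (default 0.5).
#' @param constants [atpConstants()] for the ATP decomposition.
#' @param controlGroup control label for flux/assay branches.
#' @param outDir optional output directory for TSV results.
#' @return list of class `ecdymetReport`: `n_genes_tested`, `n_up`,
#'   `n_down`, `model` ([CorrectionModel-class]), `de` (corrected DE table),
#'   `atp` (per-well rates), `atp_summary`, `assay_summaries`, `version`,
#'   `config`.
#' @examples
#' se <- simulateCounts(simCountsConfig(n_genes = 300, seed = 11))
#' rep <- runPipeline(se)
#' rep$n_up + rep$n_down <= rep$n_genes_tested
#' @export
runPipeline <- function(counts, samples = NULL, geneMeta = NULL,
                        traces = NULL, assays = NULL,
                        fdrThreshold = 0.05, logfcThreshold = 0.1,
                        priorCount = 0.5, constants = atpConstants(),
                        controlGroup = "control", outDir = NULL) {
    se <- if (is.character(counts)) {
        if (is.null(samples))
            stop("stage counts: a sample sheet path is required with a counts path")
        readCountMatrix(counts, samples,
                        if (is.character(geneMeta)) geneMeta else NULL)
    } else counts
    stopifnot(is(se, "DECountSet"))
    meta <- if (is.null(geneMeta) || is.character(geneMeta)) se
            else geneMeta
    de <- .stage("de", runDE(se, priorCount = priorCount))
    corr <- .stage("lenbias",
                   correctTable(de, meta, fdrThreshold = fdrThreshold,
                                logfcThreshold = logfcThreshold))
    nUp <- sum(corr$table$call == "up")
    nDown <- sum(corr$table$call == "down")

    atp <- atpSummary <- NULL
    if (!is.null(traces)) {
        ts <- if (is.character(traces)) readSeahorseTraces(traces) else traces
        atp <- .stage("seahorse", atpRates(phaseRates(ts), constants))
        atpSummary <- .stage("seahorse",
                             summarizeAtpByGroup(atp, controlGroup))
    }
    assaySummaries <- NULL
    if (!is.null(assays)) {
        assaySummaries <- lapply(assays, function(tab) {
            tab <- .stage("assays", percentOfControl(tab, controlGroup))
            tst <- twoGroupTest(tab$value[tab$group != controlGroup],
                                tab$value[tab$group == controlGroup])
            list(table = tab, test = tst)
        })
    }
    report <- structure(list(
        n_genes_tested = nrow(corr$table),
        n_up = nUp, n_down = nDown,
        model = corr$model, de = corr$table,
        atp = atp, atp_summary = atpSummary,
        assay_summaries = assaySummaries,
        version = as.character(packageVersion("ecdymet")),
        config = list(fdrThreshold = fdrThreshold,
                      logfcThreshold = logfcThreshold,
                      priorCount = priorCount, constants = constants,
                      controlGroup = controlGroup)),
        class = "ecdymetReport")
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        write.table(corr$table, file.path(outDir, "de_corrected.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(atp)) {
            write.table(atp, file.path(outDir, "atp_rates.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            write.table(atpSummary, file.path(outDir, "atp_summary.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        }
        writeLines(utils::capture.output(print(report)),
                   file.path(outDir, "report.txt"))
    }
    report
}

## wrap a pipeline stage so failures carry the stage name
.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

#' @export
print.ecdymetReport <- function(x, ...) {
    cat("ecdymet run report (v", x$version, ")\n", sep = "")
    cat(sprintf("  genes tested: %d; up: %d; down: %d (FDR <= %g, |LogFC| >= %g)\n",
                x$n_genes_tested, x$n_up, x$n_down,
                x$config$fdrThreshold, x$config$logfcThreshold))
    cat(sprintf("  length-bias fit: slope %+.4f, Spearman rho %+.3f\n",
                correctionSlope(x$model), spearmanRho(x$model)))
    if (!is.null(x$atp_summary)) {
        cat("  ATP production (fold vs control):\n")
        s <- x$atp_summary[x$atp_summary$fold_vs_control != 1 |
                           !is.na(x$atp_summary$pvalue), ]
        for (i in seq_len(nrow(x$atp_summary))) {
            r <- x$atp_summary[i, ]
            cat(sprintf("    %-8s %-10s mean %8.2f +/- %6.2f  fold %5.2f  p %s\n",
                        r$group, r$measure, r$mean, r$sem, r$fold_vs_control,
                        ifelse(is.na(r$pvalue), "-",
                               format(round(r$pvalue, 4)))))
        }
    }
    if (!is.null(x$assay_summaries)) {
        for (nm in names(x$assay_summaries)) {
            tst <- x$assay_summaries[[nm]]$test
            cat(sprintf("  assay %s: %s p = %.4f (%s)\n", nm, tst$test_name,
                        tst$pvalue, tst$significance_label))
        }
    }
    invisible(x)
}

#' Convert a mass concentration to molarity
#'
#' `uM = (ng/mL) / (g/mol)`: e.g. plasma levels of 350-650 ng/mL of
#' 20-hydroxyecdysone (MW 480.64 g/mol) correspond to 0.73-1.35 uM (shown
#' at 2 decimals; full precision is returned).
#'
#' @param ng_per_ml mass concentration(s) in ng/mL, > 0.
#' @param mw molecular weight in g/mol, > 0.
#' @return concentration(s) in micromolar.
#' @examples
#' round(massToMolar(c(350, 650), 480.64), 2)  # 0.73 1.35
#' @export
massToMolar <- function(ng_per_ml, mw) {
    if (any(!is.finite(ng_per_ml)) || any(ng_per_ml <= 0))
        stop("concentration must be positive")
    if (length(mw) != 1L || !is.finite(mw) || mw <= 0)
        stop("molecular weight must be a positive scalar")
    ng_per_ml / mw
}
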