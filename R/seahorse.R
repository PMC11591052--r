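## Extracellular-flux trace parsing and the real-time ATP-rate decomposition
## into mitochondrial and glycolytic production rates.

#' Read / write three-phase flux traces
#'
#' CSV columns: `well, group, phase, time_min, ocr_pmol_per_min,
#' ecar_mpH_per_min` with `phase` one of `basal`, `post_oligomycin`,
#' `post_rotaa`. Reading validates the assay structure (every well covers
#' all three phases in injection order, strictly increasing time) and sorts
#' rows by (well, time); errors name the offending well.
#'
#' @param path CSV file path.
#' @return `readSeahorseTraces`: a [SeahorseTraceSet-class].
#' @export
readSeahorseTraces <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(.TRACE_COLS, colnames(df))
    if (length(missing))
        stop("format error: missing column(s) ",
             paste(missing, collapse = ", "), " in ", path)
    SeahorseTraceSet(df)
}

#' @rdname readSeahorseTraces
#' @param x a [SeahorseTraceSet-class].
#' @return `writeSeahorseTraces`: `path`, invisibly.
#' @export
writeSeahorseTraces <- function(x, path) {
    stopifnot(is(x, "SeahorseTraceSet"))
    write.csv(traces(x), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Per-well phase rates
#'
#' Reduces each well's trace to the four quantities the ATP decomposition
#' needs. The default (`stat = "plugin"`) follows the vendor convention:
#' last basal-phase OCR and ECAR, minimum OCR within each post-injection
#' phase (the maximal inhibitor response). `stat = "mean"` uses phase means
#' throughout.
#'
#' @param x a [SeahorseTraceSet-class].
#' @param stat `"plugin"` (last basal / min post-injection) or `"mean"`.
#' @return data.frame with one row per well: `well`, `group`, `ocr_basal`,
#'   `ocr_oligo`, `ocr_rotaa`, `ecar_basal`.
#' @examples
#' ts <- simulateSeahorse(simSeahorseConfig(noise_cv = 0))
#' phaseRates(ts)
#' @export
phaseRates <- function(x, stat = c("plugin", "mean")) {
    stopifnot(is(x, "SeahorseTraceSet"))
    stat <- match.arg(stat)
    tr <- traces(x)
    ws <- unique(tr$well)
    pick <- function(v, last) if (stat == "mean") mean(v)
                              else if (last) v[length(v)] else min(v)
    out <- lapply(ws, function(w) {
        sub <- tr[tr$well == w, , drop = FALSE]  # already time-sorted
        bas <- sub[sub$phase == "basal", , drop = FALSE]
        oli <- sub[sub$phase == "post_oligomycin", , drop = FALSE]
        rot <- sub[sub$phase == "post_rotaa", , drop = FALSE]
        data.frame(well = w, group = sub$group[1],
                   ocr_basal = pick(bas$ocr_pmol_per_min, TRUE),
                   ocr_oligo = pick(oli$ocr_pmol_per_min, FALSE),
                   ocr_rotaa = pick(rot$ocr_pmol_per_min, FALSE),
                   ecar_basal = pick(bas$ecar_mpH_per_min, TRUE))
    })
    do.call(rbind, out)
}

#' Decompose ATP production into mitochondrial and glycolytic rates
#'
#' The real-time ATP-rate calculation: the oligomycin-sensitive OCR drop is
#' ATP-linked respiration,
#' `mito_atp = max(0, ocr_basal - ocr_oligo) * oPerO2 * poRatio`
#' (pmol ATP/min); basal ECAR is converted to a proton efflux rate
#' `PER = ecar_basal * bufferFactor * chamberVolumeUl * kvol`, the
#' mitochondrial (CO2-derived) acidification
#' `mitoPER = max(0, ocr_basal - ocr_rotaa) * ccf` is subtracted, and the
#' remainder is glycolytic ATP (1 ATP per exported H+):
#' `glyco_atp = max(0, PER - mitoPER)`. Negative intermediate rates (noise)
#' are clamped to zero with a warning; `total_atp = mito_atp + glyco_atp`.
#'
#' @param rates per-well phase rates from [phaseRates()].
#' @param constants an [atpConstants()] object.
#' @return data.frame per well: the phase rates plus `mito_atp`,
#'   `glyco_atp`, `total_atp` (pmol ATP/min) and `clamped`.
#' @examples
#' r <- data.frame(well = "A1", group = "control", ocr_basal = 100,
#'                 ocr_oligo = 40, ocr_rotaa = 10, ecar_basal = 60)
#' atpRates(r)$mito_atp  # (100 - 40) * 2 * 2.75 = 330
#' @export
atpRates <- function(rates, constants = atpConstants()) {
    stopifnot(is(constants, "ATPConstants"))
    validObject(constants)
    need <- c("well", "group", "ocr_basal", "ocr_oligo", "ocr_rotaa",
              "ecar_basal")
    if (!all(need %in% colnames(rates)))
        stop("rates needs columns: ", paste(need, collapse = ", "))
    dOligo <- rates$ocr_basal - rates$ocr_oligo
    dRotaa <- rates$ocr_basal - rates$ocr_rotaa
    per <- rates$ecar_basal * constants@bufferFactor *
        constants@chamberVolumeUl * constants@kvol
    mitoPer <- pmax(0, dRotaa) * constants@ccf
    mito <- pmax(0, dOligo) * constants@oPerO2 * constants@poRatio
    glyco <- pmax(0, per - mitoPer)
    clamped <- (dOligo < 0) | (dRotaa < 0) | (per - mitoPer < 0)
    if (any(clamped))
        warning("negative intermediate rate(s) clamped to 0 in well(s): ",
                paste(rates$well[clamped], collapse = ", "))
    data.frame(rates, mito_atp = mito, glyco_atp = glyco,
               total_atp = mito + glyco, clamped = clamped)
}

#' Group summaries of ATP production rates
#'
#' Mean, SEM and fold-versus-control for `mito_atp`, `glyco_atp` and
#' `total_atp`, plus the two-sided exact Mann-Whitney p-value of each group
#' against the control group (exact enumeration for min(n1, n2) <= 8,
#' tie-corrected normal approximation above; see [mannWhitneyTest()]).
#'
#' @param results per-well table from [atpRates()].
#' @param controlGroup label of the control group (must have >= 2 wells).
#' @return data.frame with one row per (group, measure): `group`,
#'   `measure`, `n`, `mean`, `sem`, `fold_vs_control`, `pvalue` (NA for the
#'   control group itself).
#' @export
summarizeAtpByGroup <- function(results, controlGroup = "control") {
    if (!controlGroup %in% results$group)
        stop("unknown control group label: ", controlGroup)
    if (sum(results$group == controlGroup) < 2L)
        stop("control group needs at least 2 wells")
    measures <- c("mito_atp", "glyco_atp", "total_atp")
    groups <- unique(results$group)
    out <- list()
    for (m in measures) {
        ctrl <- results[results$group == controlGroup, m]
        for (g in groups) {
            v <- results[results$group == g, m]
            p <- if (g == controlGroup) NA_real_
                 else mannWhitneyTest(v, ctrl)$pvalue
            out[[length(out) + 1L]] <- data.frame(
                group = g, measure = m, n = length(v),
                mean = mean(v), sem = sd(v) / sqrt(length(v)),
                fold_vs_control = mean(v) / mean(ctrl), pvalue = p)
        }
    }
    do.call(rbind, out)
}
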