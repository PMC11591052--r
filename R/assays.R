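## Bench-assay arithmetic and the two-group tests with the study's N-based
## test selection (pooled-variance t for triplicates, exact Mann-Whitney for
## the five-replicate flux experiments).

#' Exact two-sided Mann-Whitney U test
#'
#' U is computed for `a` from mid-ranks of the pooled sample. For
#' `min(n1, n2) <= 8` the null distribution is obtained by full enumeration
#' of all `choose(n1 + n2, n1)` assignments of the pooled (possibly tied)
#' values, and the two-sided p doubles the smaller tail (observed value
#' included), capped at 1. Larger samples use the normal approximation with
#' tie correction and continuity correction.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list: `statistic` (U for `a`), `pvalue`, `n1`, `n2`, `method`
#'   (`"exact"` or `"normal"`).
#' @examples
#' mannWhitneyTest(1:5, 6:10)$pvalue  # 2/252
#' @export
mannWhitneyTest <- function(a, b) {
    if (length(a) < 2 || length(b) < 2)
        stop("each sample needs >= 2 observations")
    n1 <- length(a); n2 <- length(b); n <- n1 + n2
    r <- rank(c(a, b))  # mid-ranks
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    if (min(n1, n2) <= 8L) {
        cmb <- combn(n, n1)
        us <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
        eps <- 1e-9
        lower <- mean(us <= u + eps)
        upper <- mean(us >= u - eps)
        p <- min(1, 2 * min(lower, upper))
        method <- "exact"
    } else {
        mu <- n1 * n2 / 2
        ties <- table(r)
        sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
        if (sig2 == 0) {
            p <- 1
        } else {
            z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
            p <- min(1, 2 * pnorm(-abs(z)))
        }
        method <- "normal"
    }
    list(statistic = u, pvalue = p, n1 = n1, n2 = n2, method = method)
}

#' Significance label for a p-value
#'
#' The study's convention: `***` for p < 0.001, `**` for p < 0.01, `*` for
#' p < 0.05, otherwise `ns`.
#'
#' @param p p-value(s) in \[0, 1\].
#' @return character vector of labels.
#' @export
significanceLabel <- function(p) {
    ifelse(p < 0.001, "***",
           ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Two-group test with N-based selection
#'
#' `kind = "auto"` mirrors the study's rule: pooled-variance Student's t
#' for small designs (`min(n) <= 3`; `min(n) = 4` also falls back to t,
#' with a message) and the exact Mann-Whitney U test for `min(n) >= 5`.
#' Degenerate pooled variance is handled by convention: p = 1 when the
#' means are equal, p = 0 otherwise (logged via a message).
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param kind `"auto"`, `"student_t"` or `"mann_whitney"`.
#' @return list of class `TwoGroupResult`: `test_name`, `statistic`
#'   (t for `a - b`, or U for `a`), `pvalue`, `n1`, `n2`,
#'   `significance_label`.
#' @examples
#' twoGroupTest(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p = 0.0214, "*"
#' @export
twoGroupTest <- function(a, b, kind = c("auto", "student_t", "mann_whitney")) {
    kind <- match.arg(kind)
    if (length(a) < 2 || length(b) < 2)
        stop("each sample needs >= 2 observations")
    if (kind == "auto") {
        m <- min(length(a), length(b))
        if (m == 4L)
            message("min(n) = 4: falling back to Student's t")
        kind <- if (m >= 5L) "mann_whitney" else "student_t"
    }
    if (kind == "mann_whitney") {
        mw <- mannWhitneyTest(a, b)
        res <- list(test_name = "mann_whitney", statistic = mw$statistic,
                    pvalue = mw$pvalue, n1 = mw$n1, n2 = mw$n2)
    } else {
        n1 <- length(a); n2 <- length(b)
        sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
        if (sp2 == 0) {
            equal <- isTRUE(all.equal(mean(a), mean(b)))
            message("zero pooled variance: p set to ", if (equal) 1 else 0,
                    " by convention")
            res <- list(test_name = "student_t",
                        statistic = if (equal) 0 else sign(mean(a) - mean(b)) * Inf,
                        pvalue = if (equal) 1 else 0, n1 = n1, n2 = n2)
        } else {
            tt <- t.test(a, b, var.equal = TRUE)
            res <- list(test_name = "student_t",
                        statistic = unname(tt$statistic),
                        pvalue = tt$p.value, n1 = n1, n2 = n2)
        }
    }
    res$significance_label <- significanceLabel(res$pvalue)
    class(res) <- "TwoGroupResult"
    res
}

#' @export
print.TwoGroupResult <- function(x, ...) {
    cat(sprintf("%s: statistic = %.4g, p = %.4g (%s), n = %d vs %d\n",
                x$test_name, x$statistic, x$pvalue, x$significance_label,
                x$n1, x$n2))
    invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical-replicate Ct values are averaged per (sample, gene); per sample
#' dCt = Ct(target) - Ct(reference); per gene ddCt = dCt - mean(control-group
#' dCt); relative expression = 2^-ddCt, so the control group is geometrically
#' centred at 1.
#'
#' @param table data.frame with columns `sample`, `group`, `gene`, `ct`.
#' @param referenceGene reference (housekeeping) gene id, measured in every
#'   sample.
#' @param controlGroup control group label (non-empty).
#' @return data.frame per (gene, sample): `sample`, `group`, `gene`,
#'   `delta_ct`, `delta_delta_ct`, `rel_expr`.
#' @export
ddctExpression <- function(table, referenceGene, controlGroup = "control") {
    need <- c("sample", "group", "gene", "ct")
    if (!all(need %in% colnames(table)))
        stop("qPCR table needs columns: ", paste(need, collapse = ", "))
    if (any(table$ct < 5 | table$ct > 40))
        warning("Ct value(s) outside the typical 5-40 cycle range")
    ## average technical replicates
    agg <- aggregate(ct ~ sample + group + gene, data = table, FUN = mean)
    refs <- agg[agg$gene == referenceGene, ]
    samples <- unique(agg$sample)
    noRef <- setdiff(samples, refs$sample)
    if (length(noRef))
        stop("missing reference gene Ct for sample(s): ",
             paste(noRef, collapse = ", "))
    if (!controlGroup %in% agg$group)
        stop("control group '", controlGroup, "' not present")
    tgt <- agg[agg$gene != referenceGene, ]
    tgt$delta_ct <- tgt$ct - refs$ct[match(tgt$sample, refs$sample)]
    out <- do.call(rbind, lapply(split(tgt, tgt$gene), function(d) {
        ctrlMean <- mean(d$delta_ct[d$group == controlGroup])
        d$delta_delta_ct <- d$delta_ct - ctrlMean
        d$rel_expr <- 2^(-d$delta_delta_ct)
        d
    }))
    rownames(out) <- NULL
    out[, c("sample", "group", "gene", "delta_ct", "delta_delta_ct",
            "rel_expr")]
}

#' Densitometry normalization to a loading control
#'
#' Band intensity divided by the loading-control (e.g. actin) intensity;
#' by default the ratios are rescaled so the control-group mean ratio is 1
#' (matching how such ratios are displayed), which makes the output
#' invariant to rescaling either channel.
#'
#' @param band,loading per-sample intensities; `loading` must be > 0.
#' @param group group label per sample.
#' @param controlGroup control group label.
#' @param rescale rescale to control mean 1 (default TRUE).
#' @return list: `values` (data.frame `group`, `ratio`) and `summary`
#'   (per-group `mean`, `sem`).
#' @export
densitometryNormalize <- function(band, loading, group,
                                  controlGroup = "control", rescale = TRUE) {
    if (any(!is.finite(loading)) || any(loading <= 0))
        stop("loading-control intensities must be positive")
    if (!controlGroup %in% group)
        stop("control group '", controlGroup, "' not present")
    ratio <- band / loading
    if (rescale)
        ratio <- ratio / mean(ratio[group == controlGroup])
    values <- data.frame(group = group, ratio = ratio)
    summary <- do.call(rbind, lapply(split(values$ratio, values$group),
        function(v) data.frame(mean = mean(v),
                               sem = sd(v) / sqrt(length(v)))))
    summary <- data.frame(group = rownames(summary), summary,
                          row.names = NULL)
    list(values = values, summary = summary)
}

#' Percent of control
#'
#' Each value divided by the control-group mean, times 100; the control
#' group averages to 100 by construction.
#'
#' @param table data.frame with columns `sample`, `group`, `value` (or any
#'   table with `group` and `value`).
#' @param controlGroup control group label; its mean value must be > 0.
#' @return the input with an added `percent_of_control` column.
#' @examples
#' percentOfControl(data.frame(group = rep(c("control", "treated"), each = 3),
#'                             value = c(8, 10, 12, 15, 15, 15)))
#' @export
percentOfControl <- function(table, controlGroup = "control") {
    if (!all(c("group", "value") %in% colnames(table)))
        stop("table needs columns group, value")
    if (!controlGroup %in% table$group)
        stop("control group '", controlGroup, "' not present")
    ctrlMean <- mean(table$value[table$group == controlGroup])
    if (!is.finite(ctrlMean) || ctrlMean <= 0)
        stop("control mean must be > 0")
    table$percent_of_control <- table$value / ctrlMean * 100
    table
}
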