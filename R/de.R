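## Minimal classic negative-binomial DE engine: median-of-ratios size
## factors, method-of-moments dispersion with shrinkage toward a common
## value, a conditional exact test on library-size-equalized pseudo-counts,
## and Benjamini-Hochberg adjustment.

.morFactors <- function(m) {
    if (any(colSums(m) == 0))
        stop("normalization error: a sample has no nonzero counts")
    lg <- log(m)
    geo_ok <- apply(is.finite(lg), 1L, all)
    if (!any(geo_ok))
        stop("normalization error: no gene has nonzero counts in all samples")
    logGeo <- rowMeans(lg[geo_ok, , drop = FALSE])
    f <- apply(exp(lg[geo_ok, , drop = FALSE] - logGeo), 2L, median)
    f / exp(mean(log(f)))
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes of the ratio of its count to the
#' gene-wise geometric mean (computed over genes with all-positive counts),
#' rescaled so the geometric mean of the factors is 1.
#'
#' @param object a [DECountSet-class].
#' @param ... unused.
#' @return named numeric vector of positive per-sample factors.
#' @examples
#' m <- matrix(c(10L, 40L), 1, dimnames = list("g1", c("a", "b")))
#' sizeFactors(DECountSet(m, c("control", "treated")))  # 0.5, 2
#' @export
setMethod("sizeFactors", "DECountSet", function(object, ...) {
    .morFactors(counts(object))
})

.normCounts <- function(se, factors) {
    sweep(counts(se), 2L, factors, "/")
}

#' Method-of-moments NB dispersion with shrinkage
#'
#' Per gene, the normalized counts are pooled across groups after removing
#' the group-mean difference; with pooled residual variance \eqn{s^2}
#' (denominator n - 2) and grand mean \eqn{\mu}, the raw estimate is
#' \eqn{\max(0, (s^2 - \mu)/\mu^2)}. The common dispersion is a trimmed
#' mean of the raw estimates, and the returned per-gene ("tagwise")
#' dispersion shrinks the raw estimate toward the common value.
#'
#' @param se a [DECountSet-class] with at least 2 replicates per group.
#' @param factors size factors (default [sizeFactors()]).
#' @param shrink weight on the common dispersion in the tagwise estimate
#'   (default 0.7).
#' @param trim trim fraction for the common-dispersion trimmed mean.
#' @return list with `common` (scalar), `tagwise` and `raw` (per-gene
#'   vectors).
#' @export
estimateDispersion <- function(se, factors = sizeFactors(se),
                               shrink = 0.7, trim = 0.1) {
    g <- sampleGroups(se)
    if (any(table(g) < 2L))
        stop("dispersion estimation needs >= 2 replicates in each group")
    z <- .normCounts(se, factors)
    iA <- g == "control"; iB <- g == "treated"
    mA <- rowMeans(z[, iA, drop = FALSE])
    mB <- rowMeans(z[, iB, drop = FALSE])
    rss <- rowSums((z[, iA, drop = FALSE] - mA)^2) +
           rowSums((z[, iB, drop = FALSE] - mB)^2)
    s2 <- rss / (ncol(z) - 2L)
    mu <- rowMeans(z)
    raw <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
    common <- mean(raw, trim = trim)
    list(common = common,
         tagwise = setNames((1 - shrink) * raw + shrink * common,
                            rownames(se)),
         raw = setNames(raw, rownames(se)))
}

## Conditional exact test for one gene: pseudo-count group sums sA, sB with
## nA, nB replicates and dispersion phi. Under the equal-mean null the group
## sums are NB with sizes nA/phi, nB/phi; conditioning on the total T makes
## the success probability cancel, leaving
##   P(y) propto  G(y + rB)/y!  *  G(T - y + rA)/(T - y)!
## Two-sided p doubles the smaller tail (observed split included), capped
## at 1. phi = 0 reduces to Binomial(T, nB/(nA+nB)).
.exactTestOne <- function(sA, sB, nA, nB, phi) {
    tot <- sA + sB
    if (tot == 0) return(1)
    if (phi <= 0) {
        pr <- nB / (nA + nB)
        lower <- pbinom(sB, tot, pr)
        upper <- pbinom(sB - 1, tot, pr, lower.tail = FALSE)
        return(min(1, 2 * min(lower, upper)))
    }
    rA <- nA / phi; rB <- nB / phi
    y <- 0:tot
    lw <- lgamma(y + rB) - lgamma(y + 1) + lgamma(tot - y + rA) -
          lgamma(tot - y + 1)
    w <- exp(lw - max(lw))
    w <- w / sum(w)
    lower <- sum(w[y <= sB])
    upper <- sum(w[y >= sB])
    min(1, 2 * min(lower, upper))
}

#' Conditional NB exact test for two-group count data
#'
#' Counts are rescaled to a common effective library size (divided by the
#' size factor, whose geometric mean is 1) and rounded to the nearest
#' integer; for each gene the two-sided exact p-value of the split of the
#' conditioned total between the groups is computed under an equal-mean NB
#' model with the supplied dispersion.
#'
#' @param se a [DECountSet-class].
#' @param factors size factors (default [sizeFactors()]).
#' @param dispersion scalar or per-gene NB dispersion(s), >= 0.
#' @return named vector of p-values in (0, 1].
#' @export
nbExactTest <- function(se, factors = sizeFactors(se), dispersion) {
    if (any(dispersion < 0))
        stop("dispersion must be nonnegative")
    pseudo <- round(.normCounts(se, factors))
    g <- sampleGroups(se)
    nA <- sum(g == "control"); nB <- sum(g == "treated")
    sA <- rowSums(pseudo[, g == "control", drop = FALSE])
    sB <- rowSums(pseudo[, g == "treated", drop = FALSE])
    phi <- rep_len(dispersion, nrow(se))
    setNames(vapply(seq_len(nrow(se)), function(i)
        .exactTestOne(sA[i], sB[i], nA, nB, phi[i]), numeric(1)),
        rownames(se))
}

#' Per-gene log2 fold change with a prior count
#'
#' `log2((mean normalized treated + prior) / (mean normalized control +
#' prior))`. Genes where both group means and the prior are all zero are
#' undefined; they are returned as 0 and flagged in the `"undefined"`
#' attribute.
#'
#' @param se a [DECountSet-class].
#' @param factors size factors (default [sizeFactors()]).
#' @param priorCount nonnegative stabilizing prior (default 0.5).
#' @return named numeric vector of log2 fold changes (treated vs control),
#'   with a logical `"undefined"` attribute.
#' @export
estimateLogFC <- function(se, factors = sizeFactors(se), priorCount = 0.5) {
    if (priorCount < 0) stop("priorCount must be >= 0")
    z <- .normCounts(se, factors)
    g <- sampleGroups(se)
    mA <- rowMeans(z[, g == "control", drop = FALSE])
    mB <- rowMeans(z[, g == "treated", drop = FALSE])
    undef <- (mA + priorCount == 0) & (mB + priorCount == 0)
    lfc <- log2((mB + priorCount) / (mA + priorCount))
    lfc[undef] <- 0
    structure(setNames(lfc, rownames(se)), undefined = undef)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment (via [stats::p.adjust()]) with input validation;
#' input order is preserved and adjusted values are capped at 1.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhAdjust <- function(pvalues) {
    if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(pvalues, method = "BH")
}

#' Run the two-group differential-expression engine
#'
#' Size factors, dispersion estimation, the conditional exact test and BH
#' adjustment in one call.
#'
#' @param se a [DECountSet-class].
#' @param priorCount prior count for the fold-change estimate (default 0.5).
#' @param shrink dispersion shrinkage weight, see [estimateDispersion()].
#' @return data.frame (`gene_id`, `logfc`, `pvalue`, `fdr`,
#'   `mean_norm_count`), one row per gene in input order.
#' @examples
#' se <- simulateCounts(simCountsConfig(n_genes = 100, seed = 3))
#' head(runDE(se))
#' @export
runDE <- function(se, priorCount = 0.5, shrink = 0.7) {
    f <- sizeFactors(se)
    disp <- estimateDispersion(se, f, shrink = shrink)
    p <- nbExactTest(se, f, disp$tagwise)
    lfc <- estimateLogFC(se, f, priorCount)
    data.frame(gene_id = rownames(se),
               logfc = as.numeric(lfc),
               pvalue = as.numeric(p),
               fdr = bhAdjust(as.numeric(p)),
               mean_norm_count = rowMeans(.normCounts(se, f)),
               row.names = NULL)
}
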