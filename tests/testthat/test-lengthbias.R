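test_that("trend fit matches closed-form OLS and rank correlations", {
    meta <- function(tl) data.frame(gene_id = paste0("g", seq_along(tl)),
                                    transcript_length_bp = tl)
    de <- function(y) data.frame(gene_id = paste0("g", seq_along(y)),
                                 logfc = y)
    # constant response
    expect_warning(m0 <- fitCorrection(de(rep(0.7, 5)), meta(2^(1:5))),
                   "constant")
    expect_equal(correctionSlope(m0), 0)
    expect_equal(correctionIntercept(m0), 0.7)
    expect_equal(spearmanRho(m0), 0)
    # exact linear, monotone decreasing
    x <- 9:13
    m1 <- fitCorrection(de(-0.1 * x + 1), meta(2^x))
    expect_equal(correctionSlope(m1), -0.1)
    expect_equal(correctionIntercept(m1), 1)
    expect_equal(spearmanRho(m1), -1)
    # (1,1), (2,2), (3,2): slope 1/2, intercept 2/3
    m2 <- fitCorrection(de(c(1, 2, 2)), meta(2^(1:3)))
    expect_equal(correctionSlope(m2), 0.5)
    expect_equal(correctionIntercept(m2), 2 / 3)
    # rank formula: x 1..5, y (2,1,4,3,5) -> rho 0.8
    m3 <- fitCorrection(de(c(2, 1, 4, 3, 5)), meta(2^(1:5)))
    expect_equal(spearmanRho(m3), 0.8)
    # degenerate cases
    expect_error(fitCorrection(de(1:3), meta(rep(1024, 3))), "degenerate")
    expect_error(fitCorrection(de(1:2), meta(2^(1:2))), "fewer than 3")
})

test_that("reconciliation keeps the smaller-magnitude estimate or zeroes on sign flips", {
    expect_equal(reconcileLogFC(0.8, 0.3), 0.3)
    expect_equal(reconcileLogFC(0.8, -0.2), 0)
    expect_equal(reconcileLogFC(-0.5, -0.9), -0.5)
    expect_equal(reconcileLogFC(0, 0), 0)
    expect_equal(reconcileLogFC(0, 0.4), 0)   # one-sided zero: disagreement
    expect_equal(reconcileLogFC(0.4, 0), 0)
    expect_error(reconcileLogFC(NA, 1), "finite")
    withr::with_seed(8, {
        a <- runif(500, -2, 2); b <- runif(500, -2, 2)
        got <- reconcileLogFC(a, b)
        ref <- mapply(function(x, y) {
            if (x * y <= 0) 0 else if (abs(x) <= abs(y)) x else y
        }, a, b)
        expect_equal(got, ref)
        expect_true(all(abs(got) <= pmin(abs(a), abs(b)) + 1e-15))
    })
})

test_that("correction preserves significance gating and handles missing lengths", {
    de <- data.frame(gene_id = paste0("g", 1:6),
                     logfc = c(1.5, 0.05, -0.8, 1.5, 0.3, 0.2),
                     pvalue = 0.001,
                     fdr = c(0.2, 0.01, 0.01, 0.01, 0.01, 0.01))
    meta <- data.frame(gene_id = paste0("g", 1:5),   # g6 has no length
                       transcript_length_bp = c(2^10, 2^11, 2^12, 2^13, 2^9))
    res <- correctTable(de, meta)
    tab <- res$table
    expect_s4_class(res$model, "CorrectionModel")
    expect_equal(as.character(tab$call[1]), "not_significant")  # FDR gate
    expect_true(tab$length_missing[6])
    expect_equal(tab$final_logfc[6], tab$initial_logfc[6])
    expect_true(all(abs(tab$final_logfc) <= abs(tab$initial_logfc) + 1e-12))
    expect_error(correctTable(de, meta, fdrThreshold = 0), "\\(0, 1\\]")
    expect_error(correctTable(de, meta, logfcThreshold = -1), "> 0")
})

test_that("ten-gene toy table reproduces the hand-worked correction chain", {
    x <- seq(9, 13, length.out = 10)            # LogTL
    resid <- c(0.3, -0.2, 0.15, 0.4, -0.5, 0.05, -0.05, 0.25, -0.3, 0.1)
    y <- 0.5 - 0.2 * x + resid                  # initial LogFC
    de <- data.frame(gene_id = paste0("g", 1:10), logfc = y, fdr = 0.01)
    meta <- data.frame(gene_id = paste0("g", 1:10),
                       transcript_length_bp = 2^x)
    res <- correctTable(de, meta, fdrThreshold = 0.05, logfcThreshold = 0.1)
    # independent chain: R's lm() as the regression oracle
    fit <- lm(y ~ x)
    corr <- unname(residuals(fit))
    fin <- ifelse(y * corr <= 0, 0, ifelse(abs(y) <= abs(corr), y, corr))
    call <- ifelse(fin >= 0.1, "up", ifelse(fin <= -0.1, "down",
                                            "not_significant"))
    expect_equal(res$table$corrected_logfc, corr, tolerance = 1e-12)
    expect_equal(res$table$final_logfc, fin, tolerance = 1e-12)
    expect_equal(as.character(res$table$call), call)
})

test_that("corrected fold changes are orthogonal to transcript length", {
    withr::with_seed(31, {
        for (i in 1:5) {
            n <- 200
            x <- runif(n, 9, 14)
            de <- data.frame(gene_id = paste0("g", 1:n),
                             logfc = 0.3 - 0.07 * x + rnorm(n, 0, 0.4),
                             fdr = runif(n))
            meta <- data.frame(gene_id = paste0("g", 1:n),
                               transcript_length_bp = 2^x)
            tab <- correctTable(de, meta)$table
            m <- fitCorrection(data.frame(gene_id = meta$gene_id,
                                          logfc = tab$corrected_logfc), meta)
            expect_lt(abs(correctionSlope(m)), 1e-10)
            expect_lt(abs(pearsonR(m)), 1e-10)
        }
    })
})

test_that("injected artifact slopes are recovered and removed", {
    se <- simulateCounts(simCountsConfig(
        n_genes = 5000, dispersion = 0.05, artifact_slope = -0.15,
        frac_up = 0, frac_down = 0, seed = 55))
    de <- runDE(se)
    m <- fitCorrection(de, se)
    expect_lt(abs(correctionSlope(m) - (-0.15)), 0.02)
    # de-biasing at the study's observed correlation, no true DE
    se2 <- simulateCounts(simCountsConfig(
        n_genes = 10000, frac_up = 0, frac_down = 0,
        target_spearman = -0.42, seed = 56))
    de2 <- runDE(se2)
    res <- correctTable(de2, se2)
    rho <- cor(res$table$corrected_logfc, log2(geneLengths(se2)),
               method = "spearman")
    expect_lt(abs(S4Vectors::metadata(se2)$realized_spearman - (-0.42)), 0.05)
    expect_lt(abs(rho), 0.05)
})
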