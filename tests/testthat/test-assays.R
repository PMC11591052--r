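qpcrTable <- function(ct_target_ctrl, ct_target_trt,
                      ct_ref_ctrl = 15, ct_ref_trt = 15, gene = "Hk2") {
    nC <- length(ct_target_ctrl); nT <- length(ct_target_trt)
    smp <- c(paste0("c", seq_len(nC)), paste0("t", seq_len(nT)))
    grp <- rep(c("control", "treated"), c(nC, nT))
    rbind(data.frame(sample = smp, group = grp, gene = gene,
                     ct = c(ct_target_ctrl, ct_target_trt)),
          data.frame(sample = smp, group = grp, gene = "Actb",
                     ct = c(rep_len(ct_ref_ctrl, nC), rep_len(ct_ref_trt, nT))))
}

test_that("ddCt relative expression matches the Livak arithmetic", {
    # single control: ddCt = (20-15) - (21-15) = -1 -> 2.0
    r <- ddctExpression(qpcrTable(21, 20), "Actb")
    expect_equal(r$rel_expr[r$group == "treated"], 2.0)
    expect_equal(r$rel_expr[r$group == "control"], 1.0)  # self-reference
    # control dCt (5, 6), treated dCt 4 -> ddCt = -1.5 -> 2^1.5
    r2 <- ddctExpression(qpcrTable(c(20, 21), 19), "Actb")
    expect_equal(r2$rel_expr[r2$group == "treated"], 2^1.5)
    # shifting every Ct by a constant leaves relative expression unchanged
    t1 <- qpcrTable(c(20, 21, 20.5), c(19, 18.5, 19.2))
    t2 <- t1; t2$ct <- t2$ct + 3.7
    expect_equal(ddctExpression(t1, "Actb")$rel_expr,
                 ddctExpression(t2, "Actb")$rel_expr)
    # technical replicates are averaged per sample first
    t3 <- rbind(t1, t1[t1$gene == "Hk2", ])
    expect_equal(ddctExpression(t3, "Actb")$rel_expr,
                 ddctExpression(t1, "Actb")$rel_expr)
    # missing reference names the sample
    t4 <- t1[!(t1$sample == "t1" & t1$gene == "Actb"), ]
    expect_error(ddctExpression(t4, "Actb"), "t1")
    expect_warning(ddctExpression(qpcrTable(45, 20), "Actb"), "5-40")
})

test_that("densitometry normalization rescales to control mean 1", {
    grp <- rep(c("control", "treated"), each = 3)
    # bands proportional to loading -> all ratios 1
    r <- densitometryNormalize(c(2, 4, 6, 3, 5, 7) * 1.5,
                               c(2, 4, 6, 3, 5, 7), grp)
    expect_equal(r$values$ratio, rep(1, 6))
    # control ratios 1, treated 1.5/1.6/1.4 -> mean 1.5, SEM 0.1/sqrt(3)
    r2 <- densitometryNormalize(c(1, 1, 1, 1.5, 1.6, 1.4), rep(1, 6), grp)
    s <- r2$summary[r2$summary$group == "treated", ]
    expect_equal(s$mean, 1.5)
    expect_equal(s$sem, 0.1 / sqrt(3))
    # invariant to rescaling the loading channel
    r3 <- densitometryNormalize(c(1, 1, 1, 1.5, 1.6, 1.4), rep(2, 6), grp)
    expect_equal(r3$values$ratio, r2$values$ratio)
    expect_error(densitometryNormalize(1:6, c(1, 1, 0, 1, 1, 1), grp),
                 "positive")
})

test_that("percent of control centres the control group at 100", {
    tab <- data.frame(group = rep(c("control", "treated"), each = 3),
                      value = c(10, 10, 10, 15, 15, 15))
    p <- percentOfControl(tab)
    expect_equal(p$percent_of_control[p$group == "treated"], rep(150, 3))
    tab2 <- data.frame(group = rep(c("control", "treated"), c(3, 1)),
                       value = c(8, 10, 12, 15))
    p2 <- percentOfControl(tab2)
    expect_equal(p2$percent_of_control[p2$group == "treated"], 150)
    expect_equal(mean(p2$percent_of_control[p2$group == "control"]), 100)
    expect_error(percentOfControl(transform(tab, value = -value)), "> 0")
})

test_that("two-group test arithmetic and N-based selection follow the design", {
    a <- c(1, 2, 3); b <- c(4, 5, 6)
    r <- twoGroupTest(a, b)
    expect_identical(r$test_name, "student_t")
    expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
    expect_equal(r$pvalue, 2 * pt(-3 / sqrt(2 / 3), df = 4),
                 tolerance = 1e-12)
    expect_equal(r$pvalue, 0.0214, tolerance = 1e-2)
    expect_identical(r$significance_label, "*")
    # identical samples
    same <- twoGroupTest(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$statistic, 0)
    expect_equal(same$pvalue, 1)
    expect_identical(same$significance_label, "ns")
    # auto selection: n = 5 -> Mann-Whitney; n = 4 -> t with a message
    expect_identical(twoGroupTest(1:5, 6:10)$test_name, "mann_whitney")
    expect_equal(twoGroupTest(1:5, 6:10, "mann_whitney")$pvalue, 2 / 252)
    expect_identical(twoGroupTest(1:5, 6:10, "mann_whitney")$significance_label,
                     "**")
    expect_message(r4 <- twoGroupTest(1:4, 5:8), "min\\(n\\) = 4")
    expect_identical(r4$test_name, "student_t")
    # degenerate pooled variance conventions
    expect_message(z1 <- twoGroupTest(c(2, 2), c(2, 2)), "convention")
    expect_equal(z1$pvalue, 1)
    expect_message(z2 <- twoGroupTest(c(2, 2), c(3, 3)), "convention")
    expect_equal(z2$pvalue, 0)
})

test_that("two-group test is symmetric in its arguments", {
    withr::with_seed(23, {
        for (i in 1:8) {
            a <- rnorm(3); b <- rnorm(3, 1)
            ra <- twoGroupTest(a, b, "student_t")
            rb <- twoGroupTest(b, a, "student_t")
            expect_equal(ra$statistic, -rb$statistic)
            expect_equal(ra$pvalue, rb$pvalue)
            x <- rnorm(5); y <- rnorm(5, 1)
            expect_equal(twoGroupTest(x, y, "mann_whitney")$pvalue,
                         twoGroupTest(y, x, "mann_whitney")$pvalue)
        }
    })
})

test_that("significance labels follow the strict p-value cutoffs", {
    expect_identical(significanceLabel(c(0.2, 0.049, 0.009, 0.0009)),
                     c("ns", "*", "**", "***"))
    expect_identical(significanceLabel(c(0.05, 0.01, 0.001)),
                     c("ns", "*", "**"))
})
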