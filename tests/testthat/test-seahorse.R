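fixturePath <- system.file("extdata", "synthetic_seahorse_traces.csv",
                           package = "ecdymet")

test_that("trace CSV round-trips bit-identically and validates structure", {
    ts <- readSeahorseTraces(fixturePath)
    out <- file.path(withr::local_tempdir(), "rt.csv")
    writeSeahorseTraces(ts, out)
    expect_identical(readLines(out), readLines(fixturePath))
    # dropping one well's post_rotaa rows errors naming the well
    tr <- traces(ts)
    bad <- tr[!(tr$well == "B1" & tr$phase == "post_rotaa"), ]
    badPath <- file.path(withr::local_tempdir(), "bad.csv")
    write.csv(bad, badPath, row.names = FALSE, quote = FALSE)
    expect_error(readSeahorseTraces(badPath), "B1")
    # non-monotone time errors
    tr2 <- tr
    tr2$time_min[2] <- tr2$time_min[1]
    expect_error(SeahorseTraceSet(tr2), "strictly increasing")
})

test_that("simulator output parses with zero warnings", {
    path <- file.path(withr::local_tempdir(), "sim.csv")
    writeSeahorseTraces(simulateSeahorse(simSeahorseConfig(seed = 3)), path)
    expect_no_warning(ts <- readSeahorseTraces(path))
    expect_length(wells(ts), 10)
})

test_that("phase statistics are last-basal and min-post-injection", {
    ts <- makeTraces()
    r <- phaseRates(ts)
    expect_equal(r$ocr_basal, 100)   # last, not mean
    expect_equal(r$ocr_oligo, 40)    # minimum
    expect_equal(r$ocr_rotaa, 10)
    expect_equal(r$ecar_basal, 50)
    rm <- phaseRates(ts, stat = "mean")
    expect_equal(rm$ocr_basal, mean(c(95, 98, 100)))
    # zero-noise simulated wells give the configured values exactly
    ts0 <- simulateSeahorse(simSeahorseConfig(
        groups = data.frame(name = "control", ocr_multiplier = 1,
                            ecar_multiplier = 1), noise_cv = 0))
    r0 <- phaseRates(ts0)
    expect_true(all(r0$ocr_basal == 100 & r0$ocr_oligo == 40 &
                    r0$ocr_rotaa == 10))
})

test_that("ATP decomposition follows the stated arithmetic", {
    r <- data.frame(well = "A1", group = "control", ocr_basal = 100,
                    ocr_oligo = 40, ocr_rotaa = 10, ecar_basal = 60)
    a <- atpRates(r)
    expect_equal(a$mito_atp, (100 - 40) * 2 * 2.75)  # 330
    expect_equal(a$glyco_atp, 60 - (100 - 10) * 0.61)
    expect_equal(a$total_atp, a$mito_atp + a$glyco_atp)
    # mitoPER = 0 limit: basal == rotaa, unit ECAR conversion, ECAR 50
    r2 <- transform(r, ocr_rotaa = 100, ecar_basal = 50)
    expect_equal(atpRates(r2)$glyco_atp, 50)
    # oligomycin-insensitive limit
    r3 <- transform(r, ocr_oligo = 100)
    expect_equal(atpRates(r3)$mito_atp, 0)
    # clamping logs a warning
    r4 <- transform(r, ocr_oligo = 120)
    expect_warning(a4 <- atpRates(r4), "A1")
    expect_equal(a4$mito_atp, 0)
    expect_error(atpRates(r, atpConstants(poRatio = -1)), "positive")
})

test_that("ATP rates are additive and scale-equivariant", {
    ts <- simulateSeahorse(simSeahorseConfig(seed = 14))
    a1 <- atpRates(phaseRates(ts))
    expect_equal(a1$total_atp, a1$mito_atp + a1$glyco_atp)
    tr <- traces(ts)
    tr$ocr_pmol_per_min <- 3 * tr$ocr_pmol_per_min
    tr$ecar_mpH_per_min <- 3 * tr$ecar_mpH_per_min
    a3 <- atpRates(phaseRates(SeahorseTraceSet(tr)))
    expect_equal(a3$mito_atp, 3 * a1$mito_atp)
    expect_equal(a3$glyco_atp, 3 * a1$glyco_atp)
    expect_equal(a3$total_atp, 3 * a1$total_atp)
})

test_that("group summaries: symmetry, separation, zero-noise fold", {
    base <- data.frame(well = paste0("A", 1:5), group = "control",
                       ocr_basal = c(100, 101, 99, 100, 100),
                       ocr_oligo = 40, ocr_rotaa = 10, ecar_basal = 150)
    same <- transform(base, group = "treated", well = paste0("B", 1:5))
    s <- summarizeAtpByGroup(atpRates(rbind(base, same)))
    trt <- s[s$group == "treated", ]
    expect_equal(trt$fold_vs_control, rep(1, 3))
    expect_equal(trt$pvalue, rep(1, 3))
    # fully separated 5v5: exact two-sided p = 2/252
    sep <- transform(base, group = "treated", well = paste0("B", 1:5),
                     ocr_basal = c(200, 201, 199, 200, 202))
    s2 <- summarizeAtpByGroup(atpRates(rbind(base, sep)))
    expect_equal(s2$pvalue[s2$group == "treated" & s2$measure == "mito_atp"],
                 2 / 252)
    # zero-noise simulation with OCR multiplier 1.5 -> exact mito fold 1.5
    ts <- simulateSeahorse(simSeahorseConfig(noise_cv = 0))
    s3 <- summarizeAtpByGroup(atpRates(phaseRates(ts)))
    expect_equal(s3$fold_vs_control[s3$group == "treated" &
                                    s3$measure == "mito_atp"], 1.5)
    expect_error(summarizeAtpByGroup(atpRates(base), "DMSO"), "unknown")
})

test_that("treatment effects on mito ATP are detected across seeds", {
    hits <- folds <- numeric(50)
    for (s in 1:50) {
        ts <- simulateSeahorse(simSeahorseConfig(noise_cv = 0.05,
                                                 seed = 700 + s))
        sm <- summarizeAtpByGroup(atpRates(phaseRates(ts)))
        row <- sm[sm$group == "treated" & sm$measure == "mito_atp", ]
        folds[s] <- row$fold_vs_control
        hits[s] <- row$pvalue < 0.05
    }
    expect_lt(abs(mean(folds) - 1.5), 0.1)
    expect_gte(mean(hits), 0.9)
})

test_that("exact Mann-Whitney agrees with wilcox.test and tied enumeration", {
    withr::with_seed(19, {
        for (i in 1:25) {
            n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
            a <- rnorm(n1); b <- rnorm(n2, 0.8)
            got <- mannWhitneyTest(a, b)
            ref <- wilcox.test(a, b, exact = TRUE)
            expect_equal(got$statistic, unname(ref$statistic))
            expect_equal(got$pvalue, ref$p.value, tolerance = 1e-12)
        }
        for (i in 1:10) {   # ties: compare with the enumeration oracle
            a <- sample(1:4, 5, replace = TRUE)
            b <- sample(2:6, 5, replace = TRUE)
            expect_equal(mannWhitneyTest(a, b)$pvalue, mwOracle(a, b))
        }
    })
    big <- mannWhitneyTest(rnorm(12), rnorm(15))
    expect_identical(big$method, "normal")
    expect_true(big$pvalue > 0 && big$pvalue <= 1)
})
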