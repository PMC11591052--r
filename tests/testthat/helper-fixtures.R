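# Small in-code fixtures and independent oracles shared across test files.

# tiny two-group count set from an explicit matrix
makeCounts <- function(m, nctrl = ncol(m) / 2) {
    if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
    DECountSet(m, rep(c("control", "treated"),
                      c(nctrl, ncol(m) - nctrl)))
}

# Independent brute-force oracle for the conditional NB exact test: the
# conditional pmf of the treated group sum given the total, via dnbinom
# products at an arbitrary fixed mean (the success probability cancels only
# in the normalized ratio, which is exactly what we normalize here).
exactTestOracle <- function(sA, sB, nA, nB, phi) {
    tot <- sA + sB
    if (tot == 0) return(1)
    y <- 0:tot
    if (phi <= 0) {
        w <- dbinom(y, tot, nB / (nA + nB))
    } else {
        mu <- 7.3  # arbitrary; cancels after normalization
        w <- dnbinom(y, size = nB / phi, mu = nB * mu) *
             dnbinom(tot - y, size = nA / phi, mu = nA * mu)
        w <- w / sum(w)
    }
    lower <- sum(w[y <= sB])
    upper <- sum(w[y >= sB])
    min(1, 2 * min(lower, upper))
}

# Independent Mann-Whitney enumeration oracle on mid-ranks
mwOracle <- function(a, b) {
    n1 <- length(a); n <- n1 + length(b)
    r <- rank(c(a, b))
    uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    us <- apply(combn(n, n1), 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
    min(1, 2 * min(mean(us <= uObs + 1e-9), mean(us >= uObs - 1e-9)))
}

# hand-rolled traces for phase-statistic tests
makeTraces <- function(ocr = list(basal = c(95, 98, 100),
                                  post_oligomycin = c(45, 40, 42),
                                  post_rotaa = c(12, 10, 11)),
                       ecar = 50, well = "A1", group = "control") {
    ph <- rep(names(ocr), lengths(ocr))
    SeahorseTraceSet(data.frame(
        well = well, group = group, phase = ph,
        time_min = seq_along(ph) * 6.5,
        ocr_pmol_per_min = unlist(ocr, use.names = FALSE),
        ecar_mpH_per_min = ecar))
}
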