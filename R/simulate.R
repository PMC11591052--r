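## Seeded synthetic-data generators. Every generator is bit-identical under a
## fixed seed; seeds are applied with withr::with_seed so the caller's RNG
## state is untouched.

#' Configuration for the bulk RNA-seq count simulator
#'
#' Defines a two-group negative-binomial experiment with a minority of true
#' DE genes (more up- than down-regulated by default) and an optional
#' length-coupled artifactual trend in the observed log2 fold changes,
#' specified either directly as a slope (log2FC per log2 bp) or as a target
#' Spearman correlation between estimated LogFC and log2 transcript length
#' to which the slope is calibrated.
#'
#' @param n_genes number of genes.
#' @param n_replicates_per_group biological replicates per group (default 6).
#' @param frac_up,frac_down fractions of truly up-/down-regulated genes;
#'   their sum must be at most 1. Defaults 0.06 and 0.045 keep the
#'   up/down imbalance characteristic of an anabolic stimulus.
#' @param effect_logfc_scale scale of true effects (log2 units): each DE gene
#'   gets |LogFC| = `effect_logfc_scale` x Uniform(0.5, 1.5).
#' @param baseline_mean_log_range log10 range of baseline mean counts
#'   (default `c(1, 3.5)`, i.e. expressed genes with means 10-3162).
#' @param dispersion NB dispersion phi (variance mu + phi mu^2); 0 gives
#'   Poisson counts.
#' @param length_log2_range log2 range of transcript lengths in bp
#'   (default `c(9, 14)`, i.e. 512 bp to 16 kb, log2-uniform).
#' @param artifact_slope length-artifact slope in log2FC per log2 bp.
#'   Exactly one of `artifact_slope` / `target_spearman` may be given;
#'   if neither is, `artifact_slope = 0`.
#' @param target_spearman target Spearman correlation (in \[-1, 1\]) between
#'   the sample-estimated LogFC and log2 transcript length; the slope is
#'   calibrated to approach it as `n_genes` grows.
#' @param seed integer RNG seed.
#' @return A validated `SimCountsConfig` (list).
#' @seealso [simulateCounts()]
#' @export
simCountsConfig <- function(n_genes = 10000L,
                            n_replicates_per_group = 6L,
                            frac_up = 0.06, frac_down = 0.045,
                            effect_logfc_scale = 1.0,
                            baseline_mean_log_range = c(1, 3.5),
                            dispersion = 0.05,
                            length_log2_range = c(9, 14),
                            artifact_slope = NULL,
                            target_spearman = NULL,
                            seed = 1L) {
    if (!is.null(artifact_slope) && !is.null(target_spearman))
        stop("configuration error: give only one of artifact_slope / target_spearman")
    if (is.null(artifact_slope) && is.null(target_spearman))
        artifact_slope <- 0
    if (n_genes < 1 || n_replicates_per_group < 2)
        stop("configuration error: need n_genes >= 1 and >= 2 replicates per group")
    if (frac_up < 0 || frac_down < 0 || frac_up + frac_down > 1)
        stop("configuration error: frac_up, frac_down must be >= 0 with sum <= 1")
    if (effect_logfc_scale <= 0 || dispersion < 0)
        stop("configuration error: effect_logfc_scale > 0 and dispersion >= 0 required")
    if (diff(baseline_mean_log_range) < 0 || diff(length_log2_range) < 0)
        stop("configuration error: ranges must be ordered low <= high")
    if (!is.null(target_spearman)) {
        if (abs(target_spearman) > 1)
            stop("configuration error: target_spearman must lie in [-1, 1]")
        if (n_genes < 10)
            stop("calibration error: target_spearman needs n_genes >= 10")
    }
    structure(list(n_genes = as.integer(n_genes),
                   n_replicates_per_group = as.integer(n_replicates_per_group),
                   frac_up = frac_up, frac_down = frac_down,
                   effect_logfc_scale = effect_logfc_scale,
                   baseline_mean_log_range = baseline_mean_log_range,
                   dispersion = dispersion,
                   length_log2_range = length_log2_range,
                   artifact_slope = artifact_slope,
                   target_spearman = target_spearman,
                   seed = as.integer(seed)),
              class = "SimCountsConfig")
}

## Calibrate the artifact slope so Spearman(estimated LogFC, LogTL) hits the
## target. Deterministic pilot with common random numbers: the per-gene LogFC
## estimator is approximated as true + artifact + z * sd(slope), with the
## delta-method sd of log2 of a ratio of NB replicate means, and a fixed
## standard-normal draw z per gene, so the objective is smooth in the slope
## and uniroot converges cleanly.
.calibrateArtifactSlope <- function(target, log2tl, mu0, true_logfc,
                                    dispersion, nrep) {
    z <- rnorm(length(mu0))
    xc <- log2tl - mean(log2tl)
    obj <- function(slope) {
        muT <- mu0 * 2^(true_logfc + slope * xc)
        sdl <- sqrt((1 / mu0 + dispersion) / nrep +
                    (1 / muT + dispersion) / nrep) / log(2)
        est <- true_logfc + slope * xc + z * sdl
        cor(est, log2tl, method = "spearman") - target
    }
    lo <- obj(-3); hi <- obj(3)
    if (lo > 0 || hi < 0)
        stop("calibration error: target_spearman unreachable for this design")
    uniroot(obj, c(-3, 3), tol = 1e-5)$root
}

.nbDraw <- function(n, mu, dispersion) {
    if (dispersion > 0) rnbinom(n, mu = mu, size = 1 / dispersion)
    else rpois(n, mu)
}

#' Simulate a two-group NB count matrix with a length-coupled artifact
#'
#' Draws transcript lengths log2-uniformly, baseline means log10-uniformly,
#' assigns a minority of genes a true log2 fold change (up before down), adds
#' a centred length-coupled artifact `slope * (LogTL - mean LogTL)` to every
#' gene's observed effect, and draws negative-binomial counts. When the
#' configuration specifies `target_spearman`, the slope is first calibrated
#' by a deterministic pilot (see the methods vignette). The realized Spearman
#' correlation of the sample-estimated LogFC with LogTL is computed from the
#' simulated counts and stored in the object metadata.
#'
#' @param config a [simCountsConfig()].
#' @return A [DECountSet-class] whose `rowData` carries
#'   `transcript_length_bp`, `true_logfc`, `is_de` and `artifact_component`,
#'   and whose `metadata` carries `artifact_slope`, `realized_spearman` and
#'   the config.
#' @examples
#' se <- simulateCounts(simCountsConfig(n_genes = 200, seed = 7))
#' se
#' @export
simulateCounts <- function(config) {
    stopifnot(inherits(config, "SimCountsConfig"))
    withr::with_seed(config$seed, {
        n <- config$n_genes
        nrep <- config$n_replicates_per_group
        log2tl <- runif(n, config$length_log2_range[1],
                        config$length_log2_range[2])
        tl <- pmax(1, round(2^log2tl))
        log2tl <- log2(tl)
        mu0 <- 10^runif(n, config$baseline_mean_log_range[1],
                        config$baseline_mean_log_range[2])
        n_up <- round(config$frac_up * n)
        n_down <- round(config$frac_down * n)
        true_logfc <- numeric(n)
        if (n_up + n_down > 0) {
            de_idx <- sample.int(n, n_up + n_down)
            mag <- config$effect_logfc_scale * runif(n_up + n_down, 0.5, 1.5)
            true_logfc[de_idx] <- rep(c(1, -1), c(n_up, n_down)) * mag
        }
        slope <- if (!is.null(config$target_spearman)) {
            .calibrateArtifactSlope(config$target_spearman, log2tl, mu0,
                                    true_logfc, config$dispersion, nrep)
        } else config$artifact_slope
        artifact <- slope * (log2tl - mean(log2tl))
        muT <- mu0 * 2^(true_logfc + artifact)
        cc <- matrix(.nbDraw(n * nrep, rep(mu0, nrep), config$dispersion),
                     nrow = n)
        ct <- matrix(.nbDraw(n * nrep, rep(muT, nrep), config$dispersion),
                     nrow = n)
        m <- cbind(cc, ct)
        dimnames(m) <- list(sprintf("gene%05d", seq_len(n)),
                            c(sprintf("ctrl_%d", seq_len(nrep)),
                              sprintf("trt_%d", seq_len(nrep))))
        se <- DECountSet(m, rep(.GROUPS, each = nrep), transcriptLength = tl)
        SummarizedExperiment::rowData(se)$true_logfc <- true_logfc
        SummarizedExperiment::rowData(se)$is_de <- true_logfc != 0
        SummarizedExperiment::rowData(se)$artifact_component <- artifact
        est <- tryCatch(
            estimateLogFC(se, priorCount = 0.5),
            error = function(e) NULL)
        rs <- if (is.null(est)) NA_real_
              else cor(est, log2tl, method = "spearman")
        S4Vectors::metadata(se) <- list(artifact_slope = slope,
                                        realized_spearman = rs,
                                        config = config)
        se
    })
}

#' Configuration for the three-phase extracellular-flux simulator
#'
#' @param groups data.frame with columns `name`, `ocr_multiplier`,
#'   `ecar_multiplier`; the default emulates a control and a treated group
#'   with 1.5x respiration and 1.6x glycolysis.
#' @param wells_per_group replicate wells per group (default 5).
#' @param measurements_per_phase measurements in each of the three phases.
#' @param basal_ocr_mean,basal_ecar_mean control-group basal means. OCR is in
#'   pmol O2/min; ECAR is in mpH/min but, under the default unit conversion of
#'   [atpConstants()], is read directly as a proton efflux rate, so its default
#'   (120) is set well above the CO2-derived acidification of the default OCR
#'   so that simulated wells have a nondegenerate glycolytic rate.
#' @param oligo_ocr_fraction,rotaa_ocr_fraction fractions of basal OCR
#'   remaining after oligomycin and after rotenone/antimycin A; must satisfy
#'   `rotaa < oligo < 1`.
#' @param noise_cv coefficient of variation of the multiplicative
#'   (mean-preserving lognormal) measurement noise.
#' @param seed integer RNG seed.
#' @return A validated `SimSeahorseConfig` (list).
#' @export
simSeahorseConfig <- function(groups = data.frame(
                                  name = c("control", "treated"),
                                  ocr_multiplier = c(1, 1.5),
                                  ecar_multiplier = c(1, 1.6)),
                              wells_per_group = 5L,
                              measurements_per_phase = 3L,
                              basal_ocr_mean = 100,
                              basal_ecar_mean = 120,
                              oligo_ocr_fraction = 0.4,
                              rotaa_ocr_fraction = 0.1,
                              noise_cv = 0.05,
                              seed = 1L) {
    groups <- as.data.frame(groups)
    if (!all(c("name", "ocr_multiplier", "ecar_multiplier") %in% colnames(groups)))
        stop("configuration error: groups needs name, ocr_multiplier, ecar_multiplier")
    if (!(rotaa_ocr_fraction < oligo_ocr_fraction && oligo_ocr_fraction < 1) ||
        rotaa_ocr_fraction < 0)
        stop("configuration error: need 0 <= rotaa_ocr_fraction < oligo_ocr_fraction < 1")
    if (basal_ocr_mean <= 0 || basal_ecar_mean <= 0)
        stop("configuration error: basal means must be positive")
    if (wells_per_group < 1 || measurements_per_phase < 1 || noise_cv < 0)
        stop("configuration error: wells, measurements >= 1 and noise_cv >= 0")
    structure(list(groups = groups,
                   wells_per_group = as.integer(wells_per_group),
                   measurements_per_phase = as.integer(measurements_per_phase),
                   basal_ocr_mean = basal_ocr_mean,
                   basal_ecar_mean = basal_ecar_mean,
                   oligo_ocr_fraction = oligo_ocr_fraction,
                   rotaa_ocr_fraction = rotaa_ocr_fraction,
                   noise_cv = noise_cv, seed = as.integer(seed)),
              class = "SimSeahorseConfig")
}

## mean-preserving lognormal multiplicative noise
.lnoise <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    s <- sqrt(log(1 + cv^2))
    exp(rnorm(n, -s^2 / 2, s))
}

#' Simulate three-phase OCR/ECAR plate traces
#'
#' Each well measures `measurements_per_phase` points in the basal phase,
#' then after oligomycin injection, then after the rotenone/antimycin-A mix,
#' on a 6.5-minute cadence. Phase OCR means are `basal`, `basal * oligo
#' fraction` and `basal * rotaa fraction`; ECAR stays at its basal mean
#' during the basal phase and rises to 1.3x after oligomycin (compensatory
#' glycolysis) in this simulator. Multiplicative lognormal noise with the
#' configured CV is applied per measurement and is mean-preserving, so the
#' zero-noise traces equal the configured means exactly.
#'
#' @param config a [simSeahorseConfig()].
#' @return A [SeahorseTraceSet-class].
#' @examples
#' ts <- simulateSeahorse(simSeahorseConfig(noise_cv = 0, seed = 1))
#' head(traces(ts))
#' @export
simulateSeahorse <- function(config) {
    stopifnot(inherits(config, "SimSeahorseConfig"))
    withr::with_seed(config$seed, {
        mpp <- config$measurements_per_phase
        npts <- 3L * mpp
        tt <- seq_len(npts) * 6.5
        phase <- rep(.PHASES, each = mpp)
        ocr_frac <- rep(c(1, config$oligo_ocr_fraction,
                          config$rotaa_ocr_fraction), each = mpp)
        ecar_frac <- rep(c(1, 1.3, 1.3), each = mpp)
        out <- vector("list", nrow(config$groups) * config$wells_per_group)
        k <- 0L
        for (gi in seq_len(nrow(config$groups))) {
            g <- config$groups[gi, ]
            for (wi in seq_len(config$wells_per_group)) {
                k <- k + 1L
                out[[k]] <- data.frame(
                    well = sprintf("%s%d", LETTERS[gi], wi),
                    group = g$name,
                    phase = phase,
                    time_min = tt,
                    ocr_pmol_per_min = config$basal_ocr_mean *
                        g$ocr_multiplier * ocr_frac *
                        .lnoise(npts, config$noise_cv),
                    ecar_mpH_per_min = config$basal_ecar_mean *
                        g$ecar_multiplier * ecar_frac *
                        .lnoise(npts, config$noise_cv))
            }
        }
        SeahorseTraceSet(do.call(rbind, out))
    })
}

#' Simulate a two-group bench-assay value table
#'
#' Lognormal (mean-preserving) multiplicative noise around the group means
#' `control_mean` and `control_mean * effect_multiplier`, mirroring the
#' triplicate plate-assay designs of the study.
#'
#' @param n_per_group replicates per group (>= 2).
#' @param control_mean control group mean (assay units, > 0).
#' @param effect_multiplier treated/control mean ratio (> 0).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer RNG seed.
#' @return data.frame with columns `sample`, `group`, `value`.
#' @examples
#' simulateAssays(3, 100, 1.5, 0.05, seed = 2)
#' @export
simulateAssays <- function(n_per_group, control_mean, effect_multiplier,
                           noise_cv, seed = 1L) {
    if (n_per_group < 2)
        stop("n_per_group must be >= 2 (two-group tests are undefined below that)")
    if (control_mean <= 0 || effect_multiplier <= 0 || noise_cv < 0)
        stop("control_mean, effect_multiplier must be > 0 and noise_cv >= 0")
    withr::with_seed(as.integer(seed), {
        means <- rep(c(control_mean, control_mean * effect_multiplier),
                     each = n_per_group)
        grp <- rep(.GROUPS, each = n_per_group)
        data.frame(
            sample = sprintf("%s_%d", grp, rep(seq_len(n_per_group), 2)),
            group = grp,
            value = means * .lnoise(2L * n_per_group, noise_cv))
    })
}
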