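---
title: "Methods: length-bias-corrected differential expression and ATP-rate decomposition"
author: "ecdymet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: length-bias-corrected differential expression and ATP-rate decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecdymet)
```

# Scope

`ecdymet` packages the computational core of a cell-culture study of
20-hydroxyecdysone (20E, ecdysterone), an arthropod steroid with anabolic
and adaptogenic pharmacology in mammals. Such studies combine bulk RNA-seq
of treated versus control myoblasts or fibroblasts with extracellular-flux
(Seahorse) energy profiling and bench assays (qPCR, immunoblot
densitometry, plate assays). The package implements four analysis layers —
a minimal negative-binomial differential-expression (DE) engine, a
transcript-length fold-change bias correction, the real-time ATP-rate
decomposition, and the bench-assay statistics — together with seeded
synthetic-data generators that reproduce the statistical structure each
layer assumes, so the whole pipeline is testable without any external
download. Upstream read processing (trimming, alignment, quantification)
and downstream enrichment analyses are out of scope: the pipeline starts
from a gene-level count matrix.

# The differential-expression engine

The engine is a deliberately minimal classic exact-test pipeline, not a
wrapper around an existing DE package, so that every step has a closed,
testable form.

**Normalization** uses median-of-ratios size factors: for sample $j$,
$f_j = \mathrm{median}_g \; c_{gj} / \left(\prod_k c_{gk}\right)^{1/m}$
over genes $g$ whose counts are positive in all $m$ samples, rescaled so
$\left(\prod_j f_j\right)^{1/m} = 1$. This replaces TMM with a simpler
estimator that has exact small fixtures (e.g. a single gene with counts
10 and 40 gives factors 0.5 and 2).

**Dispersion** follows the NB parameterization
$\mathrm{Var} = \mu + \phi \mu^2$. Per gene, normalized counts are pooled
across groups after removing the group-mean difference; with pooled
residual variance $s^2$ (denominator $n - 2$) and grand mean $\hat\mu$,
the method-of-moments estimate is
$\hat\phi = \max\{0, (s^2 - \hat\mu)/\hat\mu^2\}$. The common dispersion
is a 10%-trimmed mean of the per-gene estimates, and the tagwise value
shrinks each gene 70% of the way toward the common value. The weight 0.7
is a fixed moderation choice in the spirit of empirical-Bayes shrinkage:
with six replicates per group the per-gene estimate is noisy, and a
common-dominated mixture stabilizes the exact test without erasing
gene-level signal.

**Testing** is the conditional NB exact test. Counts are divided by their
size factor (a common effective library size, since the factors have
geometric mean 1) and rounded — a quantile-free simplification of
pseudo-count equalization. Under the equal-mean null the group sums are
NB with sizes $n_A/\phi$ and $n_B/\phi$; conditioning on the total $T$
cancels the mean, leaving
$P(y) \propto \frac{\Gamma(y + n_B/\phi)}{y!}\,
\frac{\Gamma(T - y + n_A/\phi)}{(T - y)!}$,
evaluated exactly over $y = 0, \dots, T$. The two-sided p-value doubles
the smaller tail (observed split included) and caps at 1; $\phi = 0$
reduces to an exact binomial test. The test suite checks equality with a
brute-force enumeration oracle to $10^{-12}$ for conditioned totals up
to 50, and null calibration (type-I error $0.05 \pm 0.01$ at
$\alpha = 0.05$) on simulated data.

**Fold change** is $\log_2\frac{\bar z_T + c}{\bar z_C + c}$ with prior
count $c = 0.5$ by default; FDR control is Benjamini–Hochberg (delegated
to `p.adjust`, with the hand-workable step-up examples asserted in tests).

# The transcript-length bias correction

A negative correlation between per-gene log2 fold change (LogFC) and log2
transcript length (LogTL) is a recognized artifact signature in comparisons
of bulk RNA-seq groups — classically produced by differential RNA
degradation and 3′-bias, though it can in principle reflect biology. The
correction implemented here is deliberately agnostic about the cause:

1. `fitCorrection()` regresses LogFC on LogTL by OLS (all genes with a
   finite LogFC and positive length by default; a subset can be supplied)
   and records the Spearman (average ranks on ties) and Pearson
   correlations.
2. `correctTable()` subtracts the fitted line:
   $\mathrm{LogFC}^{corr}_g = \mathrm{LogFC}_g - (a + b\,\mathrm{LogTL}_g)$.
3. `reconcileLogFC()` takes the final effect size as whichever of the
   initial and corrected values has the smaller magnitude, and sets it to
   zero when their signs differ. A zero on either side is treated as a
   sign disagreement (conservative), so the rule is: zero whenever
   `initial * corrected <= 0`, otherwise the min-abs value.
4. Genes are called `up`/`down` at FDR ≤ 0.05 and |final LogFC| ≥ 0.1
   (the LogFC threshold is applied to both directions). P-values are not
   recomputed: the correction adjusts effect sizes, while significance
   derives from the counts.

Because step 2 produces exact OLS residuals, the corrected LogFC is
orthogonal to LogTL by construction (slope and Pearson correlation zero to
machine precision), and the min-abs rule guarantees
$|\mathrm{final}| \le |\mathrm{initial}|$ — the corrected calls are a
shrunken, never inflated, version of the uncorrected ones.

Two genuinely open choices are fixed as follows: the trend is fitted on
*all* usable genes (the dependence being corrected is a global trend, and
fitting on significant genes only would couple the fit to the calls), and
a zero value on either side of the reconciliation counts as a sign flip
(the alternative — treating zero as sign-neutral and keeping the other
value — is anti-conservative). Genes with no usable length cannot be
corrected; they keep their initial LogFC and are flagged rather than
silently dropped.

# The synthetic count simulator

`simulateCounts()` emulates the study design: two groups of six biological
replicates, NB counts, a minority of true DE genes with more up- than
down-regulation, and an injectable length-coupled artifact.

Defaults (all overridable) and their rationale:

* `dispersion = 0.05` — biological CV ≈ 0.22, typical of immortalized
  cell-line replicates.
* `baseline_mean_log_range = c(1, 3.5)` (log10) — mean counts 10–3162,
  the expressed-gene range after the usual low-count prefiltering.
* `length_log2_range = c(9, 14)` — transcripts of 0.5–16 kb,
  log2-uniform; real length distributions are heavier in the middle, but
  a uniform spread in the regressor is the conservative choice for
  exercising a regression-based correction.
* `frac_up = 0.06`, `frac_down = 0.045` — a ~4:3 up/down imbalance at
  roughly transcriptome scale, reflecting an anabolic stimulus that
  preferentially induces expression.
* true effect magnitudes are `effect_logfc_scale` × Uniform(0.5, 1.5),
  bounded away from zero so that "true DE" is a meaningful recovery
  target at the study's |LogFC| ≥ 0.1 threshold.

The artifact is an additive, centred term on every gene's true effect:
$\delta_g = \beta\,(\mathrm{LogTL}_g - \overline{\mathrm{LogTL}})$,
leaving the global mean LogFC unchanged. $\beta$ can be given directly or
calibrated to a target Spearman correlation between the *estimated* LogFC
and LogTL. Calibration uses a deterministic pilot with common random
numbers: the LogFC estimator is approximated as
true + artifact + $z_g \cdot \mathrm{sd}_g(\beta)$, with $\mathrm{sd}_g$
the delta-method standard deviation of a log-ratio of NB replicate means
and $z_g$ a fixed standard-normal draw, making the objective smooth in
$\beta$ so `uniroot` converges cleanly; the realized correlation is then
measured on the actual simulated counts and stored in the object metadata.
At 10,000 genes the realized value is within ±0.02 of the target in
typical runs; tests assert ±0.05 against the study's observed −0.42.

What the simulator does *not* model: read-level effects (3′ coverage bias,
GC content, mapping ambiguity), correlated genes, library-size outliers,
and single-cell or UMI structure. Passing tests on this generator
therefore demonstrate that the correction removes a length-linear trend of
the kind it assumes — not that any real dataset's LogFC–LogTL dependence
is artifactual, which the underlying study itself leaves open.

# The ATP-rate decomposition

A real-time ATP-rate assay measures each well's oxygen consumption rate
(OCR, pmol O₂/min — respiration) and extracellular acidification rate
(ECAR, mpH/min — glycolysis) through three phases: basal, after
oligomycin (ATP-synthase inhibition), and after rotenone/antimycin A
(electron transport abolished). `phaseRates()` reduces each well to
last-basal OCR/ECAR and the minimum OCR within each post-injection phase
(the maximal inhibitor response; phase means are available via
`stat = "mean"`). `atpRates()` then computes, per well,

* `mito_atp = max(0, OCR_basal − OCR_oligo) × 2 × P/O`, with the P/O
  ratio defaulting to 2.75 pmol ATP per pmol atomic O;
* `PER = ECAR_basal × bufferFactor × chamberVolume × Kvol`, the proton
  efflux rate;
* `mitoPER = max(0, OCR_basal − OCR_rotaa) × CCF`, the CO₂-derived
  acidification (CCF default 0.61);
* `glyco_atp = max(0, PER − mitoPER)` (1 ATP per lactate-derived H⁺)
  and `total_atp = mito_atp + glyco_atp`.

The P/O and CCF defaults are the vendor conventions for this assay; the
ECAR→PER conversion product defaults to 1, i.e. ECAR is read as an
already-calibrated proton efflux rate, because buffer factor, microchamber
volume and the volume scaling factor are instrument- and medium-specific
numbers that belong in the user's assay configuration, not in code.
Negative intermediate rates, which measurement noise can produce, are
clamped to zero with a logged warning rather than an error. The
zero-noise simulator propagates configured group multipliers exactly
(e.g. a 1.5× OCR multiplier yields exactly a 1.5× mitochondrial ATP
fold), which the tests exploit.

Group comparisons use mean ± SEM, fold versus control, and the exact
two-sided Mann–Whitney U test: full enumeration of all
$\binom{n_1+n_2}{n_1}$ mid-rank assignments for $\min(n_1,n_2) \le 8$
(ties handled exactly), tie-corrected normal approximation with
continuity correction above. The two-sided p doubles the smaller tail and
caps at 1, so a fully separated 5-vs-5 comparison gives p = 2/252.

# Bench-assay statistics

* `ddctExpression()` — Livak 2^−ΔΔCt: technical replicates averaged per
  sample, ΔCt against the reference gene per sample, ΔΔCt against the
  arithmetic mean of control ΔCt per gene (so control relative
  expression is geometrically centred at 1).
* `densitometryNormalize()` — band/loading ratios rescaled to control
  mean 1 by default (figures conventionally display control near 1); a
  `rescale = FALSE` switch reports raw ratios.
* `percentOfControl()` — value / control mean × 100.
* `twoGroupTest()` — encodes the study's N-based rule: pooled-variance
  Student's t (the study names Student, not Welch) for min(n) ≤ 3,
  exact Mann–Whitney for min(n) ≥ 5; min(n) = 4 is unspecified by the
  rule and falls back to t with a logged note. Zero pooled variance is
  resolved by convention (p = 1 for equal means, p = 0 otherwise,
  logged). Significance labels use the strict cutoffs
  `*** < 0.001 ≤ ** < 0.01 ≤ * < 0.05 ≤ ns`.

# Orchestration and numerical conventions

`runPipeline()` chains counts → DE → correction, plus the flux and assay
branches when inputs are provided, accepts in-memory objects or TSV/CSV
paths, propagates stage-tagged errors, and returns a printable run report
(genes tested, up/down calls, correction model, ATP and assay summaries,
version and config echo); partial inputs give partial reports, never
silent omissions. `massToMolar()` converts dosing units:
µM = (ng/mL)/(g/mol), so plasma levels of 350–650 ng/mL of 20E
(MW 480.64 g/mol) correspond to 0.73–1.35 µM (display rounded to two
decimals; full precision returned).

Determinism: every generator takes an explicit seed and restores the
caller's RNG state; identical seeds give bit-identical outputs, which the
round-trip and determinism tests assert. Problem sizes used by the test
suite and the acceptance script — 10,000 genes for artifact calibration
and recovery, 5,000-gene null replicates for test calibration,
2,000 genes for power, 25–50 simulated plates for flux folds — were
chosen as the smallest scales at which the Monte-Carlo noise of each
checked quantity is comfortably below its assertion tolerance.

# Known limitations

* The exact test conditions on rounded equalized pseudo-counts; for very
  small libraries the rounding is a source of discreteness that the
  calibration tests bound but do not remove.
* The dispersion estimator is method-of-moments with fixed shrinkage, not
  a likelihood-based empirical-Bayes fit; it is near-unbiased at the
  simulated settings but less efficient than qCML-style estimators.
* The length correction removes a *linear* LogTL trend; curvature in a
  real LogFC–LogTL dependence would leave a residual.
* The flux decomposition trusts the phase labels in its input; it does
  not infer injection timing from raw instrument exports.
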