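---
title: "Models and methods behind methylCD8"
author: "methylCD8 authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methylCD8}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylCD8)
```

# Scope and data model

methylCD8 analyses EPIC-like DNA-methylation array data from sorted CD8⁺
T cells in a three-group design — healthy controls (HC), skin psoriasis
(Pso) and psoriatic arthritis (PsA) — with optional paired
before/after-treatment samples for patients on cytokine blockers. The
central container, `MethylationExperiment`, extends
`RangedSummarizedExperiment`: the `beta` assay holds methylation
fractions, `rowRanges()` the probe manifest (1-based positions, I/II
chemistry, gene/region labels, CpG-island context), `colData()` the
sample sheet. Internal coordinates are 1-based inclusive, the Illumina
manifest convention; BED export converts to 0-based half-open, so BED
width equals `end − start + 1`. Strand is carried but ignored — after
bisulfite conversion, methylation calls are strand-symmetric. The
pipeline is genome-assembly-agnostic; an assembly string travels as
metadata only. Missing β values are rejected at the door: probe filtering
precedes analysis, and every downstream contract can then assume a
complete matrix.

# Quality control and normalization

`filterProbes()` removes probes in a fixed, documented order: (i) any
sample's detection p above the 0.01 cutoff, (ii) known-SNP probes,
(iii) probes not in CpG context, (iv) cross-reactive probes. A probe
matching several rules is counted once, at the first rule, so the filter
report reconciles exactly (`nInput − Σremoved = nRetained`). Non-CpG
probes are recognized by probe-id prefix (ids not starting `cg`, i.e.
Illumina `ch`/`rs` naming), since the manifest's type column describes
chemistry (I/II), not sequence context. SNP and cross-reactive lists are
user-supplied plain-text files; ids absent from the matrix are warned
about and ignored rather than treated as errors, because published
exclusion lists routinely cover more probes than any filtered matrix.

Statistics run on M values, M = log₂(β/(1−β)), which are far closer to
homoscedastic across the β range than β itself; effect sizes are reported
on β, which is what a biologist can read as a methylation-percentage
difference. β is clipped into [ε, 1−ε] with ε = 1e-6 before the logit —
|M| is then bounded by ≈ 19.9, safely finite yet far outside any
biological value, and `mToBeta(betaToM(x))` is an identity to 1e-10 on
the clipped domain.

Probe-chemistry normalization maps, within each sample, the type II β
values onto the type I empirical quantile function: each type II value is
replaced by the type I quantile at its own rank (rescaled to [0, 1]).
The map is monotone, leaves type I values untouched, is the identity when
the two chemistries already share an empirical distribution, and is
verified by a distribution-distance (KS) reduction test. We chose this
single direct quantile map over a three-state beta-mixture fit: the goal
— aligning the two chemistries' distributions — is the same, the map has
no convergence failure modes, and its correctness is testable by simple
distributional assertions.

## Batch correction

`combatCorrect()` implements the parametric empirical-Bayes
location/scale family: per probe, data are standardized against a design
holding batch indicators plus the biological group factor (so balanced
group contrasts survive); per-(batch, probe) location γ and scale δ²
estimates are shrunk toward a normal and an inverse-gamma prior whose
hyperparameters come from across-probe moments; posterior modes are found
by a fixed-point iteration (relative tolerance 1e-4, at most 100
iterations — in practice a handful suffice); the adjusted data are
back-transformed. Guards: a single batch returns the input unchanged, a
batch with one sample is an error (its scale is undefined), and a batch
perfectly confounded with group is an error naming the confounding —
no adjustment can separate the two.

Two properties deserve honesty. First, the residual between-batch mean
difference after correction is bounded below by the sampling noise of the
per-batch means, scaled down by the EB shrinkage; on M-value data at the
array's residual noise (SD ≈ 0.25) with 20 samples per batch, a planted
+1 shift drops to a median residual of a few hundredths. Second, the
adjustment is only approximately idempotent: a second pass re-estimates
scales as 1 + sampling noise and the inverse-gamma shrinkage rescales by
that noise, so the second-pass shift is small (an order of magnitude
below any real batch effect) but not zero. The test suite asserts the
real behaviour, and the suite also cross-checks the whole adjustment
against an independent reference implementation to ~1e-5.

# Differential methylation

## Positions

The moderated t machinery lives in `fitModerationPrior()` and
`moderatedTTest()`. The hierarchical variance model is: observed residual
variances s² | σ² ~ σ²·χ²_d/d, with the per-probe true variances drawn
from the scaled chi-squared prior σ² ~ s₀²·χ²_{d₀}/d₀. Both
hyperparameters are estimated by matching the empirical mean and variance
of log s² to the model's digamma/trigamma moments; the variance match
needs `trigammaInverse()`, a Newton iteration accurate to 1e-8 across
twelve orders of magnitude. Degenerate regimes are explicit: identical
variances or no excess dispersion beyond χ² sampling noise give d₀ = ∞
with s₀² the common variance; all-zero variances are an error. `df = Inf`
is accepted for variances observed without sampling noise, which is how
the prior-recovery simulation is expressed. Note this parameterization
shares its d₀ moment match with the inverse-chi-squared formulation used
by the classic microarray EB machinery but differs in the sign of the
digamma correction for s₀²; the two coincide as d₀ grows, and the test
suite pins down both the shared quantities (against limma) and the exact
limits d₀ = 0 (classical pooled t, equal to `t.test` to 1e-10) and
d₀ = ∞ (z-like statistic with pooled prior variance).

`callDMPs()` keeps probes with BH-FDR < 0.05 and |Δβ| > 0.1 — the joint
rule matters: the FDR controls error rates, the Δβ floor removes
statistically solid but biologically negligible calls. Direction
(`hyper`/`hypo`) is defined relative to the second-listed contrast group;
the before/after-treatment contrast defaults to the paired one-sample
analogue keyed on `subject_id` (the same subjects are measured twice;
both modes are exposed because the pairing choice is a design decision,
not a fact of the data). FDR is computed within each contrast
separately. Sex and age are recorded in the sample sheet but not modelled
— the contrasts are plain two-group comparisons.

## Regions

`callDMRs()` is deliberately two-layered. Candidate probes must pass the
probe-level FDR gate *and* have kernel-smoothed t² above the
squared-standard-normal 5 % critical value (`qchisq(0.95, 1)` ≈ 3.84).
The smoothing (Gaussian kernel, bandwidth λ = 1000 bp, SD = λ/C with
C = 2, weights normalized so every output is a convex combination)
confirms that a candidate sits in an elevated neighbourhood; the
significance decision itself stays with the exact probe-level FDR. We
chose this over propagating smoothed variances into approximate region
p-values: the module remains testable against exact oracles, at the cost
of not reproducing the smoothed-variance p-value column some region
callers report. Candidates are merged while consecutive gaps are ≤ λ —
the kernel's own scale is the only distance the model distinguishes — and
regions are kept when they contain ≥ `minCpgs` probes (reported for 5,
10 and 20; the sets nest by construction) and |mean Δβ| ≥ 0.1. Combined
region statistics: Stouffer (z̄ = Σzᵢ/√k with zᵢ = Φ⁻¹(1−pᵢ)), Fisher
(−2Σln pᵢ against χ²_{2k}) and the harmonic mean of the member FDRs;
p = 0 inputs are clipped to 1e-300 with a warning. A region's genes are
the union of its member probes' manifest gene labels — a probe-annotation
union, not a positional interval query, which keeps the column faithful
to what the array actually measured.

# Annotation and over-representation

`distributionTable()` classifies each DMP once per axis: gene-region
(promoter = TSS1500/TSS200/5′UTR, 3′UTR, Body, ExonBnd, IGR, with
precedence promoter > 3′UTR > ExonBnd > Body > IGR for multi-gene
probes — single-count classification is what makes the percentages sum
to 100) and island context (Island/Shore/Shelf/OpenSea), split by
all/hyper/hypo. For *gene-set* construction the opposite convention
applies: all annotated genes of a multi-gene probe qualify, since a
promoter DMP in two genes is evidence about both. `overlapSets()`
enumerates the full inclusion–exclusion lattice (Venn region counts),
checked against brute force. `hypergeometricEnrichment()` computes the
upper-tail hypergeometric p with Bonferroni correction across terms; the
universe is the set of genes annotated on the post-filter manifest — the
standard array-aware background, since genes never measured cannot be
enriched. Gene sets arrive as GMT files; there are no live database
queries, which keeps runs reproducible and offline.

# The disease-activity score

The score asks a narrow clinical question: do the treatment-responsive
CpGs in the cytokine pathways under therapy track skin disease activity?
`selectActivityDMPs()` restricts a DMP list to probes on pathway genes,
then keeps probes whose β–PASI Pearson correlation exceeds |r| > 0.8
across patient samples (by default every sample with a PASI value,
before and after treatment; a `timepoints` argument restricts).
`fitScoreModel()` freezes per-probe healthy-control means and SDs (β
scale, n−1 denominator; probes constant across controls are dropped with
a warning). `computeScores()` sums SV = (β − mean_HC)/SD_HC, so a sample
sitting on the healthy means scores exactly 0 and one probe one SD out
moves the score by exactly 1.

One methodological caveat is built into the interface rather than hidden:
the published procedure selects probes by their PASI correlation and then
reports the score–PASI correlation on overlapping samples. The package
reproduces that procedure and makes the circularity visible —
`correlateScoreActivity()` reports how many correlated samples were also
selection samples — and the `timepoints` argument supports held-out
variants (select on before-treatment samples only, evaluate elsewhere).
No claim is made about which variant the original analysis used.

# The synthetic cohort and what it does (not) show

`generateCohort()` works entirely on the M scale:

    M = logit₂(β_base) + group effect + batch offset + activity term + ε,

with ε ~ N(0, 0.25) and β recovered by the inverse logistic — effects
stay additive where the statistics live and β stays in (0, 1) without
truncation. Baseline β_base is a low/mid/high trimodal mixture
(weights 0.45/0.15/0.40), the familiar two-shoulder array marginal.
Defaults mirror the study design the package targets: 9 HC / 10 Pso /
7 PsA with 5 treated subjects resampled after therapy; 20,000 probes over
four chromosomes (a desk-scale stand-in for the 850k array); 1 % planted
DMPs at |Δβ| = 0.2 (targeted on the β scale, converted to M shifts);
three directionally coherent 8-CpG DMR blocks placed in dense,
island-like probe clusters — real DMRs live at CpG-dense loci, and a
region with mixed signs is not a DMR; two batches with per-(batch, probe)
N(0, 0.3) M-scale offsets; 10 activity CpGs with mid-high baselines.
Manifest geometry is a two-state dense/sparse gap chain whose island
context is derived from neighbour distance with the real definitions
(≤ 2 kb shore, 2–4 kb shelf); gene labels come in consecutive runs at
roughly one third promoter, one third body, one third intergenic.

Disease activity is generated causally in the direction methylation →
PASI: each patient draws a latent severity, activity CpGs are
hypomethylated proportionally (loading ~ U(0.8, 1.2)), and PASI is the
mean activity-CpG β mapped through a negative slope (default −0.03 β per
PASI unit) plus noise, truncated at 0. After-treatment samples keep 15 %
of their severity, so their methylation — and hence their score — moves
back toward the healthy controls, and their PASI falls. The activity
CpGs therefore genuinely differ between HC and patients and between
before and after, and the truth object records them in those contrasts.

What passing tests on this generator show: the estimators recover the
planted parameters, error rates are calibrated on exchangeable nulls, and
the full chain (QC → normalization → batch correction → paired DMPs →
pathway restriction → |r| filter → score) finds a planted activity signal
of realistic size. What they do not show: robustness to features the
generator omits — cell-composition drift, probe-specific artefacts
beyond the label lists, spatial correlation of noise along the genome,
non-normal M-value noise, confounded batches, or PASI measurement error
correlated with treatment. Results on real cohorts depend on those.

# Numerical choices and degenerate inputs

* ε = 1e-6 for the logit clip; 1e-300 for zero p-values; score SDs of 0
  drop the probe rather than emit infinities.
* Kernel support is truncated at 4 SD with a sliding window, so smoothing
  is O(n·window) per chromosome; λ → 0 degenerates to the identity.
* Quantile mapping uses type-7 quantiles with ranks rescaled by
  (rank − 1)/(n − 1); ties share a rank (ties.method = "average") and so
  map to equal values — order is preserved weakly, never inverted.
* The moderation-prior fit replaces isolated zero variances by 1e-3 times
  the smallest positive value before taking logs; all-zero input errors.
* `trigammaInverse` uses closed-form tails (1/x below 1e-6, 1/√x above
  1e7) around the Newton region.
* Seeds: every generator function derives a child seed from the design
  seed and a stage label by a small integer hash kept below 2³¹, so
  stages are independently reproducible and reordering stages cannot
  silently change a stage's stream.

Test and acceptance problem sizes — chosen as the smallest sizes at
which the asserted statistical properties are stable, and stated here as
the package's own study conditions: type-I calibration on 200 effect-free
cohorts of 5,000 probes (9 vs 10 samples); prior recovery at 10⁴ probes;
DMP recovery at 10⁴ probes with 1 % planted effects (10 vs 10); DMR
recovery over 100 replicates of three 6-CpG blocks in 5,000 probes;
batch correction at 5,000 probes, 20 per batch; the end-to-end score
chain over 100 replicates of the default 20,000-probe cohort.

# Pipeline, caching, provenance

`runPipeline()` executes simulate → preprocess → DMP → DMR →
annotate/enrich → score from one YAML config. Each stage writes its
outputs plus a key file holding the digests of its inputs and config
slice; a stage whose outputs exist under an unchanged key is skipped, so
deleting an intermediate recomputes that stage while upstream stages are
served from cache and downstream stages revalidate against the
regenerated (byte-identical) digests. A JSON run manifest records the
config snapshot, input digests, per-stage row counts, package version and
seed; a JSON-lines log records per-stage timings. Exit semantics for the
thin command-line wrapper (`inst/scripts/methcd8.R`): 0 success, 2
usage/config error, 3 data error.

# Known limitations

* No IDAT/raw-intensity support: the pipeline starts at a β matrix.
* Two-group contrasts only; no covariate adjustment, surrogate variables
  or cell-type deconvolution.
* The region caller reports combined probe-level statistics, not
  smoothed-variance region p-values.
* The enrichment module is set-based; no GO-graph topology or term
  redundancy handling.
* The activity score is descriptive: no cross-validation, no penalized
  selection, no clinical cut-points. The selection/evaluation overlap it
  reports is the reader's warning, not a correction.
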