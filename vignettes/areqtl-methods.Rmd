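---
title: "Methods and design of areqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of areqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`areqtl` analyzes the genetic regulation of active regulatory elements
(AREs) — promoter/enhancer intervals marked by H3K27ac — across tissues:
quantification, module classification, cis-haQTL mapping, cross-tissue
sharing, colocalization with GWAS and eQTL signals, and ARE–gene
linking. This vignette documents the models, the parameters that matter,
the synthetic-data design, and the numerical and design choices, in the
order the pipeline runs them.

## ARE activity and normalization

Activity of ARE $i$ in sample $k$ is fragment coverage per base,

$$\mathrm{Activity}_{i,k} \;=\; \frac{\sum_j
\mathrm{overlap}(\mathrm{Frag}_{j,k}, \mathrm{ARE}_i)}{\mathrm{length}_i},$$

with BED-style 0-based half-open coordinates throughout. Fragment
extension from raw reads is out of scope: inputs are already fragment
intervals. Quantification is additive in fragments and uses
IRanges/GenomicRanges overlap machinery.

Sample depth is removed by median-of-ratios size factors: for AREs
positive in every sample, factor$_k$ = median$_i$ of
value$_{i,k}$/geomean$_i$, computed in log space (for an even number of
informative AREs the log-space median — the geometric mean of the two
central ratios — is used, matching the reference implementation of this
estimator) and rescaled so the factors have geometric mean 1. A matrix
with no all-positive ARE row is an error instructing the caller to
pseudo-count or filter, rather than silently guessing.

GC-content correction is deliberately simple — per-sample median
equalization within GC-quantile bins (default 10) — and off by default:
it removes monotone GC artifacts but is a coarser tool than full
loess-style corrections, and on GC-independent data it perturbs values
only at the level of bin-median sampling noise.

Candidate-peak filtering keeps a peak if (q ≤ 0.01 and it overlaps
peak calls, by ≥ 1 bp, in ≥ 2 Tier-1 samples) or it overlaps a
tissue-matched reference peak; rescue deliberately ignores the q-value,
since a reference overlap is independent evidence of activity. Peaks
must then overlap a promoter/enhancer chromatin-state interval by
≥ 50 bp. "Presence in a sample" is defined as ≥ 1 bp overlap between
peak calls; any stricter reciprocal-overlap rule would add a parameter
with no principled default.

## Module classification

Activity (or −log10 p signal) is binarized at an inclusive cutoff
(default 2) and clustered by a Lloyd-style k-centroids algorithm under
the generalized Jaccard distance $1 - \sum_j \min(x_j, c_j) / \sum_j
\max(x_j, c_j)$, which reduces to 1 − Jaccard index for binary vectors
and extends naturally to the real-valued mean centroids used in the
update step. Assignment ties break to the lowest module index; the best
of `n_restarts` random restarts by total within-cluster distance is
kept. Because the mean centroid is not guaranteed to be the
distance-minimizing centroid under this metric, an iteration that fails
to decrease the objective terminates the run with the previous state,
so the recorded objective trace is non-increasing by construction.
Equivalence with other k-centroids implementations is asserted at the
level of planted-partition recovery (adjusted Rand index 1 on
noise-free blocks), not coordinate-level identity.

Groups follow a fixed rule order: ubiquitous score (fraction of samples
with module-mean activity ≥ 0.2) above 0.5 → broadly-active; in
(0.1, 0.5] → multitissue; all-zero activity → newly-detected; otherwise
the sample cluster (average-linkage hierarchical clustering on
1 − Pearson correlation; default 11 clusters in real mode, configurable
down for small cohorts) where the module's mean signal is strongest.
Boundary scores (exactly 0.5 or 0.1) fall to the lower category because
the defining rule for the upper category is a strict "above".

## cis-QTL mapping

Phenotypes are residualized once on known covariates plus the top
principal components of the phenotype matrix, then scanned. PCs stand in
for latent-factor inference: they capture the same broad unwanted
variation (including the cell-fraction-like confounder the generator
plants) and are deterministic. Residualize-then-scan is orders of
magnitude faster than per-variant multiple regression; the lost degrees
of freedom are restored by testing with df = n − 2 − (number of
removed regressors), so nominal p-values match the full regression
asymptotically and the permutation null uses the same df.

The nominal scan covers variants within 100 kb of the ARE center at
MAF ≥ 0.05 (computed on the tested individuals). Empirical p-values
follow the permutation scheme standard for cis-QTL mapping: permute the
phenotype (default 1,000 times), record the minimum nominal p per
permutation, fit Beta(a, b) to the minima by maximum likelihood
(L-BFGS-B on log-shapes from a method-of-moments start, shapes clamped
to [10⁻³, 10⁶], minima clamped away from 0/1 before taking logs), and
report BetaCDF(observed lead p) together with the direct estimate
(r + 1)/(n + 1). Both are reported because they can disagree at
finite permutation counts; the Beta-approximated value is used
downstream. gAREs are features with empirical p ≤ 0.005; their haQTLs
are variants with nominal p at or below the per-locus threshold
BetaQuantile(0.005; a, b) — with a single tested variant the fitted
shapes are near (1, 1) and the threshold collapses to 0.005 itself.
Lead ties break by smallest p, then smallest |distance to center|, then
variant id, making results order-independent. Each feature draws its
permutations from a child seed of the global seed, so per-feature
results do not depend on which other features are in the batch.

## Tissue sharing

For lead haQTLs of gAREs discovered in one tissue, replication
statistics in another tissue are attached for the same (ARE, variant)
pair; AREs absent from the replication tissue are routed to the
ARE-specific class rather than silently dropped. Pairs are binned by
replication nominal p at (10⁻⁵, 10⁻³, 0.1); the directionality
consistency DC$_i$ is the sign-agreement fraction in bin $i$ (pairs
with an exactly-zero effect are dropped with a warning — the sign is
undefined and the estimator is unaffected asymptotically), and

$$\mathrm{sharing} \;=\; \sum_i \mathrm{Perc}_i\,(2\,\mathrm{DC}_i - 1),$$

so a bin at chance consistency contributes nothing and a perfectly
concordant bin contributes its full weight. The raw value lies in
[−1, 1]; the reported value is clamped to [0, 1] with the signed value
retained for diagnostics. This estimator is consistent for the planted
sharing proportion only when replication is well powered: with
replication standard error $s$ and discovery effects $\beta \sim
N(0, \sigma^2)$ the expected estimate is $s^{*} \cdot
E[2\Phi(|\beta|/s) - 1]$, a downward bias of order $s/\sigma$. The
validation fixture (`simulate_lead_pairs`) therefore uses a
well-powered replication ($s = 0.02$ at $\sigma = 0.8$, bias ≈ 0.013)
and plants the shared count exactly as round(s·n). gARE types use the
replication threshold p ≤ 0.02 in ≥ 1 other tissue for type I; the
per-gARE aggregation over replication tissues is "any", the natural
per-element summary of the pairwise definition.

## Colocalization

Per-variant evidence is the Wakefield approximate Bayes factor,
$\log \mathrm{ABF} = \tfrac12 \log(1 - r) + \tfrac12 z^2 r$ with
$r = W/(V + W)$, $V = \mathrm{se}^2$, and prior effect variance
$W = 0.15^2$ for quantitative traits (0.2 on the log-odds scale for
case-control), the field-standard defaults, as are the priors
p1 = p2 = 10⁻⁴ and p12 = 10⁻⁵. Hypothesis sums over
single-causal-variant configurations are computed entirely in log space
(log-sum-exp; H3 via the stable log-difference
$\log(S_1 S_2 - S_{12})$), which stays finite for |z| up to 50 across
10⁴ variants. Loci are colocalized at GWAS–haQTL PP4 ≥ 0.5;
colocalized loci with no gene reaching GWAS–eQTL PP4 ≥ 0.1 are
bulk-eQTL-missing. Fewer than 10 shared variants triggers a warning
rather than an error.

## gLink scores

Candidate pairs are gAREs 2 kb–1 Mb from a gene TSS, distance measured
to the nearer ARE boundary (the "proximal" language of the linking
framework refers to element edges, not centers). The six component
scores: distance from the gARE to the gene's fine-mapped eQTLs (0 if
inside, infinite sentinel if the gene has none; proximal ≤ 2 kb);
minimum nominal eQTL p within 2 kb of the gARE; coloc PP4 between the
haQTL and eQTL signals; PP4/PP3 capped at 10⁶ when PP3 underflows; the
MR Wald ratio β_eQTL/β_haQTL at the lead-haQTL instrument with
first-order delta-method standard error, BH-adjusted across pairs and
called at adjusted p < 0.2 (instruments with |β_haQTL| < 10⁻¹² are
flagged invalid; an inverse-variance-weighted multi-instrument variant
is available); and the Pearson correlation between gARE activity and
polygenic-score expression (Σ weight·dosage over the gene's independent
eQTLs). The unified score maps each available component to a percentile
rank oriented so larger = stronger (distances and p-values inverted;
the ExpPGS correlation enters by magnitude) and averages them, ignoring
missing components but recording their count — a transparent rank
aggregation chosen because the combination rule is otherwise
unconstrained; it is configurable. Enrichment of GWAS-colocalized gAREs
among linked gAREs uses a one-sided two-sample proportion z-test with
pooled variance and no continuity correction.

## The synthetic cohort generator

The generator exists so that every stage can be tested against known
ground truth without access-controlled data. Genotypes are two
independent haplotypes per individual, each a thresholded AR(1)
Gaussian field (correlation `ld_rho` between adjacent variants inside
`ld_block_size` blocks), giving Hardy–Weinberg dosages with
geometrically decaying within-block LD — simple, controllable, and
sufficient for QTL and colocalization testing, though without
population structure, admixture, or realistic recombination maps.
Activity is baseline + β·dosage + covariate loadings + homoscedastic
Gaussian noise; count-level noise enters only through
`simulate_fragments`, which inverts the activity formula with Poisson
fragment counts placed uniformly inside each ARE so the expected
re-quantified activity equals the depth-scaled input. No explicit
generative model for ARE activity is established in this field; the
linear-Gaussian form mirrors the additive model the QTL regression
assumes, which is exactly what makes planted effects recoverable and
calibration interpretable. Covariate loadings are drawn once per
cohort, with the first covariate loading in a common direction across
AREs to mimic a cell-fraction confounder and justify factor removal.

Effects are planted in a primary tissue and propagated to others with
the probability given by the symmetric `sharing_matrix`, always with
identical sign and magnitude. Genes are paired round-robin with
effect-carrying AREs; a fraction `frac_shared_causal` of pairs reuses
the ARE's causal variant (these are the true links), the rest draw a
distinct cis variant. GWAS effects are planted on a fraction of haQTL
causal variants at a target |z| (default 8), propagated through panel
LD, and perturbed at the standard-error scale
1/√(2·MAF·(1−MAF)·n), the standard value for a standardized trait.
Two geometry choices matter for colocalization: AREs are spaced ~33 kb
apart by default (`pos_step` = 5 kb × ~6.7 variants per ARE), and
planted GWAS-causal variants keep a minimum spacing of one cis-window
diameter (200 kb, greedy selection), so each locus carries at most one
planted association peak — the geometry the single-causal-variant
colocalization model assumes. Violating either (dense AREs, unspaced
GWAS causals) floods windows with foreign peaks and legitimately
suppresses PP4.

What passing tests on this generator do **not** show: robustness to
count overdispersion, GC and mappability artifacts, duplicated reads,
cell-type heterogeneity beyond one linear confounder, non-Gaussian
effect-size distributions, or LD mismatch between the QTL cohort and
the GWAS population. At the default cohort size (60 individuals per
tissue) GWAS–haQTL colocalization yield is low (0–3 loci per seed)
because haQTL Bayes factors are weak at that n — the same sample-size
limitation reported for real cohorts of this design; the dedicated
colocalization validations therefore plant |z| ≥ 8 on both sides.

## Validation problem sizes

The shipped checks use: worked formula cases (exact); 50 × 5 random
designs against closed-form regression (10⁻¹⁰); a global-null
calibration with 200 features × 100 individuals × 50 variants × 1,000
permutations (KS uniformity, type-I at 0.05 inside the 99% binomial
band) plus 50 loci at 10,000 permutations for the Beta-vs-direct
comparison (within 0.02); 200 planted loci at n = 100 for effect
recovery, asserted as a bias bound of 0.05 at the causal variant — the
mean *absolute* error of a single-locus OLS slope at this n and noise
level is ~0.8·se ≈ 0.1 by the sampling distribution and is reported
alongside, not bounded; 1,000 simulated lead pairs at planted sharing
0.2/0.5/0.8 (within ±0.07); colocalization enumeration oracles on
5-variant loci (10⁻⁹) and 100 planted 200-variant loci (median PP4,
PP3 ≥ 0.9); a 400 × 40 planted-block clustering (ARI = 1); and a
400-gARE / 200-gene / n = 200 cohort for gLink recovery (AUPRC of
coloc PP4 and of the unified score ≥ 3× the planted base rate, MR sign
agreement ≥ 95% among MR-confirmed pairs — a sign claim is only
meaningful where the Wald ratio is distinguishable from zero, and with
Gaussian planted effects the unconditional agreement is analytically
capped near 90% by near-zero outcome effects).

## Known limitations

Single-causal colocalization only (no multi-signal or LD-aware
fine-mapping); no conditional or trans QTL mapping; no genome-wide FDR
across features (the empirical-p threshold is fixed by design); the GC
correction is a coarse bin-median equalizer; fine-mapped eQTLs are
consumed as input (planted truth in synthetic mode), never computed;
and the unified score is one reasonable aggregation among several — its
percentile-rank form is transparent and monotone-invariant but ignores
component correlation.
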