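---
title: "Statistical methods and design notes for mppscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods and design notes for mppscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mppscan)
```

# The mapping model

mppscan analyzes eight-founder multiparental mouse populations (the
Collaborative Cross and Diversity Outbred stocks). The genotype data are
founder haplotype dosage probabilities: for each individual and marker, a
probability vector over the 8 founder strains (A/J, C57BL/6J, 129S1/SvImJ,
NOD/ShiLtJ, NZO/HlLtJ, CAST/EiJ, PWK/PhJ, WSB/EiJ; letter codes A–H). The
additive genome scan fits, at every marker m,

$$y_i = \mathbf{p}_{im}^\top\boldsymbol\beta_m + \mathbf{x}_i^\top\boldsymbol\gamma + g_i + \varepsilon_i,
\qquad g \sim N(0,\; \sigma^2_g K), \quad \varepsilon \sim N(0,\; \sigma^2_e I),$$

where $\mathbf{p}_{im}$ is the 8-vector of founder dosages, $\mathbf{x}_i$
the covariates (explicit intercept; factors treatment-coded), and $K$ a
genetic relationship matrix. The interactive model adds a factor and its
dosage-by-factor products; its default display statistic is the
*interaction-delta* LOD (full-model LOD minus additive LOD), because the
interactive question is the improvement over the additive fit. The
full-model curve is always returned alongside, since the choice of display
statistic is a convention, not a theorem.

The X chromosome is treated exactly like the autosomes: sex differences are
expected to be encoded in the input probabilities, and sex is recommended
(not forced) as a covariate.

## Kinship

$K_{ij} = \frac{1}{M}\sum_m \sum_f p_{imf}\,p_{jmf}$ — the marker-averaged
probability of sampling the same founder allele. With fully certain
homozygous calls the diagonal is exactly 1. No rescaling to mean-diagonal 1
is applied: LOD curves are invariant under $K \to cK$ because the variance
ratio reparameterizes (this invariance is tested to 1e-4). The
leave-one-chromosome-out (LOCO) family computes each chromosome's matrix as
a direct sum over the *other* chromosomes — not as "total minus one", which
would leak floating-point perturbations from the left-out chromosome into
its own K and break exact LOCO independence (this bit-for-bit independence
is a tested invariant).

## Fitting schedule

The variance ratio $h^2 = \sigma^2_g/(\sigma^2_g+\sigma^2_e)$ is estimated
once per (trait, chromosome) under the null — no QTL term — by restricted
maximum likelihood, and held fixed across the chromosome's markers. This is
the standard fast approximation in multiparental-population practice: it
makes a scan cost one least-squares solve per marker in the eigen-rotated
space, where $\mathrm{LOD}_m = \frac{n}{2}\log_{10}(RSS_0/RSS_m)$ with $n$
the complete-case count. With `kinship = NULL` the scan reduces to
Haley–Knott-style ordinary least squares, which is the path validated
against an independent SVD-projector oracle to 1e-8.

Numerical choices:

* REML search: Brent (`optimize`) on $h^2 \in [0,\,1-10^{-6}]$, tolerance
  1e-8, with the boundary $h^2 = 0$ checked explicitly.
* Eigenvalues of K below 1e-10 are clipped to zero (PSD repair), so
  rotation weights $h^2\lambda_k + (1-h^2)$ are never negative.
* The marker design (8 dosage columns plus intercept) is rank-deficient by
  construction (the dosages sum to 1). All LODs come from residual sums of
  squares via rank-revealing pivoted QR, so the coefficient basis never
  affects the LOD — dropping any one founder column is a tested exact
  invariance.
* Markers with no dosage variance contribute LOD 0, not an error.
* Complete cases are taken per trait (and per mediator in mediation);
  rank-deficient covariate designs raise an error naming the collinear
  columns.

## Null distribution of the LOD

The founder-dosage block is a 7-degree-of-freedom test, so under the null
$2\ln(10)\,\mathrm{LOD} \sim \chi^2_7$ asymptotically and the *median*
per-marker LOD is about 1.38. This matters when reading mediation output
(a completely mediated QTL falls to this null level, not to zero) and
explains why small-median heuristics apply only to 1-df statistics such as
the SNP-dosage scan (median ≈ 0.10). The test suite asserts both laws.

# Founder allele effects

Fixed-mode effects are the 8 dosage-block coefficients with the intercept
absorbed into the block; they reproduce the scan LOD exactly (same residual
space). For display they are centered to sum zero across founders — the
centering convention is a design choice (no standard exists); the raw basis
is retained in the object.

BLUP mode treats the 8 effects as a random vector $b \sim N(0, \tau^2 I)$
with the intercept back among the fixed effects. The ratio
$\tau^2/\sigma^2_e$ is estimated per marker by a grid-refined Brent REML
search (tolerance 1e-6) using Woodbury identities so every solve is 8×8.
Properties that follow and are tested: the centered BLUP sum of squares
never exceeds the fixed-effect one (shrinkage); ratio 0 gives exactly zero
effects; ratio $10^6$ recovers the centered fixed effects within 1e-3 (the
flat-prior limit is the minimum-norm, i.e. sum-zero, solution of the
rank-deficient fixed fit).

# SNP association

A biallelic variant's strain distribution pattern (SDP) is an 8-bit integer
— bit f set when founder f carries the alternate allele, A/J = bit 0,
little-endian, stored as a decimal 1..254 (0 and 255 are monomorphic and
rejected everywhere). The imputed dosage sums the carrier founders'
probabilities at the *nearest marker* (ties to the lower position).
Nearest-marker rather than interpolation is a deliberate cheap standard; at
DO marker density the difference is negligible, and this is documented as a
fidelity caveat rather than a claim. Variants sharing (nearest marker, SDP)
are statistically identical, so they are fit once and broadcast; the
association table records the number of distinct fits. Complementary SDPs
give identical LODs (the dosage flip is affine). With kinship, the region
chromosome's LOCO matrix and the haplotype engine's null $h^2$ are reused.

# Mediation

For each candidate mediator the QTL at the chosen locus is retested with
the mediator appended to the covariates. The kinship term is excluded from
*both* the null and the alternative of every conditional fit — the standard
efficiency shortcut — so conditional LODs are comparable within a scan; the
kinship-aware marginal LOD from the haplotype engine is a different
quantity and is never mixed in. Each mediator is fit on the complete cases
of (target, mediator, covariates) with the null recomputed on that subset,
and the subset's marginal LOD is reported alongside; otherwise unequal
missingness across -omic mediators would distort comparability. A mediator
that explains the target exactly (e.g. the target itself) is flagged
degenerate with conditional LOD 0 rather than producing a spurious finite
value. Output is a ranked table, not significance calls: LOD-drop mediation
is known to be susceptible to false positives from linked independent
effects, so no formal threshold is attached.

# Summaries

* **Peaks**: per trait and chromosome, the maximum-LOD marker at or above
  the threshold; with `peakdrop`, additional local maxima separated from
  every accepted peak by a valley at least `peakdrop` below the lower of
  the two. Support intervals are the contiguous 1.5-LOD-drop region. The
  default -omic threshold of 7 is a conventional screen value and
  deliberately arbitrary; peak calling is threshold-monotone by
  construction.
* **Transcriptome map**: a peak is *local* when on the gene's chromosome
  within 10 Mbp of its midpoint, else *distal*. The numeric window is a
  design decision (labels by chromosome alone miss same-chromosome distal
  cases); shrinking the window can only convert local to distal.
* **Hotspots**: distal peaks counted in deterministic half-open bins
  `[lo, hi)` from the chromosome start.
* **Correlation**: both members residualized on the adjustment design, then
  Pearson; with an intercept-only design this equals plain Pearson to
  1e-10.

# The synthetic world

The simulator is first-class, tested code, and its defaults are the stated
world of the package's tests: 200 individuals, two chromosomes (90/80 cM,
120/100 Mbp), 101 markers per chromosome, outbreeding-generation scaling
g = 20 (typical of published DO cohorts), Dirichlet blurring with
concentration 200 (near-certain calls), balanced sex.

Haplotypes are first-order Markov founder mosaics: across an interval of
d cM a recombination event occurs with probability $1 - e^{-g d/100}$ and
the founder is redrawn uniformly. Uniform 1/8 founder frequencies are the
stationary law. This is adequate for exercising the statistics but is *not*
a population-genetic model of the DO: there is no crossover interference,
no CC-funnel pedigree structure, no founder-frequency distortion, and no
X-specific transmission. Dosage probabilities are the haplotype-pair
indicator averages, optionally Dirichlet-blurred with a small (1%) floor so
off-call founders receive trace mass — emulating genotyping uncertainty
while preserving row sums of 1 and the 1/8 marginals.

Traits are sums of *standardized* components — planted locus effects
(dosages times an 8-vector, or a ±1/2 biallelic SDP split), a
kinship-structured polygenic draw, a transmitted standardized mediator —
weighted by the square roots of their configured variance fractions, plus
iid noise carrying the remainder; a sex shift is added on top in residual-SD
units. Standardizing components empirically means realized variance
fractions track the configuration closely at large n (tested), at the cost
of small-sample conservation rather than exact population semantics.
Fraction sums ≥ 1 are rejected at configuration time; seeds are mandatory
and every generator is deterministic given its seed.

A green test on this world establishes that the statistical machinery does
what it claims on DO-*like* data; it does not establish calibration on real
DO cohorts, where linkage structure, founder-frequency distortion and
genotyping-error patterns differ.

# The study bundle

A bundle is a directory with a control JSON naming components: marker map,
covariates (+ metadata), one genotype-probability file per chromosome,
trait CSVs (+ optional annotations), founder SNP TSV. All files are UTF-8
text with numbers at 17 significant digits, so write→read is identity up to
float representation and writes are byte-stable (hash-identical across
runs). The genotype probabilities were specified for a hierarchical array
container (HDF5-like); no such R package is available in the supported
environment and the deliverable is text-only, so each chromosome is a wide
CSV (individual × marker rows, 8 founder columns) — the contract
(round-trip identity, validation, determinism) is unchanged. Legacy
RData/RDS study objects are deliberately not parsed; converting them is
documentation-level guidance, keeping this package free of foreign
serialization.

Individuals are aligned across components by intersection in
genotype-probability order: partial overlap ≥ 50% warns and proceeds,
below 50% fails. This is a stated decision — how a shared-mouse instance
*should* align partially observed datasets is not defined anywhere
authoritative — and per-analysis intersection is the conservative choice.

# Known limitations

* No permutation thresholds or cross-trait multiple-testing control; LOD
  thresholds are user-chosen.
* No dominance or pedigree kinship; the estimator is the dosage
  cross-product average, a stated decision rather than a claim of
  bit-equality with any reference implementation.
* BLUP standard errors and per-founder confidence bands are not computed.
* The simulator's population genetics are intentionally minimal (above).
* Mediation reports ranks, not causal claims.
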