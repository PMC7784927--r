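---
title: "Ratio-genotype G-BLUP and sequencing-resource optimization for autotetraploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratio-genotype G-BLUP and sequencing-resource optimization for autotetraploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tetragp` asks an economic question with statistical machinery: how much
genotyping can an autotetraploid breeding program give up — markers, capture
probes, sequencing depth, training individuals — before genomic prediction
degrades? This vignette documents the models behind each module, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical and design choices a maintainer should know
about.

## The prediction model

Phenotypes are first adjusted to least-squares means over seasons by
ordinary least squares on `value ~ genotype + year`, both categorical fixed
effects (`lsmeans_phenotypes()`). The adjusted mean of a genotype is the
intercept plus its effect plus the unweighted mean of the year effects; on
balanced data this is the simple genotype mean, and the implementation is
tested against both a hand-solved normal-equations fixture and `emmeans`.

The genetic model is G-BLUP on *continuous ratio genotypes*. For each
individual `j` and biallelic marker `i`, the genotype is the alternative-
allele read fraction `M[j, i] = AO / (AO + RO)`, a value in [0, 1] whose
expectation under unbiased allele sampling is dosage/4. Using the fraction
directly avoids calling tetraploid dosage classes, which is unreliable
below ~50X and is exactly the step this parameterization exists to skip.
The relationship matrix is

    G = Z Z' / h,   Z = column-centered M,   h = sum_i s_i^2,

with `s_i^2` the sample variance (divisor `n − 1`) of centered marker
column `i`. The divisor is a deliberate, testable choice: with it,
`trace(G) = n − 1` and all row sums are zero *exactly* for any complete
`M`, which the test suite asserts to 1e-10. `G` is invariant to rescaling
all marker spreads by a common constant, and monomorphic columns contribute
nothing.

The mixed model `y = mu + X g + e`, `g ~ MVN(0, G sigma_a^2)`,
`e ~ MVN(0, I sigma_e^2)` is sampled by `fit_gibbs()`. Because `y` holds
one adjusted mean per genotype, `X` is an identity selection of training
rows; repeated records are out of scope.

### The sampler and its priors

The sampler is blocked and fully conjugate. `G` is eigendecomposed once,
`G = U D U'`; writing `g = W alpha` with `W = U D^{1/2}` makes
`alpha ~ N(0, sigma_a^2 I)`. A second eigendecomposition of `W'W` on the
training rows rotates `alpha` so that its full conditional is diagonal, so
each iteration costs one matrix-vector product — this is what lets a
600-individual chain run in a couple of seconds and the whole demo
factorial in minutes. Candidate individuals' genetic values are sampled
jointly with the training ones (whole-`G` sampling) rather than projected
afterwards; the two agree in posterior mean, and the joint version is the
one that can be compared coordinate-by-coordinate against the closed-form
oracle.

Variance priors are scaled-inverse-chi-square with `df0 = 5` degrees of
freedom and scales set from the phenotypic variance split evenly
(`R2 = 0.5`) between the genetic term (scaled by the mean diagonal of the
training block of `G`) and the residual — the default-hyper-parameter
convention of Bayesian whole-genome-regression software. Both `df0` and
`R2` are arguments. The intercept has a flat prior. Supplying `sigma2_a` /
`sigma2_e` fixes them, turning the posterior mean of `g` into classical
BLUP; `fit_closed_form()` computes that BLUP deterministically (GLS
intercept under `V = G sigma_a^2 + I sigma_e^2`, training solve of
`(G_tt + lambda I) alpha = y − mu`, candidates by `G_ct alpha`), and the
suite requires correlation > 0.99 between the two routes.

Chain settings: the reference analysis convention is 35,000 iterations,
5,000 burn-in, thinning 5 (`chain_control()` defaults). All desk-scale
work in this package uses `reduced_chains()` (2,000/500/5) or explicit
short chains around 1,500 iterations; with the diagonalized sampler the
stored-sample effective sizes (reported in `$diagnostics`) are ample for
posterior means of `g`, and the Gibbs-vs-BLUP test bounds the Monte-Carlo
error directly. Convergence is diagnosed (effective sample sizes via an
initial-sequence autocorrelation estimate) but never triggers automatic
re-runs.

### Numerical safeguards

* Eigenvalues of `G` in `(−1e-8 · trace, 0)` are clipped to zero; anything
  more negative is a hard error rather than a silent repair.
* A singular training system in the closed-form solver is an error; no
  hidden ridge is added.
* Zero phenotypic variance is caught: prior scales get a tiny floor, the
  genetic variance collapses toward zero, and predictions return the
  intercept (tested).

## Filtering and input

`apply_filters()` fixes an order the thresholds are applied in, because the
criteria themselves do not imply one: (1) chromosome whitelist; (2)
datapoints below the depth floor (default 2X) are set missing; (3) markers
with site-mean depth below 60X (over non-missing cells) are dropped; (4)
markers, then individuals, with more than 20% missing are dropped; (5)
markers with minor allele frequency below 0.05 are dropped. Counting
depth-missingness *before* the missing-fraction caps matches the intent of
the 2X rule — avoiding imputation — since cells that would need imputing
are what the caps then limit. Allele frequency is estimated as the mean of
per-individual read ratios (robust to depth differences between
individuals); a read-pooled estimator is available via `maf_method`.
Filtering is idempotent, which the suite asserts.

The thresholds can still leave a few missing cells (up to 20% per row and
column). The model needs a complete matrix, so `ratio_genotypes()`
mean-imputes those per marker as a last resort and reports the count; this
is a pragmatic compromise, flagged rather than hidden, and
`impute_missing = FALSE` turns it into an error.

Mapping- and variant-quality criteria act on fields that AO/RO tables no
longer carry; they are applied when input arrives as a VCF (`QUAL >= 10`,
`MQ >= 20`, biallelic records only, multiallelic records skipped and
counted) and assumed pre-applied otherwise — the `FilterReport`/VCF report
attributes say which.

## Depth downsampling

`downsample()` draws new totals `n' ~ Poisson(target)` truncated at
`min_depth = 2` — fresh draws, not thinning of the observed depth, because
the scenario specifies the new depth distribution directly — and splits
alleles as `AO' ~ Binomial(n', AO/(AO+RO))`. Re-splitting with the observed
ratio as success probability is the resampling model consistent with the
ratio parameterization itself (the ratio is the sufficient statistic the
pipeline carries forward); a hypergeometric subsample-without-replacement
mode exists behind `method = "hypergeometric"` for sensitivity checks at
targets below the input depth. Truncation semantics deserve a note: a
"minimum depth of two" could mean resampling until the draw is at least 2
(truncated Poisson — the default) or clamping smaller draws up to 2; the
two differ in the mass placed exactly at 2, both are implemented
(`truncation` argument of `simulate_read_counts()`), and the truncated
version is used throughout because clamping distorts the mean at low
targets.

## Resampling designs

* **Marker series** are cumulative: each size contains every smaller set,
  and per-chromosome counts stay within one of each other
  (`floor(size / n_chrom)` plus a randomly placed remainder, with the
  remainder chromosomes kept consistent across sizes so nesting and
  balance hold simultaneously — e.g. 500 over 12 chromosomes is always
  four 41s and eight 42s). An exhausted chromosome spills its shortfall
  with a warning.
* **Probe series** select probes at a fixed index stride along each
  chromosome with one random start per replicate per probe count, quotas
  proportional to per-chromosome probe counts (largest-remainder
  rounding). Stride sampling at different densities necessarily picks
  different positions, so probe series are *not* nested — fixed spacing
  and nesting are incompatible, and fixed spacing is the defining feature
  of this design. Whether starts should be shared across probe counts
  within a replicate was an open choice; they are drawn independently per
  count, which keeps each density's sample unconditionally uniform.
* **Test sets** (200 individuals, 5 replicates) are drawn once and shared
  across *every* factor within a replicate, so factor contrasts are never
  confounded with validation-set changes. A pseudo 5-fold: replicates are
  independent draws, not a partition.
* **Training series** are cumulative, random (shuffled-prefix) or
  family-based: families under 10 members are excluded (eligibility is
  decided on full pedigree family sizes, before test removal), level `k`
  takes `min(k, available)` per family after test individuals are removed.
  For the reference pedigree layout (103 eligible families of 1706), level
  6 yields exactly 618 trainees. Test sets are drawn from the whole
  population rather than within family boundaries — the simplest reading
  of a single shared test set, and the one that keeps test sets identical
  across composition schemes.

## What the generator emulates — and what it does not

`sim_study_population()` produces a breeding population with the structure
the analyses assume:

* **Map**: 12 chromosomes, even marker spread, position-contiguous probe
  groups of 18 markers (the observed mean markers-per-probe of capture
  panels this size), 100 cM and 50 Mb per chromosome by default.
* **Founders**: per-marker alternative-allele frequencies uniform in
  (0.1, 0.9); along chromosomes, haplotype alleles follow a first-order
  Markov chain with correlation `ld_rho = 0.3` per adjacent-marker step —
  a fast-decaying LD profile, consistent with a highly outcrossing
  species; the decay rate is a parameter, not an estimate.
* **Meiosis**: random bivalent pairing, Poisson(map length in Morgans)
  crossovers per bivalent at uniform positions, one recombinant chromatid
  transmitted per bivalent. At any single locus this gives the closed-form
  hypergeometric gamete law (2 of 4 homologs uniformly), which the suite
  checks by chi-squared at 10,000 draws. **No double reduction, no
  preferential pairing, no multivalents** — the standard autotetraploid
  baseline, chosen so the gamete law stays testable in closed form.
* **Pedigree**: biparental crosses; the `"study"` preset reproduces the
  reference population layout exactly (117 crosses, 146 parents, 1804
  offspring, 103 families of >= 10 totalling 1706). The family-size
  distribution beyond those totals is unknown; 58 families of 17, 45 of 16
  and 14 of 7 reproduce every reference total and is the fixed default.
* **Traits**: additive only. Presets span architectures — oligogenic (50
  QTL, h² = 0.7, signed-gamma effects), polygenic (500, 0.5, normal),
  infinitesimal (5000, 0.3) — with unitless scales, two seasons, and a
  fixed year shift. Residual variance is set so realized single-season
  heritability matches the target (asserted within 0.05 at n = 1000).
  Heritability targets are defined on the single-season scale; averaging
  two seasons halves the residual, which is why variance-recovery checks
  use single-season records.
* **Read counts**: truncated-Poisson totals, binomial allele split with a
  symmetric per-read miscall rate of 0.001 folded into the success
  probability.

Not emulated: dominance and epistasis, genotype-by-environment
interaction, selection across generations, linkage between family
structure and allele frequency (founders are unrelated), depth correlation
across markers within an individual (library-size effects), and
overdispersed depth distributions. Consequently, passing tests show the
*pipeline* behaves correctly under the stated stochastic models; they do
not certify predictive-ability values for any real population, where LD
structure, relatedness among parents and non-additive variance will move
the numbers.

## Problem sizes

Desk-scale defaults were chosen so every check runs comfortably on one
CPU: the demo population is 40 families × 15 = 600 individuals with 3,000
markers at 60X; grid experiments use 5 replicates with 200-individual test
sets; Gibbs chains in grids are 1,500–2,000 iterations. Variance recovery
uses 5 simulated populations of 600; the demo factorial is ~100 model fits
and completes in minutes. The `"study"` preset (1804 × ~10k) exists for
structure-faithful design computations and can be pushed through the same
grid when more time is available; `study_grid()` records the full-scale
factorial levels.

## The interface

The package's surface is its functions plus this vignette;
`scripts/acceptance.R` is the one shipped script, re-running the headline
computations end-to-end. A shell-level subcommand wrapper was considered
and dropped: every pipeline stage is a single R call on plain TSV/VCF
files, and an R analyst is the intended operator.

## Known limitations

* The Tukey comparison treats replicate-level predictive abilities as
  independent one-way samples; replicates share test sets across levels,
  so the pooled error is conservative (paired structure is ignored).
* Mean imputation of residual missing cells slightly shrinks marker
  variances; the imputed count is reported so users can judge.
* The Gibbs sampler assumes `G` is effectively low-noise; at 2X depth with
  few markers the relationship estimates themselves are noisy, and no
  depth-aware correction of `G` is applied — that correction is a known
  extension, deliberately out of scope.
* `fit_gibbs()` fits one trait at a time; multi-trait models, marker-
  specific shrinkage priors (Bayesian alphabets) and dominance terms are
  out of scope.
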