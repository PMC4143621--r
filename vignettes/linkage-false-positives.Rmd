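---
title: "Two-point linkage under null traits: models, simulation design, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-point linkage under null traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

linksim does two things: it computes exact two-point parametric LOD
scores on loop-free extended pedigrees, and it simulates whole studies
— pedigrees, dense markers, null traits — so that the family-wise
false-positive behavior of such scans can be measured under controlled
conditions. This vignette documents the models, the choices that were
genuinely open, and what the simulations do and do not show.

## The two-locus likelihood

Each individual carries an ordered pair of two-locus haplotypes
(paternal, maternal). A haplotype combines a trait-locus allele (d or
D) with a biallelic marker allele (major or minor), giving 4 haplotypes
and 16 ordered diplotype states. The pedigree likelihood is

* **founder prior** — product of haplotype frequencies assuming linkage
  equilibrium between trait locus and marker: the trait allele
  frequency `p_D` (default 0.01) times the marker's estimated minor
  allele frequency;
* **transmission** — a parent passes each of its haplotypes intact with
  probability `(1 - theta)/2` and each recombinant with `theta/2`,
  `theta` the (sex-averaged) recombination fraction;
* **penetrance** — affected individuals contribute
  `f(genotype at the trait locus)`, unaffected `1 - f`, unknown 1. The
  default dominant model is `f_dd = 0.05`, `f_Dd = f_DD = 0.5`;
* **marker observation** — an indicator of the observed minor-allele
  dosage (0/1/2), missing contributing 1.

The likelihood is evaluated by Elston–Stewart peeling, implemented as
sum–product message passing on the marriage graph: one factor per
mating connecting father, mother and their common children. On a
loop-free pedigree this graph is a tree, the computation is exact, and
it is linear in family size for the fixed 16-state space. The engine
refuses looped pedigrees; `detect_loops()` and `break_loops()`
(removal with cascading descendants, or duplication of an individual
with both parents and children present) prepare such families, the same
simple strategies a practitioner applies before running a classic
linkage program. Duplication knowingly double-counts one genome; for
null-rate estimation this approximation is acceptable, for power or
real-data analyses it is not.

The two-point LOD at `theta` is
`log10 L(theta) - log10 L(0.5)`, summed over families. At
`theta = 0.5` the joint likelihood factorizes into (trait-only) x
(marker-only); the implementation exploits this, computing the
marker-only denominator once per family per marker and the trait-only
term once per family per replicate. The scan default is `theta = 0`
(`zero_only` policy) — the natural scan when the causal variant itself
is expected among the genotyped markers; `grid_max` additionally
maximizes over the grid `{0, 0.001, 0.01, ..., 0.5}` with ties broken
toward 0 (within 1e-9, so numerically flat profiles report
`theta_hat = 0`).

**Verification.** `brute_force_log_likelihood()` enumerates all joint
diplotype assignments (restricted to states consistent with each
observed dosage, with a configurable cap) and is the independent ground
truth; the suite asserts agreement to relative error 1e-10 on 1,000
fuzzed pedigrees of up to 8 members, plus closed-form checks
(`n` phase-known fully-penetrant nonrecombinant meioses give
`LOD(0) = n log10 2`; one obligate recombinant gives `-Inf`).

## Numerical choices

Messages are rescaled to unit sum per marker, with the log10 scale
accumulated separately, so a 90-member family at MAF 0.0001 computes
without underflow; a likelihood that is exactly zero is reported as a
`-Inf` sentinel, which propagates to the family and total LOD and is
excluded from significance counting (it is evidence *against* linkage).
Marker data impossible under *any* `theta` (Mendelian inconsistency)
raise an error naming the family instead, because the gene-dropped
simulation can never produce them — in this pipeline they always
indicate a data-handling bug. The whole engine is vectorized across
markers (messages are 16 x M matrices), which is what makes
200-replicate calibration studies tractable in pure R.

## The synthetic study and its parameters

`sim_config()` holds every tunable. The defaults emulate the motivating
study system — a family WGS panel that is not publicly deposited — at
desk scale:

* `n_pedigrees = 20`, sizes 30–90, 4 generations: extended,
  multi-generation families built by forward simulation (2–5 children
  per couple, 75% of non-terminal children marry in a new founder).
  Loop-free by construction.
* `ungenotyped_fraction = 0.3`, founders 3x over-weighted: the emulated
  study completed its pedigrees with many ungenotyped (mostly founder)
  members, and founders-only MAF estimation must cope with that.
* markers: 70% rare (MAF uniform on (0.0005, 0.01]), 30% common
  ((0.01, 0.5]) — a rare-variant-heavy sequencing spectrum; spacing
  0.05 cM with Haldane's map function for intermarker recombination
  (the simplest standard choice; no interference, sex-averaged map, no
  genotyping error). `founder_haplotype_pool = K` draws founder
  haplotypes from a finite population pool per block of
  `ld_block_markers` consecutive markers, giving near-complete
  within-block LD for `K = 2`; the pool is shared across families so
  orientation is consistent study-wide. `K = 0` (default) gives
  independent markers.
* trait: heritability 0.68, mean `100 - 0.5 * age`, SD 15, drawn per
  family from a multivariate normal with covariance
  `sd^2 (h2 * 2 * Phi + (1 - h2) I)`, `Phi` the recursive kinship
  matrix. Only `h2` and the *sign* of the age slope matter to the study
  design; the mean model constants (100, -0.5/year, SD 15) are
  identifiable but otherwise arbitrary defaults.
* dichotomization: a single cutoff at the 20% quantile
  (linear-interpolation estimator, `quantile(type = 7)` — the common
  statistical default, fixed here because the rule's source does not
  name one) of founder values pooled across **all** generated
  replicates; strictly-smaller values are affected. Pooling uses
  whatever `n_replicates` is configured, and the cutoff is logged.
* complete null: affection drawn independently per individual per
  replicate at `prevalence = 0.10`.

Every stage draws from a seed derived only from
`(master seed, stage, index)` by a fixed integer rule (`stage_seed()`),
so replicate `r` is reproducible in isolation and the entire experiment
is a pure function of the config. Per-replicate parallelism would
therefore not change results, though the shipped driver is serial.

## Evaluation conventions

GWS is `total LOD >= 3.3` — boundary inclusive; suggestive is `> 1.9`.
Significant markers are profiled by family contributions:
`driver_1_2_suggestive` when 1–2 families individually exceed 1.9,
`diffuse` when no family exceeds 1.0 but 2–5 exceed 0.5, else `other`.
MAF strata are nested (floor ⊂ <0.01 ⊂ <0.05), with the 0.0001 floor
matched by exact equality. The FWER estimate across replicates carries
an exact Clopper–Pearson 95% interval (small counts are the norm here).
A cross-replicate report counts markers significant in exactly one
replicate; no acceptance value is attached to it because it depends
strongly on the marker panel.

## Problem sizes used in the checks

The shipped suite calibrates the complete-null scan on 200 replicates
of 10 pedigrees (~500 individuals) x 2,000 independent markers under
the default dominant model, asserting the per-scan FWER at LOD 3.3 does
not exceed 5% by more than 3 binomial standard errors. The
polygenic-vs-null contrast uses 50 paired replicates (identical
genotypes, 500 markers) and asserts the dichotomized-polygenic FWER is
not below the complete-null FWER (paired one-sided binomial test at
alpha 0.05). Heritability recovery doubles the age-adjusted full-sib
correlation over ~10,000+ pair observations; note that the
*per-replicate* sib correlation is biased low with few families
(grand-mean centering over a handful of correlated clusters), so the
estimator pools pairs across replicates, and its Monte-Carlo interval
is obtained by a delete-one-replicate jackknife.

## What passing these checks does and does not show

The generator reproduces the *mechanisms* that matter for null-rate
calibration — Mendelian transmission through extended pedigrees,
familial trait correlation without linkage, rare-variant-heavy panels,
missing founders — but not the scale (millions of variants) or the
texture of real sequence data (genotyping error, imputation artifacts,
long-range LD, population structure, ascertainment). Headline counts
from any real study of this kind are therefore qualitative context
only; at a few thousand markers both null traits yield very few GWS
hits, and the meaningful desk-scale claims are the calibration bound
and the *direction* of the polygenic inflation. Out of scope by
design: multipoint linkage, maximum-likelihood re-estimation of allele
frequencies with ungenotyped founders, genotype imputation,
covariate-adjusted or quantitative-trait linkage, X-linked and
age-dependent-penetrance models, and monozygotic-twin handling.
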