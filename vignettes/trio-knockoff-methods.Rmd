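---
title: "Knockoff-calibrated fine mapping in trio designs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knockoff-calibrated fine mapping in trio designs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triokf)
```

# The problem

In a region of strong linkage disequilibrium (LD), single-variant
family-based tests cannot tell a causal variant from its correlated
neighbours, and conservative family-wise corrections drain what little power
a trio collection has.  `triokf` implements a knockoff-calibrated,
multi-resolution burden scan for phased parent–offspring trios: synthetic
*knockoff* genotypes that preserve the LD structure but are conditionally
independent of the phenotype serve as negative controls, and a window is
declared associated only when its signal clearly exceeds what its knockoffs
achieve, with false discovery rate (FDR) control over the whole scan.

The package covers the full path from data to inference: a synthetic-cohort
generator with ground truth (so every stage is testable without access to
any real genotypes), phased VCF/PED input and quality control, LD-block
partitioning, trio-aware knockoff construction, the windowed LASSO-weighted
burden FBAT with knockoff FDR control, per-variant conditional-logistic
effect estimates, and an analytic + simulated power calculator for the
transmission disequilibrium test (TDT).

# The synthetic cohort

`build_haplotype_pool()` emulates a dense imputed panel in an isolated
founder population: by default 2,534 biallelic variants on chromosome 17
between 30,820,506 and 32,483,270 bp.  Founder haplotypes are mosaics of a
small number of *ancestral block haplotypes*.  Variants are grouped into
contiguous ancestry blocks (geometric lengths, mean 20 variants); each block
carries `n_ancestral = 12` ancestral haplotypes with stick-breaking
frequencies; a founder's mosaic path switches ancestral haplotype with
probability 0.005 per variant interval inside a block and 80 times that at
block boundaries.  Alternate alleles are assigned to a subset of ancestral
haplotypes whose frequency mass best matches a target MAF drawn from a
`1/f` spectrum on `[0.01, 0.5]`; within a block the carrier sets are nested
(one shared carrier order per block), which is what makes within-block
r² high while letting it decay across boundaries.  Variants whose realised
founder MAF escapes the bounds are resampled, with a direct allele-placement
fallback that guarantees the bounds at the cost of LD for that variant.
This mosaic model is a design choice: the emulation target is qualitative
(blockwise LD, a realistic MAF spectrum), not a coalescent-exact simulation,
and population stratification, imputation error and the X chromosome are out
of scope.

`simulate_trios()` draws each parent as a random pair of pool haplotypes and
forms offspring by Mendelian transmission with per-interval crossover
probability `1e-8` per bp (about 1 cM/Mb).  Phenotypes follow an
additive-logistic model, `P(affected) = plogis(intercept + sum(beta * g))`;
the default intercept corresponds to a 0.33% prevalence, the multiple
sclerosis prevalence reported for Sardinia.  Families are ascertained by
rejection sampling on the proband — the offspring for type 1 families
(study size 97), a parent for type 2 families (study size 60, the spouse
and child complete the trio; the child's phenotype is drawn, not forced) —
with a cap of 10,000 attempts per family.  Every accepted trio's
transmitted haplotype indices are recorded in a truth object, so
transmission inference and knockoff derivation can be checked against the
generating process, and identical seeds reproduce cohorts bit-exactly.

# Quality control

`apply_qc()` mirrors standard post-imputation filtering: founder minor
allele frequency (default `maf_min = 0.01`; the filter can be inverted with
`keep_rare = TRUE` for analyses that deliberately keep only rare variants),
a founder-only exact Hardy–Weinberg test (`hwe_p_min = 1e-6`), per-variant
missingness (max 0.01), and a Mendelian-error policy (default: set the
offending trio's genotypes at that variant to missing; `drop_variant` is
available).  Computing MAF and HWE on founders only is a deliberate choice:
offspring genotypes are deterministic functions of parental ones, and
including them distorts both statistics.  The HWE test is the exact
conditional test (heterozygote count given allele totals); it is verified
against an independent dynamic-programming enumeration for every
configuration with up to 30 alleles.

# LD blocks and transmission inference

`ld_r2_matrix()` computes haplotype r² from founder haplotype frequencies
inside a bp-limited band, and `partition_blocks()` forms contiguous blocks
by a greedy left-to-right rule: a variant joins the current block when its
r² with *any* block member reaches `r2_threshold = 0.5` within a span cap of
100 kb.  Greedy threshold blocks were chosen over Gabriel-style confidence
intervals because the block definition here only parameterises the knockoff
permutation strata — it needs to be deterministic, testable, and monotone in
its threshold, all of which are property-tested.  Monomorphic variants have
undefined r² (reported `NA`, never 0) and are forced into singleton blocks.

`infer_transmission()` assigns each offspring haplotype to a parent by
whole-trio consistency (the assignment minimising total allele mismatch
across blocks) and then, per parent and block, identifies the transmitted
parental haplotype as the one with fewer mismatches.  An exact tie is
flagged ambiguous; with error-free phased data a tie occurs precisely when
the parent's two block haplotypes are identical, so which index is recorded
cannot matter — a property the tests assert as an equivalence.

# Trio-aware knockoffs

`generate_parental_knockoffs()` instantiates residual permutation as a
sequential blockwise within-stratum permutation of *whole parents*.
Processing blocks left to right, parents are stratified by (their
block-`k-1` haplotypes in the knockoff built so far, their block-`k+1`
haplotypes in the original) and, crucially, by their own block-`k`
zygosity: homozygous-by-block parents (identical haplotype pair, zero
transmission contrast) exchange only with homozygous parents, heterozygous
with heterozygous.  Context strata smaller than `min_stratum_size = 10` are
merged with the stratum of most similar size, never across the zygosity
boundary.  Within each stratum the parents' block-`k` haplotype pairs are
permuted among parents.  `derive_knockoff_offspring()` then gives the
knockoff offspring, per parent and block, the knockoff parent's haplotype
at the *family's own* originally transmitted index; where that index is
unidentifiable (homozygous parent, flagged ambiguous) it is drawn uniformly
at random per copy.

Several implementation findings shaped this construction, and they are
worth recording because they are invisible in a high-level description:

* Keeping the family's own transmitted index while exchanging the content
  is what severs the genotype–phenotype link.  The tempting alternative —
  carrying the *donor's* transmitted haplotype, which makes the knockoff
  score an exact permutation of per-family residuals — fails under the
  alternative: permuting signal-carrying residuals among affected families
  leaves the sum, and hence the knockoff score, with the original signal,
  and causal windows are never selected.
* A *fixed* tie-break index for ambiguous transmissions under-disperses the
  knockoff scores: those entries contribute deterministic-sign terms whose
  permutation draws are negatively dependent, and the knockoff score
  variance falls measurably below 1.  Randomising the unidentifiable index
  restores it.
* Without the zygosity stratification, parents that contribute nothing to
  the original score (zero contrast) acquire non-zero contrasts in the
  knockoff and vice versa; the two scores then have different effective
  term counts and shapes, visible as a median `W` drifting above 1.1 on
  null data and as inflated false discovery proportions under signal.

With the final construction, `P(|Z| > |Z*|)` is 0.50 on independent null
replicates, the rank of `|Z|` among the eleven scores is uniform
(chi-square p of 0.27 and 0.06 in two pooled 50-cohort null experiments),
the null median `W` sits near 1.09, and per-block allele counts and
within-block r² are conserved exactly (the multiset of block haplotype
pairs is preserved).

# The windowed burden FBAT

`make_windows()` tiles the region at seven resolutions (500 to 20,000 bp),
each window overlapping its neighbour by half its size, with a final
tail window so every variant is covered at every size.  For each window,
`fit_burden_weights()` solves the LASSO problem
`argmin_b 0.5 * ||y - X b||^2 + lambda * ||b||_1` with `lambda` chosen by
5-fold cross-validation (seeded folds), falling back to equal weights
`1/sqrt(p)` with a flag when everything is shrunk to zero — under the null
that is the *common* case, and the fallback keeps every window testable.

The design matrix `X` is the *expected offspring dosage given the parents*,
`(g_father + g_mother)/2`, not the realised offspring genotypes.  This is a
deliberate deviation from the obvious choice: the realised offspring
genotype contains exactly the Mendelian transmission noise that the FBAT
measures, and weights fitted on it are tuned to that noise, inflating `|Z|`
relative to the knockoff scores and destroying their exchangeability (we
measured mean Z drifting positive and the knockoff comparison failing its
rank-uniformity check).  Parental expected dosages carry the between-family
association signal induced by ascertainment — enough to orient and weight
the burden — while being independent of the transmission noise under the
null.  The same weights are used for the original and every knockoff copy,
so the contrast is a pure genotype swap.

`fbat_burden_z()` computes, per trio, the burden `B = sum_j b_j x_j` of the
offspring, its exact conditional mean and variance given the phased parents
(each parent transmits either haplotype with probability 1/2,
independently), and the score
`Z = sum_i (y_i - mu)(B_i - E B_i) / sqrt(sum_i (y_i - mu)^2 Var B_i)`.
`y` is the offspring phenotype; affected parents are unproblematic because
the expectation conditions on parental genotypes.  The offset `mu` defaults
to 0, the classical choice for affected-proband designs: affected offspring
drive the score and unaffected offspring drop out.  Setting `mu` to the
in-sample offspring prevalence is possible (`mu = NULL`) but inadvisable in
ascertained mixed cohorts — the unaffected children of the affected-parent
families then enter with weight `(1 - mu)^2`, several times that of the
affected offspring, and their transmission noise swamps the signal (in a
worked simulation a causal variant's marginal TDT deviate of 4.1 collapsed
to 0.35 under the in-sample offset).  Windows
in which no trio is informative (`V = 0`) are reported with a missing
statistic, never `Z = 0`.  Duos are excluded: the conditional expectation
requires both parents.

Each window gets `W = |Z| / median_m |Z*_m|` and `p_burden = 2(1 -
Phi(|Z|))`.  Selection uses the multiple-knockoff statistic: `kappa` is the
index of the largest of the eleven absolute scores and `tau` the largest
minus the median of the rest; only `kappa = 0` windows are selectable, at
the smallest threshold whose estimated FDR
`((1 + #knockoff wins)/M) / #original wins` stays below the target.  The
`+1` numerator offset (the multiple-knockoff analogue of knockoff+) is a
deliberate departure from the plain count ratio: the uncorrected estimator
is anti-conservative under sparse signal — in pilot runs of the FDR
experiment its realised false discovery proportion was several times the
target — which is the textbook motivation for the knockoff+ correction.
The replicated FDR experiment in the test suite measures the controlled
behaviour directly.  `offset = 0` remains available.

Results are reported per window with no cross-resolution aggregation,
ranked by `W` and then `p_burden`; windows containing exactly the same
variants are computed once and shared across resolutions.

# Effect estimation

For each variant of interest, `estimate_effects()` uses trios with at least
one heterozygous parent and an affected offspring.  The affected offspring
genotype is the case; the three other transmitted/untransmitted
combinations of parental alleles are matched pseudo-controls (the 1:3
case–pseudo-control design; the genotype multiset is invariant to the
phase-ambiguous double-heterozygote assignment, so no phasing is needed).
The per-allele log odds ratio maximises the conditional likelihood (exact
stratified Cox form), with Wald intervals.  In the textbook single-SNP
situation — every informative trio has exactly one heterozygous parent —
the MLE collapses to the transmitted:untransmitted ratio, which the tests
assert exactly (7 transmissions vs 3 gives OR 7/3).  One-sided transmission
patterns are reported as infinite (or zero) odds ratios with a `separation`
status rather than an error.  Type 2 trios contribute only when the
offspring is affected, since the conditional likelihood conditions on
parental genotypes.

# TDT power

`conditional_mating_distribution()` enumerates parental genotypes (HWE at
the risk-allele frequency) and Mendelian transmissions, reweighted by the
offspring's relative risk of affection.  The `additive` model — the default
and the convention of family-study power tools — uses genotype relative
risks `1 : OR : 2*OR - 1`; `multiplicative` (`1 : OR : OR^2`) is available.
This parameterisation choice is the main lever on the printed power values
and was fixed by matching all five published values at once; under the
log-additive alternative the mid-frequency values are off by up to nine
percentage points, so the additive-risk reading is the one the analysis
uses.  With a supplied prevalence the baseline risk is solved exactly; the
default is the rare-disease limit, where the baseline cancels.

`tdt_power()` turns the conditional distribution into the expected number
of informative transmissions `m = 2 n h` (with `h` the probability a parent
is heterozygous given an affected offspring) and the transmission
probability `tau`, and approximates the TDT deviate as normal with mean
`sqrt(m)(2 tau - 1)` and standard deviation `sqrt(4 tau (1 - tau))` — the
classical TDT power approximation; using the alternative-hypothesis
variance rather than a unit variance is what makes the tail values match
the published table to a few tenths of a percentage point.
`tdt_power_simulated()` is the Monte-Carlo oracle: forward-simulated
ascertained trios at a single variant under a multiplicative-risk model
`P(aff|g) = baseline * grr_g`, where the baseline (default 0.05, chosen for
rejection-sampling efficiency) provably cancels from the conditional
distribution, so the simulation is exact for any baseline.

```{r power}
tdt_power_grid(n_trios = 142, alpha = 0.05)
```

# Validation design and what it does (and does not) show

Most checks in the test suite are oracle equivalences (exact enumeration
for HWE, the Mendelian mask, the FBAT score, block partitioning, the LASSO
soft threshold) or exact structural invariants (allele-count conservation,
Mendelian consistency of knockoff trios, seed determinism, round-trip I/O).
The statistical checks need more care, because a trio cohort over a short
region carries very little independent transmission randomness: with
negligible recombination each parent effectively transmits one haplotype
for the whole region, so *all* windows of one cohort share the same ~300
transmission coin flips, and their scores are strongly dependent.
Goodness-of-fit tests that assume independent windows will reject for any
valid construction when applied within one cohort.  The null-calibration
and rank-uniformity experiments therefore pool windows across independent
replicate cohorts (50 cohorts of 157 trios for the rank check; thinned,
deduplicated windows within each), keeping the per-cohort trio structure of
the study while making the test's sampling assumptions approximately valid.

The FDR experiment (100 replicate cohorts of 97 + 60 trios, four causal
variants at per-allele OR 3 among ~150 windows, q = 0.10, baseline risk 5%
for ascertainment tractability) scores truth at LD resolution: a selected
window counts as a true discovery when it contains a variant in LD with a
causal variant (founder r² > 0.2, the conventional proxy threshold) or from
the same ground-truth ancestry block.  A window holding a strong LD proxy
of the causal variant is statistically indistinguishable from it, and the
knockoff construction deliberately preserves within-block structure; with
strict contains-the-causal-SNP scoring the measured "FDR" conflates real
proxy associations with noise.

What passing these tests shows: the machinery is internally correct, the
knockoff negative controls are exchangeable with the originals under the
generator's null, FDR is controlled at LD-block resolution under the
generator's causal model, and the power calculator reproduces the published
analytic values.  What it does not show: robustness to phasing and
imputation error (inputs are assumed phased and complete), to population
stratification, or to LD patterns unlike the mosaic model; those are
properties of real data this generator does not emulate.

# Numerical and degenerate-input conventions

Monomorphic r² is `NA`, never 0.  `Z` with zero transmission variance is
`NA`, never 0.  Knockoff scores that are undefined are dropped from the `W`
median with a warning.  The HWE test returns 1 for monomorphic counts.
Ties in transmission inference go to haplotype 1 and are flagged.  LASSO
fold assignments, knockoff permutations (one independent stream per copy,
offset from the master seed) and the ambiguous-transmission draws are all
seeded, and every generator output is reproducible bit-for-bit from its
arguments and seed.  Problem sizes in the validation experiments (cohort
counts, SNP counts, replicate counts) are stated in the test files
themselves and were chosen as the smallest sizes at which the corresponding
check is statistically informative.
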