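# triokf

Knockoff-calibrated fine mapping for phased parent–offspring trio studies.

In a candidate region with strong linkage disequilibrium (LD), a
family-based test cannot tell a causal variant from its correlated
neighbours, and trio collections are usually too small to survive
family-wise error corrections. `triokf` addresses both problems with
*knockoff genotypes*: synthetic copies of the parental haplotypes that
preserve the region's LD structure but are conditionally independent of the
phenotype. Scanning the region with overlapping windows at several
resolutions, each window's burden association score is compared against the
scores of its own knockoffs, and windows are selected with false discovery
rate (FDR) control.

The package is aimed at statistical geneticists analysing affected-proband
trio designs (the motivating design mixes type 1 families — affected
offspring with both parents — and type 2 families — an affected parent,
spouse and child). It provides:

* a synthetic phased-cohort generator with blockwise LD, an
  additive-logistic disease model, affected-proband ascertainment and full
  ground-truth records (`build_haplotype_pool()`, `simulate_trios()`);
* phased VCF / 6-column PED input and output with Mendelian-error,
  exact Hardy–Weinberg and allele-frequency QC (`read_phased_vcf()`,
  `apply_qc()`);
* haplotype r² LD blocks (`cohort_ld_blocks()`), per-block transmission
  inference (`infer_transmission()`) and trio-aware knockoffs by
  within-stratum residual permutation (`make_knockoffs()`);
* the multi-resolution LASSO-weighted burden FBAT scan with
  multiple-knockoff FDR selection (`scan_cohort()`);
* per-variant odds ratios by 1:3 case/pseudo-control conditional logistic
  regression (`estimate_effects()`);
* analytic and simulated power of the transmission disequilibrium test
  (TDT) over a MAF × OR grid (`tdt_power()`, `tdt_power_grid()`,
  `tdt_power_simulated()`).

## The statistics in brief

For a window with member variants `j` and burden weights `b` (LASSO with
cross-validated L1 penalty, equal weights as fallback), each trio
contributes the offspring burden `B_i = Σ_j b_j x_ij`. Conditional on the
phased parents, each parent transmits either haplotype with probability
1/2, giving an exact mean `E[B_i]` and variance `Var[B_i]`; the score is

    Z = Σ_i (y_i − μ)(B_i − E[B_i]) / sqrt( Σ_i (y_i − μ)² Var[B_i] )

with `y` the offspring phenotype and offset `μ = 0` (affected offspring
drive the test). Each of `M = 10` knockoff copies yields a `Z*_m` from the
same weights; the window statistic is `W = |Z| / median_m |Z*_m|`, and
selection uses the multiple-knockoff κ/τ filter with a knockoff+ style
offset: a window is selected only when its original score beats all its
knockoffs and the estimated FDR at its threshold is below the target.

Power for the allelic TDT is computed from the conditional distribution of
parental genotypes and transmissions given an affected offspring under
additive genotype relative risks `1 : OR : 2·OR − 1`, with the normal
approximation `Z_TDT ~ N(√m(2τ−1), 4τ(1−τ))`, `m` the expected number of
heterozygous-parent transmissions and `τ = P(transmit risk allele)`.

## Worked example

Simulate a study-sized cohort (97 type 1 + 60 type 2 trios, 120 SNPs over
80 kb) with one causal variant at per-allele OR 3, run QC and the knockoff
scan, and estimate per-variant effects:

```r
library(triokf)

pool  <- build_haplotype_pool(n_founders = 300, n_variants = 120,
                              region_end = 30900506, seed = 1)
model <- disease_model(intercept = qlogis(0.05),
                       effects = c("60" = log(3)))
sim   <- simulate_trios(pool, n_type1 = 97, n_type2 = 60,
                        model = model, seed = 2)

qc   <- apply_qc(sim$cohort)
scan <- scan_cohort(qc$cohort, sizes = c(1000, 2000), M = 10,
                    q_target = 0.10, seed = 3)
glance(scan)
head(tidy(scan)[, c("start", "end", "size", "n", "dir", "W", "Z",
                    "p_burden", "q", "selected")], 3)
```

```
# A tibble: 1 × 6
  n_windows n_selected     M q_target median_W min_p_burden
      <int>      <int> <dbl>    <dbl>    <dbl>        <dbl>
1       194         30    10      0.1     1.08    0.0000243

     start      end size n dir    W    Z p_burden       q selected
1 30843868 30844867 1000 1   1 7.00 4.22 2.43e-05 0.00476     TRUE
2 30851868 30852867 1000 1   1 6.50 4.11 3.94e-05 0.00476     TRUE
3 30852368 30853367 1000 3   1 6.50 4.11 3.94e-05 0.00476     TRUE
```

The top-ranked windows (largest `W`, smallest burden p-value) land on the
causal variant's LD neighbourhood: every variant they contain has r² of
0.9–1.0 with the causal variant at position 30,851,434, and their
transmission signals (Z ≈ 4.1–4.2) stand far above their knockoff scores
(per-window q ≈ 0.005). That is the resolution limit fine mapping can
reach: perfect LD proxies are statistically indistinguishable from the
causal variant itself. A per-variant effect estimate separates the causal
variant (true per-allele OR 3) from an uncorrelated neighbour:

```r
estimate_effects(qc$cohort, c("var0060", "var0061"))
```

```
  variant n_informative n_used   or ci_lo ci_hi        p status
1 var0060            54     36 4.71  2.09 10.66 0.000194     ok
2 var0061           102     62 1.14  0.73  1.77 0.574002     ok
```

and the analytic TDT power for the study's design (142 trios, α = 0.05):

```r
tdt_power_grid(n_trios = 142, alpha = 0.05)
#    maf  or  power      e.g. 7.7% at MAF 0.05 / OR 1.2,
#   0.05 1.2 0.0767      44.6% at MAF 0.05 / OR 1.9,
#   0.30 1.9 0.8639      86.4% at MAF 0.30 / OR 1.9,
#   0.05 3.0 0.9322      93.2% at MAF 0.05 / OR 3.0.
```

`autoplot(scan)` draws `W` along the region per window size;
`autoplot(tdt_power_grid())` draws the power curves. A thin command-line
front end over the same functions lives at
`inst/scripts/triokf-cli.R` (subcommands `simulate`, `qc`, `scan`,
`estimate`, `power`).

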