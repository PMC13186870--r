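test_that("realised founder MAFs respect the configured bounds", {
  pool <- build_haplotype_pool(n_founders = 1000, n_variants = 150,
                               region_end = 30820506 + 1e5,
                               maf_min = 0.05, maf_max = 0.5, seed = 11)
  freq <- colMeans(pool$haplotypes)
  maf <- pmin(freq, 1 - freq)
  expect_true(all(maf >= 0.05 - 1e-12))
  expect_true(all(maf <= 0.5 + 1e-12))
})

test_that("without recombination every founder equals one ancestral haplotype", {
  pool <- build_haplotype_pool(n_founders = 40, n_variants = 25,
                               region_end = 30830506,
                               n_ancestral = 2, recomb_prob_per_interval = 0,
                               maf_min = 0.05, seed = 7)
  poly <- which(apply(pool$haplotypes, 2, function(x) length(unique(x)) > 1))
  r2 <- ld_r2_matrix(pool$haplotypes[, poly, drop = FALSE],
                     pool$variants$pos[poly])
  expect_true(all(abs(r2$r2 - 1) < 1e-12))
  expect_lte(nrow(unique(as.data.frame(pool$haplotypes))), 2L)
})

test_that("pool and cohort generation are seed-deterministic", {
  p1 <- small_pool(n_founders = 50, n_variants = 30, seed = 5)
  p2 <- small_pool(n_founders = 50, n_variants = 30, seed = 5)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_identical(p1$variants, p2$variants)
  s1 <- simulate_trios(p1, n_type1 = 8, n_type2 = 4, seed = 9)
  s2 <- simulate_trios(p2, n_type1 = 8, n_type2 = 4, seed = 9)
  expect_identical(s1$cohort$haplotypes, s2$cohort$haplotypes)
  expect_identical(s1$cohort$individuals, s2$cohort$individuals)
  expect_identical(s1$truth$transmitted_father, s2$truth$transmitted_father)
})

test_that("study-sized cohort has the expected structure and probands", {
  pool <- small_pool(n_founders = 300, n_variants = 60, seed = 13)
  sim <- simulate_trios(pool, n_type1 = 97, n_type2 = 60, seed = 13)
  co <- sim$cohort
  expect_equal(nrow(co$pedigree), 157L)
  expect_equal(sum(co$pedigree$trio_type == 1L), 97L)
  expect_equal(sum(co$pedigree$trio_type == 2L), 60L)
  phe <- phenotype_of(co, co$pedigree$proband)
  expect_true(all(phe == 1))
  t1 <- co$pedigree[co$pedigree$trio_type == 1L, ]
  expect_true(all(t1$proband == t1$offspring))
  t2 <- co$pedigree[co$pedigree$trio_type == 2L, ]
  expect_true(all(t2$proband %in% c(t2$father, t2$mother)))
})

test_that("generated trios contain no Mendelian errors", {
  sim <- small_cohort(n_type1 = 25, n_type2 = 10, seed = 21)
  me <- mendelian_error_mask(sim$cohort)
  expect_equal(sum(me$mask), 0L)
})

test_that("ground-truth transmissions replay to the offspring haplotypes", {
  pool <- small_pool(n_founders = 80, n_variants = 40, seed = 31)
  sim <- simulate_trios(pool, n_type1 = 10, n_type2 = 5, seed = 31)
  co <- sim$cohort
  tru <- sim$truth
  for (i in seq_len(nrow(co$pedigree))) {
    ped <- co$pedigree[i, ]
    fa <- co$haplotypes[hap_rows_for_test(co, ped$father), , drop = FALSE]
    off <- co$haplotypes[hap_rows_for_test(co, ped$offspring), , drop = FALSE]
    path <- tru$transmitted_father[i, ]
    expect_identical(off[1L, ], fa[cbind(path, seq_along(path))][seq_along(path)])
  }
})

test_that("null-model transmission from heterozygous parents is fair and the TDT is chi-square calibrated", {
  # near-independent variants (high recombination) so per-SNP TDT statistics
  # are approximately iid under the null
  pool <- build_haplotype_pool(n_founders = 400, n_variants = 500,
                               region_end = 30820506 + 5e5,
                               recomb_prob_per_interval = 0.5,
                               maf_min = 0.05, seed = 41)
  sim <- simulate_trios(pool, n_type1 = 97, n_type2 = 60, seed = 41)
  co <- sim$cohort
  ped <- co$pedigree
  g <- genotype_matrix(co)
  gf <- g[ped$father, , drop = FALSE]
  gm <- g[ped$mother, , drop = FALSE]
  gc <- g[ped$offspring, , drop = FALSE]
  # transmitted allele from a het father is gc - t_m; count only trios
  # where the other parent is homozygous so the transmission is determined
  det_f <- gf == 1L & gm != 1L
  tr_f <- (gc - gm / 2L)[det_f]
  det_m <- gm == 1L & gf != 1L
  tr_m <- (gc - gf / 2L)[det_m]
  trans <- c(tr_f, tr_m)
  expect_true(all(trans %in% 0:1))
  rate <- mean(trans)
  se <- sqrt(0.25 / length(trans))
  expect_lt(abs(rate - 0.5), 4 * se)

  # per-SNP TDT vs chi-square(1)
  b <- colSums(det_f * (gc - gm / 2L), na.rm = TRUE) +
    colSums(det_m * (gc - gf / 2L), na.rm = TRUE)
  m <- colSums(det_f) + colSums(det_m)
  stat <- ifelse(m > 0, (2 * b - m)^2 / m, NA_real_)
  ks <- suppressWarnings(stats::ks.test(stat[m > 20], function(q)
    pchisq(q, df = 1)))
  expect_gt(ks$p.value, 0.01)
})

test_that("a causal allele is over-transmitted at the multiplicative closed-form rate", {
  # per-allele OR 3 at one SNP: transmission rate from het parents to
  # affected offspring approaches 3/(1+3) = 0.75
  pool <- build_haplotype_pool(n_founders = 500, n_variants = 1,
                               region_end = 30830506,
                               maf_min = 0.19, maf_max = 0.21, seed = 51)
  model <- disease_model(intercept = qlogis(0.01),
                         effects = c("1" = log(3)))
  sim <- simulate_trios(pool, n_type1 = 500, n_type2 = 0, model = model,
                        seed = 51)
  g <- genotype_matrix(sim$cohort)
  ped <- sim$cohort$pedigree
  gf <- g[ped$father, 1L]; gm <- g[ped$mother, 1L]; gc <- g[ped$offspring, 1L]
  det_f <- gf == 1L & gm != 1L
  det_m <- gm == 1L & gf != 1L
  trans <- c((gc - gm / 2L)[det_f], (gc - gf / 2L)[det_m])
  rate <- mean(trans)
  se <- sqrt(rate * (1 - rate) / length(trans))
  expect_lt(abs(rate - 0.75), 3 * se + 0.01)
})

test_that("ascertainment failure raises a diagnostic error", {
  pool <- small_pool(n_founders = 50, n_variants = 10, seed = 61)
  model <- disease_model(intercept = -30)
  expect_error(
    simulate_trios(pool, n_type1 = 2, n_type2 = 0, model = model,
                   max_attempts = 50L, seed = 61),
    "ascertainment"
  )
})

test_that("infeasible pool configuration errors out", {
  expect_error(build_haplotype_pool(n_founders = 10, n_variants = 5,
                                    maf_min = 0.6, seed = 1),
               "MAF bounds")
  expect_error(build_haplotype_pool(n_founders = 2, n_variants = 5, seed = 1),
               "n_founders")
})
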