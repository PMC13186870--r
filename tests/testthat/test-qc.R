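test_that("Mendelian mask agrees with brute-force enumeration on all 27 triples", {
  triples <- expand.grid(gf = 0:2, gm = 0:2, gc = 0:2)
  got <- mapply(function(gf, gm, gc) {
    triokf:::mendel_incompatible(gf, gm, gc)
  }, triples$gf, triples$gm, triples$gc)
  want <- !mapply(mendel_oracle_ok, triples$gf, triples$gm, triples$gc)
  expect_equal(unname(got), unname(want))
})

test_that("Mendelian mask flags the textbook cases and spares missing data", {
  # parents AA x AA with het child: error; AA x aa with het child: fine
  expect_true(triokf:::mendel_incompatible(0L, 0L, 1L))
  expect_false(triokf:::mendel_incompatible(0L, 2L, 1L))
  expect_false(triokf:::mendel_incompatible(NA_integer_, 1L, 2L))  # duo-ok
  expect_true(triokf:::mendel_incompatible(NA_integer_, 0L, 2L))   # obligate
  expect_true(triokf:::mendel_incompatible(NA_integer_, 2L, 0L))
  expect_false(triokf:::mendel_incompatible(0L, NA_integer_, NA_integer_))
})

test_that("HWE exact test equals the DP-enumeration oracle on small tables", {
  cases <- list(c(2, 2, 2), c(5, 1, 1), c(0, 3, 4), c(1, 0, 6), c(3, 3, 0),
                c(7, 7, 1), c(4, 0, 4))
  for (cs in cases) {
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 hwe_oracle_p(cs[1], cs[2], cs[3]),
                 tolerance = 1e-10)
  }
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 7), 1)
})

test_that("HWE p-values are super-uniform under the null", {
  set.seed(101)
  n <- 120L
  p_vals <- replicate(1000L, {
    maf <- runif(1, 0.05, 0.5)
    g <- rbinom(n, 2L, maf)
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  })
  # empirical CDF below the diagonal plus a DKW band at alpha = 0.01
  grid <- seq(0.01, 1, by = 0.01)
  ecdf_vals <- vapply(grid, function(t) mean(p_vals <= t), numeric(1))
  band <- sqrt(log(2 / 0.01) / (2 * 1000))
  expect_true(all(ecdf_vals <= grid + band))
})

test_that("QC removes variants for the documented reasons", {
  sim <- small_cohort(n_type1 = 25, n_type2 = 10, seed = 91,
                      pool = small_pool(n_founders = 150, n_variants = 40,
                                        maf_min = 0.05, seed = 91))
  co <- sim$cohort
  # force variant 1 rare among founders: drop nearly all alt alleles
  fnd <- founder_ids(co)
  rows <- unlist(lapply(fnd, hap_rows_for_test, cohort = co))
  co$haplotypes[rows, 1L] <- 0L
  co$haplotypes[rows[1L], 1L] <- 1L
  # force 5% missingness at variant 2 across individuals
  n_ind <- nrow(co$individuals)
  miss_ind <- seq_len(ceiling(0.05 * n_ind))
  for (k in miss_ind) co$haplotypes[c(2 * k - 1, 2 * k), 2L] <- NA_integer_
  qc <- apply_qc(co)
  expect_false(qc$report$pass[1L])
  expect_equal(qc$report$reason[1L], "maf")
  expect_false(qc$report$pass[2L])
  expect_equal(qc$report$reason[2L], "missing")
  expect_equal(sum(!qc$report$pass), 2L)
  expect_equal(nrow(qc$cohort$variants), 38L)
})

test_that("QC at extreme thresholds is the identity and QC is idempotent", {
  sim <- small_cohort(n_type1 = 15, n_type2 = 8, seed = 95,
                      pool = small_pool(n_founders = 100, n_variants = 30,
                                        maf_min = 0.05, seed = 95))
  co <- sim$cohort
  qc0 <- apply_qc(co, hwe_p_min = 0, maf_min = 0, max_missing_rate = 1)
  expect_identical(qc0$cohort$haplotypes, co$haplotypes)
  expect_true(all(qc0$report$pass))

  co2 <- inject_missingness(co, 0.03, seed = 96)
  qc1 <- apply_qc(co2, max_missing_rate = 0.2)
  qc2 <- apply_qc(qc1$cohort, max_missing_rate = 0.2)
  expect_identical(qc1$cohort$haplotypes, qc2$cohort$haplotypes)
  expect_identical(qc1$cohort$pedigree, qc2$cohort$pedigree)
})

test_that("keep_rare inverts the MAF filter", {
  sim <- small_cohort(n_type1 = 15, n_type2 = 0, seed = 97,
                      pool = small_pool(n_founders = 100, n_variants = 30,
                                        seed = 97))
  qc_common <- apply_qc(sim$cohort, maf_min = 0.2, hwe_p_min = 0)
  qc_rare <- try(apply_qc(sim$cohort, maf_min = 0.2, hwe_p_min = 0,
                          keep_rare = TRUE), silent = TRUE)
  if (!inherits(qc_rare, "try-error")) {
    expect_equal(sort(c(qc_common$cohort$variants$id,
                        qc_rare$cohort$variants$id)),
                 sort(sim$cohort$variants$id))
  } else {
    expect_true(all(qc_common$report$pass))
  }
})

test_that("Mendelian zero-out policy sets the trio genotypes to missing", {
  sim <- small_cohort(n_type1 = 10, n_type2 = 0, seed = 99,
                      pool = small_pool(n_founders = 60, n_variants = 12,
                                        maf_min = 0.1, seed = 99))
  co <- sim$cohort
  # corrupt one offspring genotype into a Mendelian error
  ped <- co$pedigree[1L, ]
  fr <- hap_rows_for_test(co, ped$father)
  mr <- hap_rows_for_test(co, ped$mother)
  or <- hap_rows_for_test(co, ped$offspring)
  co$haplotypes[c(fr, mr), 3L] <- 0L   # both parents hom-ref
  co$haplotypes[or, 3L] <- 1L          # child hom-alt: impossible
  me <- mendelian_error_mask(co)
  expect_equal(unname(me$per_variant[3L]), 1L)
  qc <- apply_qc(co, max_missing_rate = 1)
  expect_true(all(is.na(qc$cohort$haplotypes[c(fr, mr, or), 3L])))
  qc_drop <- apply_qc(co, mendel_policy = "drop_variant", max_missing_rate = 1)
  expect_equal(qc_drop$report$reason[3L], "mendel")
})
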