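# enumeration oracle for the burden FBAT: E[B] and Var[B] per trio by
# explicit enumeration of the four equiprobable transmission combinations
fbat_oracle <- function(fa, mo, off, y, b, mu) {
  U <- 0; V <- 0
  for (i in seq_along(fa)) {
    burdens <- c()
    for (tf in 1:2) for (tm in 1:2) {
      burdens <- c(burdens, sum(b * (fa[[i]][tf, ] + mo[[i]][tm, ])))
    }
    E <- mean(burdens)
    Vi <- mean((burdens - E)^2)
    B <- sum(b * (off[[i]][1, ] + off[[i]][2, ]))
    U <- U + (y[i] - mu) * (B - E)
    V <- V + (y[i] - mu)^2 * Vi
  }
  if (V <= 0) return(NA_real_)
  U / sqrt(V)
}

four_trio_cohort <- function() {
  # 2-variant window; a mix of het and hom parents, affected and
  # unaffected offspring
  fa <- list(rbind(c(1L, 0L), c(0L, 0L)), rbind(c(1L, 1L), c(0L, 1L)),
             rbind(c(0L, 0L), c(0L, 0L)), rbind(c(1L, 0L), c(1L, 1L)))
  mo <- list(rbind(c(0L, 1L), c(0L, 0L)), rbind(c(1L, 0L), c(1L, 0L)),
             rbind(c(0L, 1L), c(1L, 0L)), rbind(c(0L, 0L), c(0L, 0L)))
  off <- list(rbind(fa[[1]][1, ], mo[[1]][2, ]),
              rbind(fa[[2]][2, ], mo[[2]][1, ]),
              rbind(fa[[3]][1, ], mo[[3]][1, ]),
              rbind(fa[[4]][2, ], mo[[4]][2, ]))
  y <- c(1, 1, 0, 1)
  haps <- list(); phen <- c(); ped <- list()
  for (i in 1:4) {
    haps[[paste0("fa", i)]] <- fa[[i]]
    haps[[paste0("mo", i)]] <- mo[[i]]
    haps[[paste0("of", i)]] <- off[[i]]
    phen[paste0("fa", i)] <- 0
    phen[paste0("mo", i)] <- 0
    phen[paste0("of", i)] <- y[i]
    ped[[i]] <- tibble::tibble(trio_id = paste0("T", i), trio_type = 1L,
                               father = paste0("fa", i),
                               mother = paste0("mo", i),
                               offspring = paste0("of", i),
                               proband = paste0("of", i))
  }
  list(cohort = manual_cohort(haps, phen, dplyr::bind_rows(ped)),
       fa = fa, mo = mo, off = off, y = y)
}

test_that("burden FBAT matches the exhaustive transmission-enumeration oracle", {
  fx <- four_trio_cohort()
  for (b in list(c(1, 1), c(0.3, -0.8), c(2, 0))) {
    for (mu in c(0, 0.25)) {
      got <- fbat_burden_z(fx$cohort$haplotypes, fx$cohort, 1:2, b, mu = mu)
      want <- fbat_oracle(fx$fa, fx$mo, fx$off, fx$y, b, mu)
      expect_equal(got$Z, want, tolerance = 1e-12)
    }
  }
})

test_that("FBAT sign, degenerate-variance and scale-invariance behaviour", {
  # one trio: het father transmits the alt allele, affected offspring
  haps <- list(fa = rbind(c(1L), c(0L)), mo = rbind(c(0L), c(0L)),
               of = rbind(c(1L), c(0L)))
  ped <- tibble::tibble(trio_id = "T1", trio_type = 1L, father = "fa",
                        mother = "mo", offspring = "of", proband = "of")
  co <- manual_cohort(haps, c(fa = 0, mo = 0, of = 1), ped)
  z <- fbat_burden_z(co$haplotypes, co, 1L, 1, mu = 0)
  expect_gt(z$Z, 0)
  expect_equal(z$dir, 1)

  # both parents homozygous everywhere: V = 0 -> undefined, not zero
  haps2 <- list(fa = rbind(c(1L), c(1L)), mo = rbind(c(0L), c(0L)),
                of = rbind(c(1L), c(0L)))
  co2 <- manual_cohort(haps2, c(fa = 0, mo = 0, of = 1), ped)
  z2 <- fbat_burden_z(co2$haplotypes, co2, 1L, 1, mu = 0)
  expect_true(is.na(z2$Z))

  # scaling the weights leaves Z unchanged
  fx <- four_trio_cohort()
  z_a <- fbat_burden_z(fx$cohort$haplotypes, fx$cohort, 1:2, c(0.4, 1.1),
                       mu = 0)
  z_b <- fbat_burden_z(fx$cohort$haplotypes, fx$cohort, 1:2,
                       7.3 * c(0.4, 1.1), mu = 0)
  expect_equal(z_a$Z, z_b$Z, tolerance = 1e-12)
})

test_that("Z-to-p conversion is the two-sided normal tail", {
  expect_equal(z_to_p(0), 1)
  expect_equal(z_to_p(1.959964), 0.05, tolerance = 1e-6)
  expect_equal(z_to_p(-2.5), z_to_p(2.5))
})

test_that("half-overlapping windows reproduce the published region tiling", {
  pos <- seq(30820506, 30880000, by = 400)
  w <- make_windows(30820506, 30880000, pos, sizes = c(500, 1000))
  w500 <- w[w$size == 500, ]
  # the top-ranked 500 bp window of the study region tiling
  expect_true(any(w500$start == 30821006 & w500$end == 30821505))
  w1000 <- w[w$size == 1000, ]
  expect_equal(w1000$start[1], 30820506)
  expect_equal(w1000$end[1], 30821505)
  # half overlap in the regular tiling (a final tail window may be closer)
  expect_equal(unique(diff(w500$start[-length(w500$start)])), 250)
  # every variant is covered by at least one window per size
  for (s in c(500, 1000)) {
    cov <- unique(unlist(w$variant_idx[w$size == s]))
    expect_setequal(cov, seq_along(pos))
  }
})

test_that("degenerate regions yield a single or clipped window", {
  pos <- c(1000L, 1200L)
  w <- make_windows(1000, 1499, pos, sizes = 500)
  expect_equal(nrow(w), 1L)
  expect_false(w$clipped)
  w2 <- make_windows(1000, 1299, pos, sizes = 500)
  expect_equal(nrow(w2), 1L)
  expect_true(w2$clipped)
  expect_equal(w2$end, 1299)
})

test_that("LASSO weights obey the soft-threshold closed form and the shrinkage limit", {
  set.seed(33)
  n <- 40
  # orthogonal two-column design
  x1 <- rep(c(1, -1), n / 2)
  x2 <- rep(c(1, 1, -1, -1), n / 4)
  X <- cbind(x1, x2)
  y <- 0.8 * x1 - 0.3 * x2 + rnorm(n, sd = 0.4)
  lam <- 6
  w <- fit_burden_weights(X, y, lambda_policy = lam)
  yc <- y - mean(y)
  soft <- function(z, l) sign(z) * pmax(abs(z) - l, 0)
  want <- c(soft(sum(x1 * yc), lam) / sum(x1^2),
            soft(sum(x2 * yc), lam) / sum(x2^2))
  expect_equal(w$b, want, tolerance = 1e-6)

  # lambda -> infinity: all zero -> equal-weight fallback with flag
  w_inf <- fit_burden_weights(X, y, lambda_policy = 1e6)
  expect_true(w_inf$fallback)
  expect_equal(w_inf$b, rep(1 / sqrt(2), 2))

  # constant phenotype: fallback with warning
  expect_warning(w_const <- fit_burden_weights(X, rep(1, n)), "constant")
  expect_true(w_const$fallback)

  # single-variant window: sign and scale of the soft-thresholded
  # univariate coefficient
  xs <- rbinom(n, 2, 0.4)
  ys <- 0.5 * xs + rnorm(n, sd = 0.8)
  w1 <- fit_burden_weights(matrix(xs), ys, lambda_policy = 2)
  xc <- xs - mean(xs)
  expect_equal(w1$b, soft(sum(xc * (ys - mean(ys))), 2) / sum(xc^2),
               tolerance = 1e-9)
})

test_that("W statistic follows the median-ratio definition", {
  expect_equal(window_statistic(2.5, rep(2.5, 10))$W, 1)
  expect_equal(window_statistic(3, c(1, 1.5, 2))$W, 2)
  expect_equal(window_statistic(-3, c(1, -1.5, 2))$W, 2)
  expect_warning(st <- window_statistic(3, c(1.5, NA)), "dropped")
  expect_equal(st$W, 2)
  expect_true(is.na(window_statistic(3, c(0, 0, 0))$W))
  expect_true(is.na(window_statistic(NA_real_, c(1, 2))$W))
})

test_that("multiple-knockoff filter selects a clear signal and controls the trivial cases", {
  M <- 10
  set.seed(44)
  n_null <- 40
  null_z <- rnorm(n_null, sd = 0.6)
  null_star <- matrix(rnorm(n_null * M, sd = 0.6), n_null)
  res <- tibble::tibble(
    Z = c(10, null_z),
    Zstar = c(list(runif(M, 0, 1)),
              lapply(seq_len(n_null), function(i) null_star[i, ]))
  )
  out <- knockoff_fdr_select(res, q_target = 0.10)
  expect_true(out$selected[1])
  expect_equal(out$kappa[1], 0L)
  expect_lte(out$q[1], 0.10)
  # without the knockoff+ offset the window clears q = 0.05 as well
  out0 <- knockoff_fdr_select(res, q_target = 0.05, offset = 0)
  expect_true(out0$selected[1])
  expect_lte(out0$q[1], 0.05)
  # the clear signal dominates: it has the largest tau among selections
  expect_equal(which.max(replace(out$tau, out$kappa != 0, -Inf)), 1L)

  # every original strictly below its knockoffs: empty selection
  res2 <- tibble::tibble(
    Z = rep(0.1, 5),
    Zstar = lapply(1:5, function(i) seq(0.5, 1.5, length.out = M))
  )
  out2 <- knockoff_fdr_select(res2, q_target = 0.2)
  expect_equal(sum(out2$selected), 0L)
})

test_that("null window scores are standard-normal calibrated and the median W is near 1", {
  # windows within one cohort share parental transmissions (essentially one
  # meiosis per parent over a short region), so they are far from
  # independent; the calibration is therefore checked on windows pooled
  # across independent replicate cohorts
  z_all <- c(); w_all <- c()
  for (s in 1:36) {
    pool <- build_haplotype_pool(n_founders = 200, n_variants = 40,
                                 region_end = 30820506 + 27000,
                                 maf_min = 0.05, seed = 210 + s)
    sim <- simulate_trios(pool, n_type1 = 30, n_type2 = 18, seed = 250 + s)
    sc <- suppressWarnings(
      scan_cohort(sim$cohort, sizes = c(1000, 2000), M = 10, seed = 300 + s)
    )
    z_all <- c(z_all, sc$Z)
    w_all <- c(w_all, sc$W)
    if (s == 1L) {
      # ranking is by W then p_burden
      wfilled <- replace(sc$W, is.na(sc$W), -Inf)
      expect_true(all(diff(wfilled) <= 1e-12))
    }
  }
  z <- z_all[!is.na(z_all)]
  expect_gte(length(z), 500)
  expect_lt(abs(mean(z)), 0.1)
  expect_gt(stats::var(z), 0.8)
  expect_lt(stats::var(z), 1.2)
  expect_gt(median(w_all, na.rm = TRUE), 0.9)
  expect_lt(median(w_all, na.rm = TRUE), 1.1)
})
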