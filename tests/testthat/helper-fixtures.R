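# shared fixtures and independent oracles, all generated in code

small_pool <- function(n_founders = 200, n_variants = 120, seed = 3,
                       span = 80000, ...) {
  build_haplotype_pool(n_founders = n_founders, n_variants = n_variants,
                       region_end = 30820506 + span, seed = seed, ...)
}

small_cohort <- function(n_type1 = 30, n_type2 = 15, seed = 4, pool = NULL,
                         ...) {
  if (is.null(pool)) pool <- small_pool()
  simulate_trios(pool, n_type1 = n_type1, n_type2 = n_type2, seed = seed, ...)
}

# hand-built cohort: explicit haplotypes, one row per individual pair
manual_cohort <- function(hap_list, phenotypes, trio_defs, positions = NULL) {
  ids <- names(hap_list)
  haps <- do.call(rbind, hap_list)
  V <- ncol(haps)
  if (is.null(positions)) positions <- seq_len(V) * 1000L + 30820506L
  variants <- tibble::tibble(id = paste0("v", seq_len(V)), chrom = "17",
                             pos = as.integer(positions),
                             ref = "A", alt = "G")
  individuals <- tibble::tibble(id = ids, sex = 0L,
                                phenotype = phenotypes[ids])
  new_cohort(haps, variants, individuals, trio_defs)
}

# exact het-count distribution by dynamic-programming enumeration over
# individuals: an independent route to the conditional HWE null
hwe_oracle_p <- function(n_AA, n_Aa, n_aa) {
  N <- n_AA + n_Aa + n_aa
  n_A <- 2L * n_AA + n_Aa
  if (n_A == 0L || 2L * N - n_A == 0L) return(1)
  # ways[a + 1, h + 1]: ordered-slot assignments among the first i
  # individuals using `a` A alleles with `h` heterozygotes
  ways <- matrix(0, 2L * N + 1L, N + 1L)
  ways[1L, 1L] <- 1
  for (i in seq_len(N)) {
    nw <- matrix(0, 2L * N + 1L, N + 1L)
    for (a in 0:(2L * i - 2L)) for (h in 0:(i - 1L)) {
      w <- ways[a + 1L, h + 1L]
      if (w == 0) next
      nw[a + 3L, h + 1L] <- nw[a + 3L, h + 1L] + w        # AA
      nw[a + 2L, h + 2L] <- nw[a + 2L, h + 2L] + 2 * w    # Aa (two orders)
      nw[a + 1L, h + 1L] <- nw[a + 1L, h + 1L] + w        # aa
    }
    ways <- nw
  }
  dist <- ways[n_A + 1L, ]
  dist <- dist / sum(dist)
  p_obs <- dist[n_Aa + 1L]
  sum(dist[dist <= p_obs * (1 + 1e-9)])
}

# brute-force Mendelian compatibility of a genotype triple: enumerate all
# transmissions from each parent's allele pair
mendel_oracle_ok <- function(gf, gm, gc) {
  alleles <- function(g) switch(g + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
  for (af in alleles(gf)) for (am in alleles(gm)) {
    if (af + am == gc) return(TRUE)
  }
  FALSE
}

# vectorised simulator of ascertained single-variant trios under a
# multiplicative-risk model P(aff | g) = baseline * or^g; returns genotype
# triples of affected-offspring trios
sim_snp_trios <- function(n, maf, or, baseline = 0.05, seed = 1L) {
  set.seed(seed)
  stopifnot(baseline * or^2 <= 1)
  gf <- integer(0); gm <- integer(0); gc <- integer(0)
  while (length(gf) < n) {
    k <- ceiling((n - length(gf)) / baseline * 1.3) + 500L
    f <- rbinom(k, 2L, maf)
    m <- rbinom(k, 2L, maf)
    tf <- ifelse(f == 1L, rbinom(k, 1L, 0.5), f / 2L)
    tm <- ifelse(m == 1L, rbinom(k, 1L, 0.5), m / 2L)
    ch <- tf + tm
    aff <- runif(k) < baseline * or^ch
    gf <- c(gf, f[aff]); gm <- c(gm, m[aff]); gc <- c(gc, ch[aff])
  }
  tibble::tibble(g_father = gf[1:n], g_mother = gm[1:n],
                 g_offspring = gc[1:n])
}

# wrap genotype triples into a single-variant cohort with affected offspring
triples_to_cohort <- function(tr) {
  n <- nrow(tr)
  split_g <- function(g) {
    cbind(ifelse(g == 2L, 1L, ifelse(g == 1L, 1L, 0L)),
          ifelse(g == 2L, 1L, 0L))
  }
  ids <- as.vector(t(outer(sprintf("T%04d", 1:n), c("_fa", "_mo", "_of"),
                           paste0)))
  hf <- split_g(tr$g_father); hm <- split_g(tr$g_mother)
  ho <- split_g(tr$g_offspring)
  haps <- matrix(0L, 6L * n, 1L)
  for (i in seq_len(n)) {
    haps[6 * i - 5, ] <- hf[i, 1]; haps[6 * i - 4, ] <- hf[i, 2]
    haps[6 * i - 3, ] <- hm[i, 1]; haps[6 * i - 2, ] <- hm[i, 2]
    haps[6 * i - 1, ] <- ho[i, 1]; haps[6 * i, ] <- ho[i, 2]
  }
  variants <- tibble::tibble(id = "snp", chrom = "17", pos = 30820506L,
                             ref = "A", alt = "G")
  individuals <- tibble::tibble(
    id = ids, sex = rep(c(1L, 2L, 0L), n),
    phenotype = rep(c(NA_real_, NA_real_, 1), n)
  )
  ped <- tibble::tibble(trio_id = sprintf("T%04d", 1:n), trio_type = 1L,
                        father = paste0(trio_id, "_fa"),
                        mother = paste0(trio_id, "_mo"),
                        offspring = paste0(trio_id, "_of"),
                        proband = offspring)
  new_cohort(haps, variants, individuals, ped)
}

hap_rows_for_test <- function(cohort, id) {
  k <- match(id, cohort$individuals$id)
  c(2L * k - 1L, 2L * k)
}
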