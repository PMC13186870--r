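#' Conditional mating/transmission distribution given an affected offspring
#'
#' Enumerates the joint distribution of the parental genotypes and the two
#' transmitted alleles conditional on the offspring being affected.  Parents
#' are in Hardy-Weinberg proportions at the given minor allele frequency;
#' each parent transmits one allele Mendelianly; the offspring's risk of
#' affection follows the genotype relative-risk model.  Under the `additive`
#' model (the default, and the convention of family-study power tools) the
#' genotype relative risks are `1 : OR : 2*OR - 1`; under `multiplicative`
#' they are `1 : OR : OR^2`.  With a supplied prevalence the baseline risk
#' is solved exactly; by default the rare-disease limit is used, where the
#' baseline cancels.
#'
#' @param maf Risk-allele frequency, in `(0, 0.5]`.
#' @param or Per-allele odds ratio (> 0.5 for the additive model).
#' @param model `"additive"` or `"multiplicative"`.
#' @param prevalence Optional disease prevalence; `NULL` (default) takes the
#'   rare-disease limit.
#' @return Tibble over `(g_father, g_mother, t_father, t_mother)` (allele
#'   counts / transmitted alleles) with the conditional probability `prob`;
#'   probabilities sum to 1.
#' @examples
#' d <- conditional_mating_distribution(0.2, 3.0)
#' sum(d$prob)
#' sum(d$prob[d$g_father == 1])  # P(father heterozygous | affected child)
#' @export
conditional_mating_distribution <- function(maf, or,
                                            model = c("additive",
                                                      "multiplicative"),
                                            prevalence = NULL) {
  model <- match.arg(model)
  stopifnot(maf > 0, maf <= 0.5, or > 0)
  grr <- genotype_relative_risks(or, model)
  p <- maf
  gf <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  d <- expand.grid(g_father = 0:2, g_mother = 0:2,
                   t_father = 0:1, t_mother = 0:1)
  ptrans <- function(g, t) ifelse(g == 0L, as.numeric(t == 0L),
                                  ifelse(g == 2L, as.numeric(t == 1L), 0.5))
  pr <- gf[d$g_father + 1L] * gf[d$g_mother + 1L] *
    ptrans(d$g_father, d$t_father) * ptrans(d$g_mother, d$t_mother)
  risk <- grr[d$t_father + d$t_mother + 1L]
  if (!is.null(prevalence)) {
    # exact baseline: solve f0 * E[grr(G)] = prevalence under HWE offspring
    gdist <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    f0 <- prevalence / sum(gdist * grr)
    if (f0 * max(grr) > 1)
      abort("prevalence incompatible with the relative risks.")
    risk <- f0 * risk
  }
  w <- pr * risk
  out <- tibble::as_tibble(d)
  out$prob <- w / sum(w)
  out
}

genotype_relative_risks <- function(or, model) {
  switch(model,
         additive = {
           if (or <= 0.5)
             abort("additive model needs OR > 0.5 (so 2*OR - 1 > 0).")
           c(1, or, 2 * or - 1)
         },
         multiplicative = c(1, or, or^2))
}

#' Analytic power of the transmission disequilibrium test
#'
#' From the conditional mating distribution the expected number of
#' informative transmissions is `m = 2 * n_trios * h`, where `h` is the
#' probability that a given parent is heterozygous given an affected
#' offspring, and `tau` is the probability that a heterozygous parent
#' transmitted the risk allele.  The TDT statistic `(b - c)^2 / (b + c)`
#' is approximated by a normal deviate with mean `sqrt(m) * (2 tau - 1)`
#' and standard deviation `sqrt(4 tau (1 - tau))`, rejecting two-sidedly at
#' level `alpha`.
#'
#' @param n_trios Number of affected-offspring trios (study value: 142).
#' @param maf Risk-allele frequency.
#' @param or Per-allele odds ratio.
#' @param alpha Two-sided type I error rate (study value: 0.05).
#' @param model Genotype relative-risk model, see
#'   [conditional_mating_distribution()].
#' @param prevalence Optional prevalence (default: rare-disease limit).
#' @return The power, in `[0, 1]`; equal to `alpha` at `or = 1`.
#' @examples
#' tdt_power(142, maf = 0.3, or = 1.9)   # ~0.866
#' @export
tdt_power <- function(n_trios, maf, or, alpha = 0.05,
                      model = c("additive", "multiplicative"),
                      prevalence = NULL) {
  model <- match.arg(model)
  stopifnot(n_trios >= 1)
  d <- conditional_mating_distribution(maf, or, model, prevalence)
  h <- sum(d$prob[d$g_father == 1L])
  tau <- sum(d$prob[d$g_father == 1L & d$t_father == 1L]) / h
  m <- 2 * n_trios * h
  mu <- sqrt(m) * (2 * tau - 1)
  sig <- sqrt(4 * tau * (1 - tau))
  z <- qnorm(1 - alpha / 2)
  pnorm((mu - z) / sig) + pnorm((-z - mu) / sig)
}

#' Analytic TDT power over a MAF-by-OR grid
#'
#' @param n_trios,alpha,model See [tdt_power()].
#' @param maf Vector of minor allele frequencies (study grid:
#'   0.05, 0.1, 0.2, 0.3).
#' @param or Vector of per-allele odds ratios (study grid: 1.2, 1.9, 3.0).
#' @return A tibble of class `triokf_power` with columns `maf`, `or` and
#'   `power`.
#' @export
tdt_power_grid <- function(n_trios = 142, maf = c(0.05, 0.1, 0.2, 0.3),
                           or = c(1.2, 1.9, 3.0), alpha = 0.05,
                           model = "additive") {
  grid <- tidyr::expand_grid(maf = maf, or = or)
  grid$power <- purrr::map2_dbl(grid$maf, grid$or,
                                ~ tdt_power(n_trios, .x, .y, alpha, model))
  attr(grid, "n_trios") <- n_trios
  attr(grid, "alpha") <- alpha
  class(grid) <- c("triokf_power", class(grid))
  grid
}

#' Simulated power of the transmission disequilibrium test
#'
#' Monte-Carlo cross-check of [tdt_power()]: affected-offspring trios are
#' simulated forward at a single variant (parents in Hardy-Weinberg
#' proportions, Mendelian transmission, affection drawn from the genotype
#' relative-risk model at a convenient baseline risk, rejection sampling on
#' the offspring), the allelic TDT is applied, and the rejection fraction is
#' returned.  Because the relative-risk weights are what the conditioning
#' retains, the baseline risk used for simulation does not change the
#' conditional distribution.
#'
#' @param n_trios,maf,or,alpha,model See [tdt_power()].
#' @param n_reps Number of replicate studies (>= 100).
#' @param seed Integer seed.
#' @param baseline_risk Baseline (genotype 0) affection probability used by
#'   the forward simulation (default 0.05).
#' @return List with `power` (rejection fraction), `se` (Monte-Carlo
#'   standard error) and `n_reps`.
#' @export
tdt_power_simulated <- function(n_trios, maf, or, alpha = 0.05,
                                n_reps = 2000L, seed = 1L,
                                model = c("additive", "multiplicative"),
                                baseline_risk = 0.05) {
  model <- match.arg(model)
  if (n_reps < 100L) abort("`n_reps` must be at least 100.")
  grr <- genotype_relative_risks(or, model)
  risk <- baseline_risk * grr
  if (any(risk > 1)) abort("baseline risk too high for these relative risks.")
  withr_seed(seed)
  need <- n_trios * n_reps
  tf <- integer(0); tm <- integer(0); hf <- integer(0); hm <- integer(0)
  while (length(tf) < need) {
    n_draw <- ceiling((need - length(tf)) / baseline_risk * 1.2) + 1000L
    gf <- rbinom(n_draw, 2L, maf)
    gm <- rbinom(n_draw, 2L, maf)
    t1 <- ifelse(gf == 1L, rbinom(n_draw, 1L, 0.5), gf / 2L)
    t2 <- ifelse(gm == 1L, rbinom(n_draw, 1L, 0.5), gm / 2L)
    aff <- runif(n_draw) < risk[t1 + t2 + 1L]
    tf <- c(tf, t1[aff]); tm <- c(tm, t2[aff])
    hf <- c(hf, (gf == 1L)[aff]); hm <- c(hm, (gm == 1L)[aff])
  }
  keep <- seq_len(need)
  rep_id <- rep(seq_len(n_reps), each = n_trios)
  b <- rowsum(as.numeric(tf[keep] * hf[keep] + tm[keep] * hm[keep]), rep_id)
  m <- rowsum(as.numeric(hf[keep] + hm[keep]), rep_id)
  cc <- m - b
  stat <- ifelse(m > 0, (b - cc)^2 / m, 0)
  rej <- stat > qchisq(1 - alpha, df = 1L)
  pw <- mean(rej)
  list(power = pw, se = sqrt(pw * (1 - pw) / n_reps), n_reps = n_reps)
}
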