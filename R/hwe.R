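#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test for deviation from Hardy-Weinberg genotype
#' proportions.  Conditional on the observed allele counts, the number of
#' heterozygotes under the null has the hypergeometric-type distribution
#' `P(h) = 2^h N! nA! na! / (nAA! h! naa! (2N)!)`; the p-value sums the
#' probabilities of all heterozygote counts (same parity, same allele
#' totals) whose probability does not exceed that of the observed count.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, not all zero).
#' @return The exact p-value; 1 for a monomorphic sample.
#' @examples
#' hwe_exact_test(10, 0, 0)   # monomorphic: 1
#' hwe_exact_test(2, 2, 2)
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) abort("genotype counts must be >= 0.")
  N <- n_AA + n_Aa + n_aa
  if (N == 0) abort("at least one genotyped individual is required.")
  n_A <- 2L * n_AA + n_Aa
  n_a <- 2L * n_aa + n_Aa
  if (n_A == 0L || n_a == 0L) return(1)
  h_vals <- seq(n_Aa %% 2L, min(n_A, n_a), by = 2L)
  logp <- h_vals * log(2) + lgamma(N + 1) + lgamma(n_A + 1) + lgamma(n_a + 1) -
    lgamma((n_A - h_vals) / 2 + 1) - lgamma(h_vals + 1) -
    lgamma((n_a - h_vals) / 2 + 1) - lgamma(2 * N + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_Aa, h_vals)]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}
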