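#' Post-imputation quality control for a phased trio cohort
#'
#' Applies, in order: the Mendelian-error policy, per-variant filters on
#' founder minor allele frequency, founder Hardy-Weinberg equilibrium and
#' per-variant genotype missingness, and finally removal of trios whose
#' proband genotype is entirely missing.  Allele frequency and HWE are
#' computed on founders only, so transmission-induced dependence between
#' family members does not distort them.
#'
#' @param cohort A `triokf_cohort` with resolved trios.
#' @param hwe_p_min HWE exact-test p-value threshold; variants with
#'   `p < hwe_p_min` are removed (default `1e-6`).
#' @param maf_min Minimum founder minor allele frequency (default `0.01`).
#'   Set `keep_rare = TRUE` to invert the filter and retain only variants
#'   below the threshold.
#' @param max_missing_rate Maximum per-variant fraction of individuals with
#'   a missing genotype (default `0.01`).
#' @param mendel_policy Either `"zero_out_trio_genotype"` (default: the
#'   offending trio's three genotypes at the variant are set to missing) or
#'   `"drop_variant"` (any Mendelian error removes the variant).
#' @param keep_rare Invert the MAF filter (see `maf_min`); default `FALSE`.
#'
#' @return A list with `cohort` (the filtered `triokf_cohort`) and `report`
#'   (a tibble with one row per input variant: `id`, `maf`, `hwe_p`,
#'   `missing_rate`, `mendel_errors`, `pass`, `reason`).  The operation is
#'   idempotent: applying it to its own output changes nothing.
#' @export
apply_qc <- function(cohort,
                     hwe_p_min = 1e-6,
                     maf_min = 0.01,
                     max_missing_rate = 0.01,
                     mendel_policy = c("zero_out_trio_genotype",
                                       "drop_variant"),
                     keep_rare = FALSE) {
  mendel_policy <- match.arg(mendel_policy)
  stopifnot(hwe_p_min >= 0, hwe_p_min <= 1, maf_min >= 0, maf_min <= 1,
            max_missing_rate >= 0, max_missing_rate <= 1)
  ped <- cohort$pedigree
  V <- nrow(cohort$variants)

  me <- mendelian_error_mask(cohort)
  if (mendel_policy == "zero_out_trio_genotype" && any(me$mask)) {
    err <- which(me$mask, arr.ind = TRUE)
    for (k in seq_len(nrow(err))) {
      i <- err[k, 1L]; v <- err[k, 2L]
      members <- stats::na.omit(c(ped$father[i], ped$mother[i],
                                  ped$offspring[i]))
      cohort$haplotypes[hap_rows(cohort, members), v] <- NA_integer_
    }
  }

  founders <- founder_ids(cohort)
  if (!length(founders)) abort("cohort has no founders; resolve trios first.")
  gf <- genotype_matrix(cohort, founders)
  alt_f <- colMeans(gf, na.rm = TRUE) / 2
  maf <- pmin(alt_f, 1 - alt_f)
  maf[is.nan(alt_f)] <- NA_real_
  hwe_p <- vapply(seq_len(V), function(v) {
    g <- gf[, v]
    hwe_exact_test(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
                   sum(g == 2L, na.rm = TRUE))
  }, numeric(1))
  n_ind <- nrow(cohort$individuals)
  gall <- genotype_matrix(cohort)
  missing_rate <- colMeans(is.na(gall))

  maf_fail <- if (keep_rare) !is.na(maf) & maf >= maf_min
              else is.na(maf) | maf < maf_min
  hwe_fail <- hwe_p < hwe_p_min
  miss_fail <- missing_rate > max_missing_rate
  mendel_fail <- mendel_policy == "drop_variant" & me$per_variant > 0L
  pass <- !(maf_fail | hwe_fail | miss_fail | mendel_fail)
  reason <- dplyr::case_when(
    mendel_fail ~ "mendel",
    maf_fail ~ "maf",
    hwe_fail ~ "hwe",
    miss_fail ~ "missing",
    TRUE ~ NA_character_
  )
  report <- tibble::tibble(
    id = cohort$variants$id,
    maf = maf, hwe_p = hwe_p, missing_rate = missing_rate,
    mendel_errors = as.integer(me$per_variant),
    pass = pass, reason = reason
  )
  if (!any(pass)) abort("all variants removed by QC; nothing left to analyse.")

  cohort$haplotypes <- cohort$haplotypes[, pass, drop = FALSE]
  cohort$variants <- cohort$variants[pass, , drop = FALSE]

  # drop trios whose proband genotype is entirely missing
  g2 <- genotype_matrix(cohort)
  uninformative <- vapply(seq_len(nrow(ped)), function(i) {
    pid <- if (is.na(ped$proband[i])) ped$offspring[i] else ped$proband[i]
    all(is.na(g2[pid, ]))
  }, logical(1))
  if (any(uninformative)) {
    dead <- ped[uninformative, , drop = FALSE]
    gone <- unique(stats::na.omit(c(dead$father, dead$mother, dead$offspring)))
    keep_ind <- !cohort$individuals$id %in% gone
    cohort$haplotypes <-
      cohort$haplotypes[rep(keep_ind, each = 2L), , drop = FALSE]
    cohort$individuals <- cohort$individuals[keep_ind, , drop = FALSE]
    cohort$pedigree <- ped[!uninformative, , drop = FALSE]
  }
  cohort <- new_cohort(cohort$haplotypes, cohort$variants,
                       cohort$individuals, cohort$pedigree)
  list(cohort = cohort, report = report)
}
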