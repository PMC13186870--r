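#' Trios informative for a variant
#'
#' A trio is informative for per-variant effect estimation when at least one
#' parent is heterozygous at the variant (and the trio is complete with all
#' three genotypes observed).
#'
#' @param cohort A `triokf_cohort`.
#' @param variant Variant id or column index.
#' @return Tibble of pedigree rows for the informative trios, with the three
#'   genotypes (`g_father`, `g_mother`, `g_offspring`) attached.
#' @export
select_informative_trios <- function(cohort, variant) {
  v <- if (is.character(variant)) match(variant, cohort$variants$id)
       else as.integer(variant)
  if (is.na(v) || v < 1L || v > nrow(cohort$variants))
    abort("unknown variant.")
  ped <- complete_trios(cohort)
  g <- genotype_matrix(cohort)[, v]
  out <- dplyr::mutate(ped,
                       g_father = g[.data$father],
                       g_mother = g[.data$mother],
                       g_offspring = g[.data$offspring])
  dplyr::filter(out,
                !is.na(.data$g_father) & !is.na(.data$g_mother) &
                  !is.na(.data$g_offspring) &
                  (.data$g_father == 1L | .data$g_mother == 1L))
}

#' Per-variant odds ratios by case/pseudo-control conditional logistic
#' regression
#'
#' For each requested variant, trios with at least one heterozygous parent
#' and an affected offspring contribute a matched set of four genotypes: the
#' affected offspring (case) and the three pseudo-controls formed from the
#' other combinations of transmitted/untransmitted parental alleles.  The
#' per-allele log odds ratio is estimated by maximising the conditional
#' likelihood ([survival::clogit()]), with Wald 95% confidence interval and
#' p-value.  Complete separation (all informative transmissions one-sided)
#' is reported as an infinite (or zero) odds ratio with a flag rather than
#' an error.
#'
#' @param cohort A `triokf_cohort`.
#' @param variants Vector of variant ids or column indices.
#' @return Tibble with one row per variant: `variant`, `n_informative`,
#'   `n_used` (informative trios with affected offspring), `or`, `ci_lo`,
#'   `ci_hi`, `p`, `status` (`"ok"`, `"separation"`, `"no_informative"`).
#' @export
estimate_effects <- function(cohort, variants) {
  purrr::map_dfr(variants, function(vr) estimate_one(cohort, vr))
}

estimate_one <- function(cohort, variant) {
  v_id <- if (is.character(variant)) variant
          else cohort$variants$id[as.integer(variant)]
  info <- select_informative_trios(cohort, variant)
  phe <- phenotype_of(cohort, info$offspring)
  used <- info[!is.na(phe) & phe == 1, , drop = FALSE]
  base <- tibble::tibble(variant = v_id, n_informative = nrow(info),
                         n_used = nrow(used), or = NA_real_,
                         ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                         status = "no_informative")
  if (!nrow(used)) return(base)

  # matched sets: case genotype and the three pseudo-control genotypes from
  # transmitted/untransmitted parental alleles; the multiset is invariant to
  # the phase-ambiguous double-heterozygous assignment
  alleles <- function(g) if (g == 0L) c(0L, 0L) else if (g == 2L) c(1L, 1L)
                         else c(1L, 0L)
  rows <- purrr::map_dfr(seq_len(nrow(used)), function(i) {
    gf <- used$g_father[i]; gm <- used$g_mother[i]; gc <- used$g_offspring[i]
    af <- alleles(gf); am <- alleles(gm)
    # pick a transmitted solution t_f + t_m = gc
    sol <- NULL
    for (tf in unique(af)) for (tm in unique(am)) {
      if (tf + tm == gc) { sol <- c(tf, tm); break }
    }
    if (is.null(sol)) return(NULL)  # Mendelian inconsistency: skip trio
    uf <- sum(af) - sol[1L]
    um <- sum(am) - sol[2L]
    tibble::tibble(trio = used$trio_id[i],
                   case = c(1L, 0L, 0L, 0L),
                   g = c(gc, sol[1L] + um, uf + sol[2L], uf + um))
  })
  if (!nrow(rows)) return(base)
  base$n_used <- length(unique(rows$trio))

  # conditional logistic likelihood == stratified Cox exact partial
  # likelihood on constant follow-up (what survival::clogit constructs)
  rows$one <- 1
  fit <- tryCatch(
    suppressWarnings(
      survival::coxph(survival::Surv(one, case) ~ g + survival::strata(trio),
                      data = rows, ties = "exact")
    ),
    error = function(e) NULL
  )
  beta <- if (!is.null(fit)) unname(coef(fit)[1L]) else NA_real_
  se <- if (!is.null(fit)) sqrt(vcov(fit)[1L, 1L]) else NA_real_
  if (is.null(fit) || !is.finite(beta) || !is.finite(se) || abs(beta) > 15 ||
      se > 1e3) {
    # complete separation: report the direction with an infinite OR
    direction <- if (!is.null(fit) && is.finite(beta) && beta < 0) 0 else Inf
    base$or <- direction
    base$status <- "separation"
    return(base)
  }
  base$or <- exp(beta)
  base$ci_lo <- exp(beta - 1.96 * se)
  base$ci_hi <- exp(beta + 1.96 * se)
  base$p <- 2 * pnorm(-abs(beta / se))
  base$status <- "ok"
  base
}
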