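#' Mendelian-error mask
#'
#' Flags genotype triples (father, mother, offspring alternate-allele counts)
#' that are impossible under Mendelian inheritance, using an unphased
#' genotype-level check.  Single-parent families (duos) are checked against
#' the present parent only (a duo error requires a homozygous parent whose
#' obligate allele is absent from the child).  Missing genotypes are never
#' flagged.
#'
#' @param cohort A `triokf_cohort` with resolved trios.
#' @return A list with `mask` (logical matrix, trios by variants, `TRUE` =
#'   Mendelian error), `per_variant` (integer error counts) and `per_trio`
#'   (integer error counts).
#' @export
mendelian_error_mask <- function(cohort) {
  ped <- cohort$pedigree
  V <- nrow(cohort$variants)
  g <- genotype_matrix(cohort)
  mask <- matrix(FALSE, nrow(ped), V,
                 dimnames = list(ped$trio_id, cohort$variants$id))
  for (i in seq_len(nrow(ped))) {
    gc <- g[ped$offspring[i], ]
    gf <- if (!is.na(ped$father[i])) g[ped$father[i], ] else rep(NA_integer_, V)
    gm <- if (!is.na(ped$mother[i])) g[ped$mother[i], ] else rep(NA_integer_, V)
    mask[i, ] <- mendel_incompatible(gf, gm, gc)
  }
  list(mask = mask,
       per_variant = colSums(mask),
       per_trio = rowSums(mask))
}

# vectorised genotype-level incompatibility; NA anywhere in the relevant
# comparison means "cannot flag"
mendel_incompatible <- function(gf, gm, gc) {
  # allele sets: genotype 0 -> {0}, 1 -> {0,1}, 2 -> {1}
  lo <- function(g) ifelse(g == 1L, 0L, g / 2L)   # minimum transmissible allele
  hi <- function(g) ifelse(g == 1L, 1L, g / 2L)   # maximum transmissible allele
  both <- !is.na(gf) & !is.na(gm) & !is.na(gc)
  err <- rep(FALSE, length(gc))
  # both parents: child must lie in [lo_f + lo_m, hi_f + hi_m]
  err[both] <- gc[both] < (lo(gf) + lo(gm))[both] |
    gc[both] > (hi(gf) + hi(gm))[both]
  # duos: obligate-allele check against the single present parent
  duo_f <- !is.na(gf) & is.na(gm) & !is.na(gc)
  duo_m <- is.na(gf) & !is.na(gm) & !is.na(gc)
  one_parent_err <- function(gp, gc) (gp == 0L & gc == 2L) | (gp == 2L & gc == 0L)
  err[duo_f] <- one_parent_err(gf[duo_f], gc[duo_f])
  err[duo_m] <- one_parent_err(gm[duo_m], gc[duo_m])
  err
}
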