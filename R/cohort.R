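#' Phased trio cohort container
#'
#' A `triokf_cohort` bundles the phased haplotype matrix with variant
#' metadata, per-individual records and the trio index.  It is the substrate
#' for every downstream stage (QC, LD blocks, knockoffs, scanning).
#'
#' @param haplotypes 0/1 integer matrix with two rows per individual
#'   (haplotype 1 then haplotype 2, in the order of `individuals`); `NA`
#'   encodes a missing genotype.
#' @param variants Tibble with columns `id`, `chrom`, `pos`, `ref`, `alt`.
#' @param individuals Tibble with columns `id`, `sex` (1 male, 2 female,
#'   0 unknown) and `phenotype` (1 affected, 0 unaffected, `NA` missing).
#' @param pedigree Tibble with one row per trio: `trio_id`, `trio_type`
#'   (1, 2 or `NA`), `father`, `mother`, `offspring`, `proband`; `father` or
#'   `mother` may be `NA` for single-parent families.
#' @return An object of class `triokf_cohort`.
#' @export
new_cohort <- function(haplotypes, variants, individuals, pedigree = NULL) {
  if (nrow(haplotypes) != 2L * nrow(individuals))
    abort("`haplotypes` must have exactly two rows per individual.")
  if (ncol(haplotypes) != nrow(variants))
    abort("`haplotypes` and `variants` disagree on the number of variants.")
  if (is.null(pedigree)) {
    pedigree <- tibble::tibble(trio_id = character(), trio_type = integer(),
                               father = character(), mother = character(),
                               offspring = character(), proband = character())
  }
  ids <- individuals$id
  for (colnm in c("father", "mother", "offspring")) {
    bad <- setdiff(stats::na.omit(pedigree[[colnm]]), ids)
    if (length(bad))
      abort(paste0("pedigree references unknown individual(s): ",
                   paste(bad, collapse = ", ")))
  }
  rownames(haplotypes) <- paste(rep(ids, each = 2L), 1:2, sep = "_")
  structure(
    list(haplotypes = haplotypes, variants = variants,
         individuals = individuals, pedigree = pedigree),
    class = "triokf_cohort"
  )
}

#' @export
print.triokf_cohort <- function(x, ...) {
  cat("<triokf_cohort> ", nrow(x$individuals), " individuals, ",
      nrow(x$variants), " variants, ", nrow(x$pedigree), " trios\n", sep = "")
  invisible(x)
}

# haplotype row indices (c(2i-1, 2i)) for a vector of individual ids
hap_rows <- function(cohort, ids) {
  idx <- match(ids, cohort$individuals$id)
  if (anyNA(idx)) abort("unknown individual id.")
  as.vector(rbind(2L * idx - 1L, 2L * idx))
}

#' Additive genotype dosage matrix
#'
#' @param cohort A `triokf_cohort`.
#' @param ids Individual ids (default: all).
#' @return Integer matrix of alternate-allele counts (0/1/2, `NA` missing),
#'   one row per individual.
#' @export
genotype_matrix <- function(cohort, ids = NULL) {
  if (is.null(ids)) ids <- cohort$individuals$id
  idx <- match(ids, cohort$individuals$id)
  g <- cohort$haplotypes[2L * idx - 1L, , drop = FALSE] +
    cohort$haplotypes[2L * idx, , drop = FALSE]
  rownames(g) <- ids
  g
}

#' Founder individuals of a cohort
#'
#' Founders are individuals listed as a father or mother of some trio and not
#' as an offspring of any; allele-frequency and Hardy-Weinberg computations
#' are restricted to them to avoid the dependence induced by transmission.
#'
#' @param cohort A `triokf_cohort`.
#' @return Character vector of individual ids.
#' @export
founder_ids <- function(cohort) {
  ped <- cohort$pedigree
  parents <- unique(stats::na.omit(c(ped$father, ped$mother)))
  setdiff(parents, ped$offspring)
}

# complete trios: both parents and the offspring present
complete_trios <- function(cohort) {
  ped <- cohort$pedigree
  ped[!is.na(ped$father) & !is.na(ped$mother) & !is.na(ped$offspring), ,
      drop = FALSE]
}

#' Per-individual phenotype vector
#' @param cohort A `triokf_cohort`.
#' @param ids Individual ids (default all).
#' @return Named numeric vector, 1 affected / 0 unaffected / `NA`.
#' @export
phenotype_of <- function(cohort, ids = NULL) {
  if (is.null(ids)) ids <- cohort$individuals$id
  setNames(cohort$individuals$phenotype[match(ids, cohort$individuals$id)], ids)
}
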