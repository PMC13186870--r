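#' Infer transmitted parental haplotypes per LD block
#'
#' For every complete trio the two offspring haplotypes are assigned to the
#' parents by whole-trio consistency: of the two possible
#' offspring-haplotype-to-parent assignments, the one minimising the total
#' allele mismatch across all blocks is chosen.  Then, per parent and block,
#' the transmitted parental haplotype is the one of the parent's two block
#' haplotypes with fewer mismatches against the offspring haplotype
#' attributed to that parent; an exact tie is resolved to haplotype 1 and
#' flagged ambiguous (with error-free phased data a tie occurs precisely
#' when the parent's two block haplotypes are identical, so the tie-break is
#' distribution-neutral).  Duos are inferred for the present parent only.
#'
#' @param cohort A phased `triokf_cohort`.
#' @param blocks A `triokf_blocks` partition of the cohort's variants.
#' @return An object of class `triokf_transmission`: tibble with columns
#'   `trio_id`, `parent` (`"father"`/`"mother"`), `block`, `transmitted`
#'   (1 or 2), `ambiguous`, `mismatches`; the offspring-haplotype
#'   assignment is carried as attribute `hap_assignment` (tibble `trio_id`,
#'   `paternal_row`: which offspring haplotype row, 1 or 2, came from the
#'   father).
#' @export
infer_transmission <- function(cohort, blocks) {
  ped <- cohort$pedigree
  vb <- attr(blocks, "variant_block")
  V <- nrow(cohort$variants)
  stopifnot(length(vb) == V)
  H <- cohort$haplotypes
  n_blk <- nrow(blocks)

  # per-block mismatch between two haplotype vectors (NAs ignored)
  block_mismatch <- function(a, b) {
    d <- as.numeric(a != b)
    d[is.na(d)] <- 0
    as.vector(rowsum(d, vb))
  }

  rows_of <- function(id) {
    k <- match(id, cohort$individuals$id)
    c(2L * k - 1L, 2L * k)
  }

  out <- list()
  assign_rows <- list()
  for (i in seq_len(nrow(ped))) {
    if (is.na(ped$offspring[i])) {
      warn(paste0("trio ", ped$trio_id[i], " has no offspring; skipped."))
      next
    }
    orow <- rows_of(ped$offspring[i])
    has_f <- !is.na(ped$father[i])
    has_m <- !is.na(ped$mother[i])
    if (!has_f && !has_m) next
    frow <- if (has_f) rows_of(ped$father[i]) else NULL
    mrow <- if (has_m) rows_of(ped$mother[i]) else NULL

    # mm[[o]][[p]][[h]]: mismatches per block of offspring hap o vs parent
    # p's hap h
    par_mm <- function(prow, o) {
      if (is.null(prow)) return(NULL)
      list(block_mismatch(H[orow[o], ], H[prow[1L], ]),
           block_mismatch(H[orow[o], ], H[prow[2L], ]))
    }
    best <- function(mm) if (is.null(mm)) rep(0, n_blk) else pmin(mm[[1L]], mm[[2L]])
    mm_f <- list(par_mm(frow, 1L), par_mm(frow, 2L))
    mm_m <- list(par_mm(mrow, 1L), par_mm(mrow, 2L))
    tot <- c(sum(best(mm_f[[1L]])) + sum(best(mm_m[[2L]])),   # o1 paternal
             sum(best(mm_f[[2L]])) + sum(best(mm_m[[1L]])))   # o2 paternal
    pat <- if (tot[2L] < tot[1L]) 2L else 1L
    assign_rows[[length(assign_rows) + 1L]] <-
      tibble::tibble(trio_id = ped$trio_id[i], paternal_row = pat)

    emit <- function(parent, mm) {
      if (is.null(mm)) return(NULL)
      transmitted <- ifelse(mm[[2L]] < mm[[1L]], 2L, 1L)
      amb <- mm[[1L]] == mm[[2L]]
      tibble::tibble(trio_id = ped$trio_id[i], parent = parent,
                     block = seq_len(n_blk), transmitted = transmitted,
                     ambiguous = amb,
                     mismatches = pmin(mm[[1L]], mm[[2L]]))
    }
    out[[length(out) + 1L]] <- dplyr::bind_rows(
      emit("father", mm_f[[pat]]),
      emit("mother", mm_m[[3L - pat]])
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "hap_assignment") <- dplyr::bind_rows(assign_rows)
  attr(res, "n_blocks") <- n_blk
  class(res) <- c("triokf_transmission", class(res))
  res
}
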