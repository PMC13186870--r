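#' Generate knockoff copies of parental haplotypes
#'
#' Residual-permutation knockoffs, instantiated as sequential blockwise
#' within-stratum permutation of whole parents.  Blocks are processed left
#' to right; for block `k`, parents (each a pair of haplotype rows) are
#' stratified by the pair (block `k-1` haplotype labels in the
#' already-generated knockoff, block `k+1` haplotype labels in the
#' original); strata smaller than `min_stratum_size` are merged with the
#' stratum of most similar size until all strata are large enough; within
#' each stratum the parents' block-`k` haplotype pairs are randomly permuted
#' among parents.  Boundary blocks condition on their single existing
#' neighbour.  Because parents move as units, the multiset of haplotype
#' rows per block is exactly preserved, so per-variant allele counts and the
#' within-block r-squared structure are conserved exactly.
#'
#' The donor parent of every (parent, block) cell is recorded (attribute
#' `"donor"` of each copy) for inspection.
#'
#' @param parent_haplotypes 0/1 matrix of parental haplotype rows, two
#'   consecutive rows per parent.
#' @param blocks A `triokf_blocks` partition of the columns.
#' @param M Number of knockoff copies (default 10).
#' @param min_stratum_size Minimum parents per permutation stratum
#'   (default 10).
#' @param seed Master seed; copy `m` uses `seed + m` so copies are
#'   independent and individually reproducible.
#' @return List of `M` knockoff matrices aligned to the input, each with an
#'   integer attribute `"donor"` (parents by blocks) giving the source
#'   parent of every block haplotype pair.
#' @export
generate_parental_knockoffs <- function(parent_haplotypes, blocks, M = 10L,
                                        min_stratum_size = 10L, seed = 1L) {
  if (M < 1L) abort("`M` must be at least 1.")
  if (nrow(parent_haplotypes) < 2L)
    abort("at least two parental haplotype rows are required.")
  if (nrow(parent_haplotypes) %% 2L != 0L)
    abort("parental haplotype rows must come in pairs.")
  vb <- attr(blocks, "variant_block")
  stopifnot(length(vb) == ncol(parent_haplotypes))
  n_blk <- nrow(blocks)
  n_par <- nrow(parent_haplotypes) / 2L
  cols_of <- split(seq_along(vb), vb)
  row1 <- 2L * seq_len(n_par) - 1L

  # unordered pair label of each parent's two haplotypes within a block
  pair_labels <- function(mat, cols) {
    sub <- mat[, cols, drop = FALSE]
    keyed <- do.call(paste, c(as.data.frame(sub), sep = ","))
    lab <- match(keyed, unique(keyed))
    a <- lab[row1]
    b <- lab[row1 + 1L]
    paste(pmin(a, b), pmax(a, b))
  }

  lapply(seq_len(M), function(m) {
    withr_seed(seed + m)
    ko <- parent_haplotypes
    donor <- matrix(seq_len(n_par), n_par, n_blk)
    for (k in seq_len(n_blk)) {
      left <- if (k > 1L) pair_labels(ko, cols_of[[k - 1L]]) else NULL
      right <- if (k < n_blk)
        pair_labels(parent_haplotypes, cols_of[[k + 1L]]) else NULL
      # own-block zygosity joins the context: homozygous parents (identical
      # pair, zero transmission contrast) exchange only with homozygous
      # parents, heterozygous with heterozygous, so the multiset of
      # per-parent contrast magnitudes — and with it the shape of the
      # knockoff burden score — matches the original exactly
      sub_k <- parent_haplotypes[, cols_of[[k]], drop = FALSE]
      own_hom <- rowSums(sub_k[row1, , drop = FALSE] !=
                           sub_k[row1 + 1L, , drop = FALSE]) == 0L
      key <- paste(if (is.null(left)) "" else left,
                   if (is.null(right)) "" else right)
      stratum <- match(key, unique(key))
      # context merging never crosses the zygosity boundary: exchanging a
      # homozygous (zero-contrast) parent with a heterozygous one would
      # change which contrast magnitudes enter the knockoff score
      for (cls in unique(own_hom)) {
        sel <- own_hom == cls
        stratum[sel] <- merge_small_strata(stratum[sel], min_stratum_size)
      }
      stratum <- match(paste(own_hom, stratum), unique(paste(own_hom, stratum)))
      cols <- cols_of[[k]]
      for (s in unique(stratum)) {
        members <- which(stratum == s)
        if (length(members) > 1L) {
          src <- sample(members)
          rows_to <- as.vector(rbind(row1[members], row1[members] + 1L))
          rows_from <- as.vector(rbind(row1[src], row1[src] + 1L))
          ko[rows_to, cols] <- parent_haplotypes[rows_from, cols,
                                                 drop = FALSE]
          donor[members, k] <- src
        }
      }
    }
    attr(ko, "donor") <- donor
    ko
  })
}

# merge strata below the minimum size with the stratum of most similar
# size, iterating until all strata are large enough (or one stratum
# remains)
merge_small_strata <- function(stratum, min_size) {
  repeat {
    tab <- table(stratum)
    if (length(tab) <= 1L) return(stratum)
    small <- names(tab)[tab < min_size]
    if (!length(small)) return(stratum)
    victim <- small[which.min(tab[small])]
    others <- setdiff(names(tab), victim)
    target <- others[which.min(abs(tab[others] - tab[victim]))]
    stratum[stratum == victim] <- target
    stratum <- match(stratum, unique(stratum))
  }
}

#' Derive knockoff offspring haplotypes
#'
#' For each trio, parent and block, the offspring's knockoff haplotype
#' copies the same parental haplotype index that was originally transmitted
#' (from [infer_transmission()]), read from the knockoff parent.  Because
#' the knockoff parent's haplotype pair comes from a permutation donor, the
#' transmitted *index* stays the family's own while the transmitted
#' *content* is exchanged, which severs the genotype-phenotype link that
#' the burden FBAT measures while preserving Mendelian consistency.  When
#' the transmission is flagged ambiguous the parent's two original block
#' haplotypes were identical and the index is unidentifiable; it is then
#' drawn uniformly at random (a fixed index would give those contributions
#' a deterministic sign and under-disperse the knockoff scores).  An
#' identity permutation with no ambiguity reproduces the original offspring
#' exactly.
#'
#' @param knockoff_parents One knockoff parental matrix (rows aligned with
#'   `parent_rows`).
#' @param cohort The original `triokf_cohort`.
#' @param parent_ids Character vector: individual id of each parent, in the
#'   order of the knockoff matrix's row pairs.
#' @param parent_rows Integer vector: which rows of `cohort$haplotypes` the
#'   knockoff matrix rows correspond to.
#' @param tmap A `triokf_transmission` covering all complete trios.
#' @param blocks The `triokf_blocks` used for `tmap`.
#' @param randomize_ambiguous Draw the transmitted index uniformly for
#'   ambiguous entries (default `TRUE`).
#' @return A full haplotype matrix shaped like `cohort$haplotypes` in which
#'   parental rows are replaced by their knockoffs and offspring rows of
#'   complete trios by the derived knockoff haplotypes; rows of individuals
#'   outside complete trios are left unchanged.
#' @export
derive_knockoff_offspring <- function(knockoff_parents, cohort, parent_ids,
                                      parent_rows, tmap, blocks,
                                      randomize_ambiguous = TRUE) {
  vb <- attr(blocks, "variant_block")
  cols_of <- split(seq_along(vb), vb)
  n_blk <- length(cols_of)
  assignment <- attr(tmap, "hap_assignment")
  H <- cohort$haplotypes
  H[parent_rows, ] <- knockoff_parents
  ped <- complete_trios(cohort)

  # transmitted haplotype index per (parent, block) from the transmission
  # map; duos (not complete trios) carry no derived offspring
  tmap <- tmap[tmap$trio_id %in% ped$trio_id, , drop = FALSE]
  pid <- ifelse(tmap$parent == "father",
                ped$father[match(tmap$trio_id, ped$trio_id)],
                ped$mother[match(tmap$trio_id, ped$trio_id)])
  p_of <- match(pid, parent_ids)
  if (anyNA(p_of)) abort("transmission map names a parent outside the cohort.")
  tmat <- matrix(NA_integer_, length(parent_ids), n_blk)
  tmat[cbind(p_of, tmap$block)] <- tmap$transmitted
  if (randomize_ambiguous) {
    amb <- which(tmap$ambiguous)
    if (length(amb)) {
      tmat[cbind(p_of[amb], tmap$block[amb])] <-
        sample.int(2L, length(amb), replace = TRUE)
    }
  }
  needed <- match(unique(c(ped$father, ped$mother)), parent_ids)
  if (anyNA(tmat[needed, , drop = FALSE]))
    abort("missing transmission entry for a (trio, parent, block) cell.")

  pat_row <- assignment$paternal_row[match(ped$trio_id, assignment$trio_id)]
  o1 <- vapply(ped$offspring, function(id) hap_rows(cohort, id)[1L],
               integer(1))
  orow_f <- o1 + pat_row - 1L
  orow_m <- o1 + (3L - pat_row) - 1L
  p_f <- match(ped$father, parent_ids)
  p_m <- match(ped$mother, parent_ids)
  prow1_f <- vapply(ped$father, function(id) hap_rows(cohort, id)[1L],
                    integer(1))
  prow1_m <- vapply(ped$mother, function(id) hap_rows(cohort, id)[1L],
                    integer(1))
  for (k in seq_len(n_blk)) {
    cols <- cols_of[[k]]
    src_f <- prow1_f + tmat[cbind(p_f, k)] - 1L
    src_m <- prow1_m + tmat[cbind(p_m, k)] - 1L
    H[orow_f, cols] <- H[src_f, cols, drop = FALSE]
    H[orow_m, cols] <- H[src_m, cols, drop = FALSE]
  }
  H
}

#' Build the full knockoff set for a cohort
#'
#' Convenience wrapper producing `M` complete knockoff haplotype matrices:
#' parental rows are knockoffs generated by within-block residual
#' permutation, offspring rows are derived from the donors' transmission
#' pattern.
#'
#' @param cohort A `triokf_cohort`.
#' @param blocks A `triokf_blocks`.
#' @param tmap Optional precomputed `triokf_transmission`.
#' @param M,min_stratum_size,seed See [generate_parental_knockoffs()].
#' @return An object of class `triokf_knockoffs`: list with `matrices`
#'   (list of `M` haplotype matrices), `parent_ids`, `parent_rows`, `tmap`,
#'   `blocks`, `M` and `seed`.
#' @export
make_knockoffs <- function(cohort, blocks, tmap = NULL, M = 10L,
                           min_stratum_size = 10L, seed = 1L) {
  if (is.null(tmap)) tmap <- infer_transmission(cohort, blocks)
  ped <- complete_trios(cohort)
  parents <- unique(c(ped$father, ped$mother))
  parent_rows <- hap_rows(cohort, parents)
  kos <- generate_parental_knockoffs(
    cohort$haplotypes[parent_rows, , drop = FALSE],
    blocks, M = M, min_stratum_size = min_stratum_size, seed = seed
  )
  mats <- lapply(seq_len(M), function(m) {
    withr_seed(seed + m + 500000L)  # independent stream for ambiguous draws
    derive_knockoff_offspring(kos[[m]], cohort = cohort,
                              parent_ids = parents,
                              parent_rows = parent_rows,
                              tmap = tmap, blocks = blocks)
  })
  structure(list(matrices = mats, parent_ids = parents,
                 parent_rows = parent_rows, tmap = tmap,
                 blocks = blocks, M = M, seed = seed),
            class = "triokf_knockoffs")
}

#' @export
print.triokf_knockoffs <- function(x, ...) {
  cat("<triokf_knockoffs> M = ", x$M, ", ",
      length(x$parent_ids), " parents, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
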