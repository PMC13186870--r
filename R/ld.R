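#' Pairwise haplotype r-squared
#'
#' Computes `r^2 = (p_AB - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B))` from
#' haplotype frequencies for every variant pair closer than
#' `window_limit_bp`.  For a monomorphic column the statistic is undefined
#' and reported as `NA`, never as 0.
#'
#' @param haplotypes 0/1 haplotype matrix (haplotypes by variants); rows
#'   with `NA` at either member of a pair are dropped for that pair.
#' @param positions Integer vector of bp positions (sorted ascending).
#' @param window_limit_bp Maximum pair distance in bp (default `Inf`).
#' @return Tibble with columns `i`, `j` (column indices, `i < j`) and `r2`.
#' @export
ld_r2_matrix <- function(haplotypes, positions, window_limit_bp = Inf) {
  if (nrow(haplotypes) < 2L) abort("at least two haplotypes are required.")
  V <- ncol(haplotypes)
  stopifnot(length(positions) == V, !is.unsorted(positions))
  if (V < 2L)
    return(tibble::tibble(i = integer(), j = integer(), r2 = numeric()))
  out_i <- list(); out_j <- list(); out_r <- list()
  for (i in seq_len(V - 1L)) {
    j_max <- i
    while (j_max < V && positions[j_max + 1L] - positions[i] <= window_limit_bp)
      j_max <- j_max + 1L
    if (j_max == i) next
    js <- (i + 1L):j_max
    r <- suppressWarnings(
      cor(haplotypes[, i], haplotypes[, js, drop = FALSE],
          use = "pairwise.complete.obs")
    )
    out_i[[length(out_i) + 1L]] <- rep.int(i, length(js))
    out_j[[length(out_j) + 1L]] <- js
    out_r[[length(out_r) + 1L]] <- drop(r)^2
  }
  tibble::tibble(i = unlist(out_i) %||% integer(),
                 j = unlist(out_j) %||% integer(),
                 r2 = as.numeric(unlist(out_r) %||% numeric()))
}

#' Partition variants into contiguous LD blocks
#'
#' Greedy left-to-right scan: the current block is extended to the next
#' variant while its r-squared with *any* variant already in the block is at
#' least `r2_threshold` and the block span stays within `max_block_span_bp`;
#' otherwise a new block starts.  Monomorphic variants (undefined r-squared)
#' are forced into singleton blocks.  The result is a total, order-preserving
#' cover of the variants.
#'
#' @param r2 Long-format tibble from [ld_r2_matrix()].
#' @param positions Integer vector of bp positions (sorted).
#' @param r2_threshold Linkage threshold for joining a block (default 0.5).
#' @param max_block_span_bp Maximum block span in bp (default 100,000).
#' @param monomorphic Optional logical vector marking monomorphic variants;
#'   by default inferred as variants all of whose pair r-squared values are
#'   `NA` (or that have no pairs).
#' @return An object of class `triokf_blocks`: a tibble with one row per
#'   block (`block`, `first`, `last` variant indices, `start_bp`, `end_bp`,
#'   `n_variants`) carrying the per-variant assignment as attribute
#'   `variant_block`.
#' @export
partition_blocks <- function(r2, positions, r2_threshold = 0.5,
                             max_block_span_bp = 1e5, monomorphic = NULL) {
  V <- length(positions)
  if (V == 0L) {
    out <- tibble::tibble(block = integer(), first = integer(),
                          last = integer(), start_bp = integer(),
                          end_bp = integer(), n_variants = integer())
    attr(out, "variant_block") <- integer()
    class(out) <- c("triokf_blocks", class(out))
    return(out)
  }
  if (is.null(monomorphic)) {
    monomorphic <- rep(FALSE, V)
    touched <- rep(FALSE, V)
    touched[unique(c(r2$i, r2$j))] <- TRUE
    defined <- rep(FALSE, V)
    ok <- !is.na(r2$r2)
    defined[unique(c(r2$i[ok], r2$j[ok]))] <- TRUE
    monomorphic <- touched & !defined
  }
  # fast lookup of r2 by pair
  key <- paste(r2$i, r2$j)
  r2v <- r2$r2
  lookup <- function(a, b) {
    k <- match(paste(pmin(a, b), pmax(a, b)), key)
    ifelse(is.na(k), NA_real_, r2v[k])
  }
  assignment <- integer(V)
  block <- 1L
  members <- 1L
  assignment[1L] <- 1L
  for (v in seq_len(V)[-1L]) {
    join <- FALSE
    if (!monomorphic[v] && !monomorphic[members[1L]]) {
      span_ok <- positions[v] - positions[members[1L]] <= max_block_span_bp
      if (span_ok) {
        link <- lookup(members, v)
        join <- any(!is.na(link) & link >= r2_threshold)
      }
    }
    if (join) {
      members <- c(members, v)
    } else {
      block <- block + 1L
      members <- v
    }
    assignment[v] <- block
  }
  out <- tibble::tibble(
    block = seq_len(max(assignment)),
    first = vapply(seq_len(max(assignment)),
                   function(b) min(which(assignment == b)), integer(1)),
    last = vapply(seq_len(max(assignment)),
                  function(b) max(which(assignment == b)), integer(1))
  )
  out$start_bp <- positions[out$first]
  out$end_bp <- positions[out$last]
  out$n_variants <- out$last - out$first + 1L
  attr(out, "variant_block") <- assignment
  attr(out, "r2_threshold") <- r2_threshold
  attr(out, "max_block_span_bp") <- max_block_span_bp
  class(out) <- c("triokf_blocks", class(out))
  out
}

#' LD blocks of a cohort's parental haplotypes
#'
#' Convenience wrapper: computes banded r-squared on the founder haplotypes
#' and partitions the variants into blocks.
#'
#' @param cohort A `triokf_cohort`.
#' @param r2_threshold,max_block_span_bp See [partition_blocks()].
#' @param window_limit_bp See [ld_r2_matrix()].
#' @return A `triokf_blocks` partition.
#' @export
cohort_ld_blocks <- function(cohort, r2_threshold = 0.5,
                             max_block_span_bp = 1e5,
                             window_limit_bp = 1e5) {
  founders <- founder_ids(cohort)
  rows <- if (length(founders)) hap_rows(cohort, founders)
          else seq_len(nrow(cohort$haplotypes))
  r2 <- ld_r2_matrix(cohort$haplotypes[rows, , drop = FALSE],
                     cohort$variants$pos, window_limit_bp)
  partition_blocks(r2, cohort$variants$pos, r2_threshold, max_block_span_bp)
}

#' Write LD blocks as BED (0-based half-open) plus an index-range TSV
#' @param blocks A `triokf_blocks`.
#' @param chrom Chromosome label for the BED output.
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the block tibble.
#' @export
write_blocks <- function(blocks, chrom, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    writeLines(paste(chrom, blocks$start_bp - 1L, blocks$end_bp,
                     paste0("block", blocks$block), sep = "\t"), bed_path)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(as.data.frame(blocks[, c("block", "first", "last",
                                                "start_bp", "end_bp",
                                                "n_variants")]),
                       tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(blocks)
}
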