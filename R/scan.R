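#' Multiple-knockoff FDR selection
#'
#' For each window let the candidate scores be
#' `(|Z|, |Z*_1|, ..., |Z*_M|)`.  Define `kappa` as the index of the largest
#' score (0 when the original wins) and `tau` as the largest score minus the
#' median of the remaining ones.  A window can only be selected when
#' `kappa = 0`; the selection threshold on `tau` is the smallest value `t`
#' such that the estimated FDR
#' `((offset + #{kappa != 0, tau >= t}) / M) / max(1, #{kappa = 0, tau >= t})`
#' is at most `q_target`.  The default `offset = 1` is the multiple-knockoff
#' analogue of the knockoff+ correction; without it the estimator is
#' anti-conservative when true signals are sparse and the realised false
#' discovery proportion can far exceed the target.  The per-window `q` is
#' the smallest target at which that window would be selected.
#'
#' @param results Tibble with columns `Z` and list-column `Zstar` (or matrix
#'   column) as produced by [scan_cohort()]; windows with undefined `Z` are
#'   ignored.
#' @param q_target Target false discovery rate (default 0.05).
#' @param offset Numerator offset in knockoff-win units; 1 (default) gives
#'   FDR control, 0 gives the uncorrected estimator.
#' @return `results` with columns `kappa`, `tau`, `q` and `selected` added.
#' @export
knockoff_fdr_select <- function(results, q_target = 0.05, offset = 1) {
  zs <- results$Zstar
  if (is.list(zs)) zs <- do.call(rbind, zs)
  score <- cbind(abs(results$Z), abs(zs))
  M <- ncol(score) - 1L
  usable <- !is.na(results$Z)
  kappa <- rep(NA_integer_, nrow(score))
  tau <- rep(NA_real_, nrow(score))
  for (i in which(usable)) {
    s <- score[i, ]
    s[is.na(s)] <- 0
    k <- which.max(s)
    kappa[i] <- k - 1L
    tau[i] <- s[k] - median(s[-k])
  }
  orig <- usable & kappa == 0L
  ko <- usable & kappa != 0L
  fdr_at <- function(t) {
    ((offset + sum(tau[ko] >= t)) / M) / max(1, sum(tau[orig] >= t))
  }
  cand <- sort(unique(tau[usable]))
  qhat <- rep(NA_real_, nrow(score))
  for (i in which(orig)) {
    ts <- cand[cand <= tau[i]]
    if (length(ts)) qhat[i] <- min(vapply(ts, fdr_at, numeric(1)))
  }
  results$kappa <- kappa
  results$tau <- tau
  results$q <- qhat
  results$selected <- !is.na(qhat) & qhat <= q_target
  results
}

#' Knockoff-calibrated multi-resolution window scan
#'
#' The full scanning pipeline on a phased trio cohort: LD blocks (computed
#' on founder haplotypes unless supplied), per-block transmission inference,
#' `M` knockoff copies of the parental haplotypes with derived knockoff
#' offspring, half-overlapping windows at the requested resolutions, LASSO
#' burden weights per window (fitted once, on the expected offspring dosage
#' given the original parental genotypes, and
#' reused for every knockoff so the contrast is a pure genotype swap), the
#' weighted burden FBAT score `Z` for the original and each knockoff copy,
#' the contrast statistic `W = |Z| / median|Z*|`, and multiple-knockoff FDR
#' selection.
#'
#' Windows that contain exactly the same variants (which happens routinely
#' across resolutions) are computed once and shared.
#'
#' @param cohort A `triokf_cohort` (typically after [apply_qc()]).
#' @param blocks Optional precomputed `triokf_blocks`.
#' @param sizes Window sizes in bp.
#' @param M Number of knockoff copies (default 10).
#' @param q_target Target FDR for selection (default 0.05).
#' @param lambda_policy `"cv_min"` (default) or a fixed penalty.
#' @param mu Phenotype offset passed to [fbat_burden_z()] (default 0).
#' @param min_stratum_size Minimum knockoff permutation stratum.
#' @param seed Master seed (knockoff permutations and CV folds).
#' @return A tibble of class `triokf_scan`, one row per window:
#'   `chrom`, `start`, `end`, `size`, `n` (variants with non-zero weight),
#'   `dir`, `W`, `Z`, `p_burden`, `kappa`, `tau`, `q`, `selected`,
#'   `fallback`, plus the list-column `Zstar`.
#' @export
scan_cohort <- function(cohort,
                        blocks = NULL,
                        sizes = c(500, 1000, 2000, 5000, 10000, 15000, 20000),
                        M = 10L,
                        q_target = 0.05,
                        lambda_policy = "cv_min",
                        mu = 0,
                        min_stratum_size = 10L,
                        seed = 1L) {
  if (is.null(blocks)) blocks <- cohort_ld_blocks(cohort)
  kos <- make_knockoffs(cohort, blocks, M = M,
                        min_stratum_size = min_stratum_size, seed = seed)
  windows <- make_windows(min(cohort$variants$pos), max(cohort$variants$pos),
                          cohort$variants$pos, sizes = sizes)
  ped <- complete_trios(cohort)
  ids <- cohort$individuals$id
  off_ids <- ped$offspring
  y <- cohort$individuals$phenotype[match(off_ids, ids)]
  # burden weights are fitted on the expected offspring dosage given the
  # parents, (g_father + g_mother) / 2, not on the realised offspring
  # genotypes: the realised genotype contains the Mendelian transmission
  # noise that the FBAT measures, and weights fitted on it would inflate
  # |Z| relative to the knockoff scores and break their exchangeability
  g_exp <- (genotype_matrix(cohort, ped$father) +
              genotype_matrix(cohort, ped$mother)) / 2
  keep_off <- !is.na(y)

  cache <- new.env(parent = emptyenv())
  eval_window <- function(idx) {
    key <- paste(idx, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    X <- g_exp[keep_off, idx, drop = FALSE]
    cc <- complete.cases(X)
    wts <- fit_burden_weights(X[cc, , drop = FALSE], y[keep_off][cc],
                              lambda_policy = lambda_policy, seed = seed)
    z0 <- fbat_burden_z(cohort$haplotypes, cohort, idx, wts$b, mu = mu)
    zk <- vapply(kos$matrices, function(h) {
      fbat_burden_z(h, cohort, idx, wts$b, mu = mu)$Z
    }, numeric(1))
    st <- window_statistic(z0$Z, zk)
    out <- list(n = sum(wts$b != 0), fallback = wts$fallback,
                Z = z0$Z, dir = z0$dir, Zstar = zk,
                W = st$W, p_burden = st$p_burden)
    cache[[key]] <- out
    out
  }

  res <- purrr::map(windows$variant_idx, eval_window)
  chrom <- cohort$variants$chrom[1L]
  out <- tibble::tibble(
    chrom = chrom,
    start = windows$start,
    end = windows$end,
    size = windows$size,
    n = purrr::map_int(res, "n"),
    dir = purrr::map_dbl(res, "dir"),
    W = purrr::map_dbl(res, "W"),
    Z = purrr::map_dbl(res, "Z"),
    p_burden = purrr::map_dbl(res, "p_burden"),
    fallback = purrr::map_lgl(res, "fallback"),
    Zstar = purrr::map(res, "Zstar")
  )
  out <- knockoff_fdr_select(out, q_target = q_target)
  out <- out[order(-replace(out$W, is.na(out$W), -Inf), out$p_burden), ]
  attr(out, "M") <- M
  attr(out, "q_target") <- q_target
  attr(out, "seed") <- seed
  attr(out, "blocks") <- blocks
  class(out) <- c("triokf_scan", class(out))
  out
}

#' Write scan results as a TSV mirroring the result-table schema
#'
#' Columns: chrom, start, end, n, Dir, W, p, Z, p.burden, q, selected.
#'
#' @param scan A `triokf_scan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  df <- data.frame(chrom = scan$chrom, start = scan$start, end = scan$end,
                   n = scan$n, Dir = scan$dir, W = scan$W,
                   p = scan$p_burden, Z = scan$Z, p.burden = scan$p_burden,
                   q = scan$q, selected = scan$selected,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
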