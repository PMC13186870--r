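#' Tile a region with half-overlapping scan windows
#'
#' For each size `s` windows start at `region_start + k * s/2`,
#' `k = 0, 1, ...`, while `start + s - 1 <= region_end`, so consecutive
#' windows of one size overlap by exactly half a window; when the tiling
#' would leave a tail of the region uncovered, a final window ending at
#' `region_end` is appended so every variant belongs to at least one window
#' per size.  Windows containing no variants are dropped.  If the region is
#' shorter than a requested size a single window clipped to the region is
#' produced and flagged.
#'
#' @param region_start,region_end 1-based inclusive region bounds in bp.
#' @param positions Variant positions used to attach member variants.
#' @param sizes Window sizes in bp (default the seven scan resolutions
#'   500, 1000, 2000, 5000, 10000, 15000 and 20000).
#' @return Tibble with columns `window_id`, `size`, `start`, `end`,
#'   `clipped` and list-column `variant_idx` of member variant indices.
#' @examples
#' make_windows(30820506, 30830000, positions = c(30821200, 30825000),
#'              sizes = c(500, 1000))
#' @export
make_windows <- function(region_start, region_end, positions,
                         sizes = c(500, 1000, 2000, 5000, 10000, 15000,
                                   20000)) {
  if (region_start > region_end) abort("region start must be <= end.")
  out <- list()
  for (s in sizes) {
    if (region_end - region_start + 1 < s) {
      starts <- region_start
      ends <- region_end
      clipped <- TRUE
    } else {
      starts <- seq(region_start, region_end - s + 1, by = s / 2)
      ends <- starts + s - 1
      # the tiling must cover every variant: close the tail with a final
      # window ending exactly at the region end
      if (max(ends) < region_end) {
        starts <- c(starts, region_end - s + 1)
        ends <- c(ends, region_end)
      }
      clipped <- FALSE
    }
    idx <- lapply(seq_along(starts), function(k) {
      which(positions >= starts[k] & positions <= ends[k])
    })
    keep <- lengths(idx) > 0L
    if (!any(keep)) next
    out[[length(out) + 1L]] <- tibble::tibble(
      size = s, start = starts[keep], end = ends[keep],
      clipped = clipped, variant_idx = idx[keep]
    )
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res))
    return(tibble::tibble(window_id = integer(), size = numeric(),
                          start = numeric(), end = numeric(),
                          clipped = logical(), variant_idx = list()))
  res$window_id <- seq_len(nrow(res))
  res[, c("window_id", "size", "start", "end", "clipped", "variant_idx")]
}
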