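#' Tidy a knockoff scan
#'
#' @param x A `triokf_scan`.
#' @param ... Unused.
#' @return A plain tibble with one row per window and the knockoff scores
#'   unnested into `Zstar_1..M` columns.
#' @method tidy triokf_scan
#' @export
tidy.triokf_scan <- function(x, ...) {
  M <- attr(x, "M")
  zs <- do.call(rbind, x$Zstar)
  colnames(zs) <- paste0("Zstar_", seq_len(ncol(zs)))
  out <- tibble::as_tibble(x[setdiff(names(x), "Zstar")])
  dplyr::bind_cols(out, tibble::as_tibble(zs))
}

#' One-row summary of a knockoff scan
#'
#' @param x A `triokf_scan`.
#' @param ... Unused.
#' @return Tibble with `n_windows`, `n_selected`, `M`, `q_target`,
#'   `median_W` and `min_p_burden`.
#' @method glance triokf_scan
#' @export
glance.triokf_scan <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x),
    n_selected = sum(x$selected, na.rm = TRUE),
    M = attr(x, "M"),
    q_target = attr(x, "q_target"),
    median_W = median(x$W, na.rm = TRUE),
    min_p_burden = suppressWarnings(min(x$p_burden, na.rm = TRUE))
  )
}

#' Tidy a power grid
#' @param x A `triokf_power`.
#' @param ... Unused.
#' @return The grid as a plain tibble.
#' @method tidy triokf_power
#' @export
tidy.triokf_power <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a power grid
#' @param x A `triokf_power`.
#' @param ... Unused.
#' @return Tibble with the study size, level and power range.
#' @method glance triokf_power
#' @export
glance.triokf_power <- function(x, ...) {
  tibble::tibble(
    n_trios = attr(x, "n_trios"),
    alpha = attr(x, "alpha"),
    min_power = min(x$power),
    max_power = max(x$power)
  )
}
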