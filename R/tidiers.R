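#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a selection scan into its per-window table
#'
#' @param x A `selection_scan` from [scan_selection()].
#' @param ... Unused.
#' @return The scored, classified window tibble.
#' @method tidy selection_scan
#' @export
tidy.selection_scan <- function(x, ...) {
  x$windows
}

#' One-row summary of a selection scan
#'
#' @param x A `selection_scan`.
#' @param ... Unused.
#' @return Tibble with window, significance and region counts, the
#'   composite-score threshold and the null provenance.
#' @method glance selection_scan
#' @export
glance.selection_scan <- function(x, ...) {
  w <- x$windows
  alpha <- x$params$alpha
  n_sig <- function(q) sum(!is.na(q) & q <= alpha)
  sig_any <- (!is.na(w$q_dpi) & w$q_dpi <= alpha) |
    (!is.na(w$q_fst) & w$q_fst <= alpha) |
    (!is.na(w$q_dtd) & w$q_dtd <= alpha)
  tibble::tibble(
    n_windows = nrow(w),
    n_sig_dpi = n_sig(w$q_dpi),
    n_sig_fst = n_sig(w$q_fst),
    n_sig_dtd = n_sig(w$q_dtd),
    n_sig_windows = sum(sig_any),
    n_regions = nrow(x$regions),
    n_regions_empirical = nrow(x$regions_empirical),
    cms_threshold = x$cms_threshold,
    null_sims = x$null$n_sims,
    null_mode = x$null$mode
  )
}

#' Tidy a null distribution into long format
#'
#' @param x A `null_dist`.
#' @param ... Unused.
#' @return Tibble with columns `statistic`, `value`.
#' @method tidy null_dist
#' @export
tidy.null_dist <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$stats), function(s) {
    tibble::tibble(statistic = s, value = x$stats[[s]])
  }))
}

#' One-row summary of a null distribution
#'
#' @param x A `null_dist`.
#' @param ... Unused.
#' @return Tibble with simulation counts, mode and per-statistic exclusions.
#' @method glance null_dist
#' @export
glance.null_dist <- function(x, ...) {
  tibble::tibble(
    n_sims = x$n_sims,
    mode = x$mode,
    seed = x$seed,
    window_bp = x$window_bp,
    excluded_dpi = x$n_excluded[["delta_pi"]],
    excluded_fst = x$n_excluded[["fst"]],
    excluded_dtd = x$n_excluded[["delta_td"]]
  )
}
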