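#' Empirical upper-tail p-values against a simulated null
#'
#' `p = #\{null >= obs\} / N`, by binary search on the sorted null; may be
#' exactly zero when the observation exceeds every simulated value.
#' Undefined observations give NA.
#'
#' @param obs Numeric vector of observed statistics (NA allowed).
#' @param null_sorted Ascending numeric vector of simulated null values.
#' @return Vector of p-values in `[0, 1]`.
#' @export
empirical_pvalues <- function(obs, null_sorted) {
  n <- length(null_sorted)
  if (n == 0) stop("empty null distribution", call. = FALSE)
  p <- (n - findInterval(obs, null_sorted, left.open = TRUE)) / n
  p[is.na(obs)] <- NA_real_
  p
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up FDR adjustment applied to the defined p-values (NA
#' entries are preserved and do not count toward the number of tests).
#'
#' @param p Numeric vector of p-values in `[0, 1]`, NA allowed.
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Composite-of-multiple-signals score from per-statistic q-values
#'
#' `CMS = (1 - q_dpi) * (1 - q_fst) * (1 - q_dtd)`, in `[0, 1]`; undefined
#' (NA) when any constituent q-value is undefined. Monotone non-increasing
#' in each q.
#'
#' @param q_dpi,q_fst,q_dtd q-values (vectors recycled to common length).
#' @return CMS scores.
#' @export
cms_1_fdr <- function(q_dpi, q_fst, q_dtd) {
  for (q in list(q_dpi, q_fst, q_dtd)) {
    if (any(q < 0 | q > 1, na.rm = TRUE)) {
      stop("q-values must lie in [0, 1]", call. = FALSE)
    }
  }
  (1 - q_dpi) * (1 - q_fst) * (1 - q_dtd)
}

#' Score observed windows against a neutral null
#'
#' Attaches, for each of the three statistics, the empirical upper-tail
#' p-value against the null and the genome-wide Benjamini-Hochberg q-value,
#' plus the composite score `cms`. Windows with an undefined Tajima's D
#' difference get NA p/q for that statistic and an NA `cms` (they are
#' excluded from composite ranking but keep their other q-values).
#'
#' @param stats Window-statistics tibble from [window_stats()].
#' @param null A `null_dist` from [simulate_null()].
#' @return `stats` with added columns `p_dpi`, `p_fst`, `p_dtd`, `q_dpi`,
#'   `q_fst`, `q_dtd`, `cms`.
#' @export
scan_windows <- function(stats, null) {
  stopifnot(inherits(null, "null_dist"))
  stats$p_dpi <- empirical_pvalues(stats$delta_pi, null$stats$delta_pi)
  stats$p_fst <- empirical_pvalues(stats$fst, null$stats$fst)
  stats$p_dtd <- empirical_pvalues(stats$delta_td, null$stats$delta_td)
  stats$q_dpi <- bh_adjust(stats$p_dpi)
  stats$q_fst <- bh_adjust(stats$p_fst)
  stats$q_dtd <- bh_adjust(stats$p_dtd)
  stats$cms <- cms_1_fdr(stats$q_dpi, stats$q_fst, stats$q_dtd)
  stats
}

#' Four-way window classification by composite score and FDR
#'
#' A window is "low-FDR" when at least one statistic has `q <= alpha`, and
#' "high-CMS" when its composite score reaches `cms_threshold` (typically
#' the minimum region-maximum score among the top-ranked regions, see
#' [cms_threshold_top_k()]). Windows with undefined `cms` are left NA, with
#' the count reported as a message.
#'
#' @param scan Scored window tibble from [scan_windows()].
#' @param cms_threshold Threshold on `cms`, in `[0, 1]`.
#' @param alpha Per-statistic FDR threshold (default 0.01).
#' @return `scan` with an added `class_label` column (factor with levels
#'   `low-CMS/high-FDR`, `high-CMS/high-FDR`, `low-CMS/low-FDR`,
#'   `high-CMS/low-FDR`).
#' @export
classify_windows <- function(scan, cms_threshold, alpha = 0.01) {
  stopifnot(cms_threshold >= 0, cms_threshold <= 1)
  qmin <- pmin(scan$q_dpi, scan$q_fst, scan$q_dtd, na.rm = TRUE)
  low_fdr <- qmin <= alpha
  high_cms <- scan$cms >= cms_threshold
  lab <- dplyr::case_when(
    is.na(scan$cms) ~ NA_character_,
    !high_cms & !low_fdr ~ "low-CMS/high-FDR",
    high_cms & !low_fdr ~ "high-CMS/high-FDR",
    !high_cms & low_fdr ~ "low-CMS/low-FDR",
    TRUE ~ "high-CMS/low-FDR"
  )
  n_na <- sum(is.na(scan$cms))
  if (n_na > 0) {
    message(n_na, " window(s) without a defined composite score left unclassified")
  }
  scan$class_label <- factor(lab, levels = c(
    "low-CMS/high-FDR", "high-CMS/high-FDR",
    "low-CMS/low-FDR", "high-CMS/low-FDR"
  ))
  scan
}
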