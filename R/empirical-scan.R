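#' Percentile ranks of a statistic
#'
#' `pct_i = #\{x <= x_i\} / N` over the defined values (maximum-rank tie
#' convention, so the largest value has percentile 1 and ties share the
#' higher percentile). NA values are excluded from ranking and propagated.
#'
#' @param x Numeric vector.
#' @return Percentiles in `(0, 1]`, NA where `x` is NA.
#' @export
percentile_rank <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) stop("no defined values to rank", call. = FALSE)
  out <- rep(NA_real_, length(x))
  out[ok] <- rank(x[ok], ties.method = "max") / sum(ok)
  out
}

#' Demography-free joint-percentile outlier statistics
#'
#' The empirical comparator to the model-based scan: each window's three
#' statistics are converted to percentile ranks, multiplied into a joint
#' product, and the product is itself percentile-ranked (`pct_joint`). The
#' joint empirical p-value is the fraction of windows with a product at
#' least as large. Windows with any undefined constituent (e.g. no
#' segregating sites in the sweep population) are excluded and carry NA.
#'
#' @param stats Window tibble with columns `fst`, `delta_pi`, `delta_td`.
#' @param top_frac Fraction flagged as outlier windows (default 0.01, the
#'   top 1%).
#' @return `stats` with added columns `pct_fst`, `pct_dpi`, `pct_dtd`,
#'   `product`, `pct_joint`, `p_joint`, `outlier`.
#' @export
joint_percentiles <- function(stats, top_frac = 0.01) {
  complete <- !(is.na(stats$fst) | is.na(stats$delta_pi) | is.na(stats$delta_td))
  pct <- function(x) {
    out <- rep(NA_real_, nrow(stats))
    out[complete] <- percentile_rank(x[complete])
    out
  }
  stats$pct_fst <- pct(stats$fst)
  stats$pct_dpi <- pct(stats$delta_pi)
  stats$pct_dtd <- pct(stats$delta_td)
  stats$product <- stats$pct_fst * stats$pct_dpi * stats$pct_dtd
  stats$pct_joint <- pct(stats$product)
  n <- sum(complete)
  p_joint <- rep(NA_real_, nrow(stats))
  p_joint[complete] <- rank(-stats$product[complete], ties.method = "max") / n
  stats$p_joint <- p_joint
  stats$outlier <- flag_top_fraction(stats$pct_joint, top_frac)
  stats
}

#' Flag the top fraction of windows by joint percentile
#'
#' Windows with `pct_joint > 1 - frac` are flagged. With heavy ties all tied
#' windows share a percentile, so a tie group is flagged in full or not at
#' all; the flagged count is reported when it deviates from `frac * N`.
#'
#' @param pct_joint Joint percentile vector (NA allowed).
#' @param frac Fraction in (0, 1).
#' @return Logical vector (NA where `pct_joint` is NA).
#' @export
flag_top_fraction <- function(pct_joint, frac = 0.01) {
  stopifnot(frac > 0, frac < 1)
  flag <- pct_joint > 1 - frac
  n_def <- sum(!is.na(pct_joint))
  n_flag <- sum(flag, na.rm = TRUE)
  if (n_def > 0 && abs(n_flag - frac * n_def) >= 1) {
    message(n_flag, " window(s) flagged in the top ", frac * 100,
            "% (ties shift the count from ", round(frac * n_def), ")")
  }
  flag
}
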