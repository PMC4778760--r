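#' Sliding-window layout
#'
#' @param size Window size in bp (default 100 kb).
#' @param step Step between window starts in bp (default 10 kb).
#' @param min_callable Minimum callable bp for a window to be retained
#'   (default 30 kb).
#' @return A `window_spec` list.
#' @export
window_spec <- function(size = 100000, step = 10000, min_callable = 30000) {
  if (step > size) stop("`step` must be <= `size`", call. = FALSE)
  if (min_callable <= 0 || min_callable > size) {
    stop("`min_callable` must be in (0, size]", call. = FALSE)
  }
  structure(list(size = size, step = step, min_callable = min_callable),
            class = "window_spec")
}

#' Enumerate sliding windows over contigs
#'
#' Windows are `[k * step, k * step + size)` for `k = 0, 1, ...` while the
#' start lies inside the contig; trailing partial windows are emitted
#' (clipped at the contig end) and later subject to the callable filter.
#'
#' @param contig_lengths Named numeric vector of contig lengths.
#' @param wspec A [window_spec()].
#' @return Tibble with `contig`, `start`, `end`.
#' @export
sliding_windows <- function(contig_lengths, wspec = window_spec()) {
  stopifnot(inherits(wspec, "window_spec"), all(contig_lengths > 0))
  out <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    starts <- seq(0, len - 1, by = wspec$step)
    tibble::tibble(contig = ctg, start = starts,
                   end = pmin(starts + wspec$size, len))
  })
  dplyr::bind_rows(out)
}

# Count of values in sorted `pos` strictly less than x (vectorized).
n_less <- function(x, pos) findInterval(x, pos, left.open = TRUE)

# Per-site pairwise-difference contributions for one population:
# c * (n - c) / choose(n, 2). Summed over a window this is the mean number
# of pairwise differences between chromosomes (Tajima's pi-hat).
site_pi_contrib <- function(c_alt, n) {
  if (n < 2) stop("need at least 2 chromosomes", call. = FALSE)
  c_alt * (n - c_alt) / choose(n, 2)
}

# Cross-population per-site contributions:
# [cA (nB - cB) + (nA - cA) cB] / (nA nB), the mean pairwise difference
# between one chromosome from each population.
site_dxy_contrib <- function(c_a, n_a, c_b, n_b) {
  (c_a * (n_b - c_b) + (n_a - c_a) * c_b) / (n_a * n_b)
}

#' Per-site nucleotide diversity within a population in one window
#'
#' \eqn{\pi = [\sum_s c_s (n - c_s) / C(n,2)] / L_{callable}}: the average
#' pairwise difference between chromosomes, per callable site.
#'
#' @param sites Site tibble with an `n_<pop>` count column.
#' @param pop Population name.
#' @param n Chromosome sample size of `pop`.
#' @param window Numeric `c(start, end)`, 0-based half-open.
#' @param callable_bp Callable length of the window (> 0).
#' @return Per-site diversity (numeric scalar).
#' @export
pi_within <- function(sites, pop, n, window, callable_bp) {
  if (callable_bp <= 0) return(NA_real_)
  keep <- sites$pos >= window[1] & sites$pos < window[2]
  sum(site_pi_contrib(sites[[paste0("n_", pop)]][keep], n)) / callable_bp
}

#' Per-site diversity between two populations in one window
#'
#' @inheritParams pi_within
#' @param pop_a,pop_b Population names.
#' @param n_a,n_b Chromosome sample sizes.
#' @return Per-site between-population diversity.
#' @export
pi_between <- function(sites, pop_a, n_a, pop_b, n_b, window, callable_bp) {
  if (callable_bp <= 0) return(NA_real_)
  keep <- sites$pos >= window[1] & sites$pos < window[2]
  sum(site_dxy_contrib(sites[[paste0("n_", pop_a)]][keep], n_a,
                       sites[[paste0("n_", pop_b)]][keep], n_b)) / callable_bp
}

#' FST from nucleotide diversities
#'
#' \eqn{F_{ST} = (\pi_{between} - \pi_{within}) / \pi_{between}} with
#' \eqn{\pi_{within}} the arithmetic mean of the two within-population
#' diversities (Hudson/Slatkin convention). Undefined (NA) when
#' \eqn{\pi_{between} = 0}; negative values are retained as-is.
#'
#' @param pi_b Between-population diversity (>= 0).
#' @param pi_1,pi_2 Within-population diversities (>= 0).
#' @return FST (vectorized).
#' @export
fst_from_pi <- function(pi_b, pi_1, pi_2) {
  if (any(stats::na.omit(c(pi_b, pi_1, pi_2)) < 0)) {
    stop("diversities must be non-negative", call. = FALSE)
  }
  pi_w <- (pi_1 + pi_2) / 2
  ifelse(!is.na(pi_b) & pi_b > 0, (pi_b - pi_w) / pi_b, NA_real_)
}

#' Tajima's D
#'
#' The standard normalized difference between the pairwise-difference and
#' segregating-sites estimators of the population mutation rate
#' (Tajima 1989). Undefined (NA) when `S = 0`.
#'
#' @param S Number of segregating sites in the window (vectorized).
#' @param pi_sum Mean number of pairwise differences between chromosomes in
#'   the window (sum over sites of `c(n-c)/C(n,2)`; not divided by length).
#' @param n Chromosome sample size (>= 2).
#' @return Tajima's D (vectorized over `S`, `pi_sum`).
#' @export
tajimas_d <- function(S, pi_sum, n) {
  if (n < 2) stop("Tajima's D requires n >= 2", call. = FALSE)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  # the variance constants cancel exactly for n <= 3, where D is undefined
  ifelse(S > 0 & v > 0, (pi_sum - S / a1) / sqrt(v), NA_real_)
}

#' Log diversity ratio between the reference and sweep populations
#'
#' \eqn{\ln(\pi_{ref} / \pi_{sweep})}; when the sweep population's diversity
#' is zero it is replaced by half the smallest attainable nonzero value,
#' `0.5 / (callable_bp * C(n_sweep, 2))`, so the ratio stays computable.
#' Undefined (NA) when the reference diversity is zero.
#'
#' @param pi_ref Diversity in the reference (e.g. wolf) population.
#' @param pi_sweep Diversity in the sweep (e.g. dog) population.
#' @param callable_bp Callable window length (> 0).
#' @param n_sweep Chromosome sample size of the sweep population.
#' @return Natural-log ratio (vectorized).
#' @export
delta_pi_log <- function(pi_ref, pi_sweep, callable_bp, n_sweep) {
  if (any(callable_bp <= 0, na.rm = TRUE)) {
    stop("`callable_bp` must be positive", call. = FALSE)
  }
  if (any(stats::na.omit(c(pi_ref, pi_sweep)) < 0)) {
    stop("diversities must be non-negative", call. = FALSE)
  }
  eps <- 0.5 / (callable_bp * choose(n_sweep, 2))
  denom <- ifelse(pi_sweep > 0, pi_sweep, eps)
  ifelse(!is.na(pi_ref) & pi_ref > 0, log(pi_ref / denom), NA_real_)
}

#' Window summary statistics for a sweep scan
#'
#' Computes, in overlapping sliding windows, within- and between-population
#' diversity, FST, Tajima's D per focal population, the log diversity ratio
#' (`delta_pi`, reference over sweep) and the Tajima's D difference
#' (`delta_td`, reference minus sweep), retaining windows whose callable
#' length is at least `wspec$min_callable`. `delta_td` (and both D values)
#' are NA where the corresponding population has no segregating sites.
#'
#' @param sites Site tibble from [read_genotypes()] (sites outside the mask
#'   are ignored).
#' @param mask Callable-mask interval tibble from [read_mask()].
#' @param spec A [pop_spec()]; statistics contrast `spec$focal[1]` (sweep)
#'   against `spec$focal[2]` (reference).
#' @param wspec A [window_spec()].
#' @param contig_lengths Optional named contig lengths; defaults to the mask
#'   extent per contig.
#' @return Tibble of retained windows with columns `contig`, `start`, `end`,
#'   `callable_bp`, `S_sweep`, `S_ref`, `pi_sweep`, `pi_ref`, `pi_between`,
#'   `fst`, `td_sweep`, `td_ref`, `delta_pi`, `delta_td`.
#' @export
window_stats <- function(sites, mask, spec, wspec = window_spec(),
                         contig_lengths = NULL) {
  stopifnot(inherits(spec, "pop_spec"), inherits(wspec, "window_spec"))
  mask <- normalize_intervals(mask)
  if (is.null(contig_lengths)) {
    contig_lengths <- vapply(split(mask$end, mask$contig), max, numeric(1))
  }
  windows <- sliding_windows(contig_lengths, wspec)
  windows$callable_bp <- callable_length(mask, windows)
  windows <- windows[windows$callable_bp >= wspec$min_callable, , drop = FALSE]
  if (nrow(windows) == 0) {
    warning("no windows pass the callable-length filter", call. = FALSE)
  }

  sweep_pop <- spec$focal[1]
  ref_pop <- spec$focal[2]
  n_s <- n_chrom(spec, sweep_pop)
  n_r <- n_chrom(spec, ref_pop)

  res <- vector("list", length(unique(windows$contig)))
  for (k in seq_along(unique(windows$contig))) {
    ctg <- unique(windows$contig)[k]
    w <- windows[windows$contig == ctg, , drop = FALSE]
    s <- sites[sites$contig == ctg, , drop = FALSE]
    m <- mask[mask$contig == ctg, , drop = FALSE]
    if (nrow(s) > 0) {
      # gate sites on the callable mask
      inside <- (coverage_before(s$pos + 1, m$start, m$end) -
                   coverage_before(s$pos, m$start, m$end)) > 0
      s <- s[inside, , drop = FALSE]
    }
    cs <- s[[paste0("n_", sweep_pop)]]
    cr <- s[[paste0("n_", ref_pop)]]
    # prefix sums of per-site contributions along the sorted positions
    P_pi_s <- c(0, cumsum(site_pi_contrib(cs, n_s)))
    P_pi_r <- c(0, cumsum(site_pi_contrib(cr, n_r)))
    P_dxy <- c(0, cumsum(site_dxy_contrib(cs, n_s, cr, n_r)))
    P_seg_s <- c(0, cumsum(as.numeric(cs > 0 & cs < n_s)))
    P_seg_r <- c(0, cumsum(as.numeric(cr > 0 & cr < n_r)))
    i1 <- n_less(w$start, s$pos) + 1
    i2 <- n_less(w$end, s$pos) + 1
    w$S_sweep <- P_seg_s[i2] - P_seg_s[i1]
    w$S_ref <- P_seg_r[i2] - P_seg_r[i1]
    pis_sum <- P_pi_s[i2] - P_pi_s[i1]
    pir_sum <- P_pi_r[i2] - P_pi_r[i1]
    w$pi_sweep <- pis_sum / w$callable_bp
    w$pi_ref <- pir_sum / w$callable_bp
    w$pi_between <- (P_dxy[i2] - P_dxy[i1]) / w$callable_bp
    w$fst <- fst_from_pi(w$pi_between, w$pi_sweep, w$pi_ref)
    w$td_sweep <- tajimas_d(w$S_sweep, pis_sum, n_s)
    w$td_ref <- tajimas_d(w$S_ref, pir_sum, n_r)
    w$delta_pi <- delta_pi_log(w$pi_ref, w$pi_sweep, w$callable_bp, n_s)
    w$delta_td <- w$td_ref - w$td_sweep
    res[[k]] <- w
  }
  dplyr::bind_rows(res)
}
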