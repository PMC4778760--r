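#' Sites fixed for the derived allele in the sweep lineage
#'
#' Identifies sites where every chromosome of the sweep population carries
#' the derived allele while every chromosome of the reference population and
#' the outgroup carries the ancestral allele (i.e. candidate lineage-specific
#' substitutions since the split). Requires polarized input (see
#' [polarize_sites()]); sites with unknown ancestral state are skipped.
#'
#' @param sites Polarized site tibble.
#' @param spec A [pop_spec()] with an outgroup.
#' @return Tibble of candidate fixed sites (`contig`, `pos`, `derived`
#'   allele and the count columns).
#' @export
find_fixed_derived <- function(sites, spec) {
  stopifnot(inherits(spec, "pop_spec"))
  if (!all(c("derived_is_alt", "ancestral_known") %in% names(sites))) {
    stop("`sites` is not polarized; run polarize_sites() first", call. = FALSE)
  }
  sweep_pop <- spec$focal[1]
  ref_pop <- spec$focal[2]
  n_s <- n_chrom(spec, sweep_pop)
  n_r <- n_chrom(spec, ref_pop)
  n_o <- n_chrom(spec, spec$outgroup)
  d_count <- function(pop, n) {
    c_alt <- sites[[paste0("n_", pop)]]
    ifelse(sites$derived_is_alt, c_alt, n - c_alt)
  }
  keep <- sites$ancestral_known &
    d_count(sweep_pop, n_s) == n_s &
    d_count(ref_pop, n_r) == 0L &
    d_count(spec$outgroup, n_o) == 0L
  keep[is.na(keep)] <- FALSE
  out <- sites[keep, , drop = FALSE]
  out$derived <- ifelse(out$derived_is_alt, out$alt, out$ref)
  out
}

#' Filter candidate fixed sites by derived-allele frequency in a panel
#'
#' @param candidates Tibble from [find_fixed_derived()].
#' @param panel_freqs Tibble `contig`, `pos`, `freq`: derived-allele
#'   frequency of each site among called panel chromosomes. Candidates
#'   absent from the panel are dropped (count reported).
#' @param min_freq Minimum panel frequency retained (default 0.75,
#'   inclusive).
#' @return Filtered tibble with a `panel_freq` column.
#' @export
filter_by_panel <- function(candidates, panel_freqs, min_freq = 0.75) {
  stopifnot(all(panel_freqs$freq >= 0 & panel_freqs$freq <= 1))
  m <- dplyr::left_join(
    candidates,
    dplyr::rename(panel_freqs[c("contig", "pos", "freq")], panel_freq = "freq"),
    by = c("contig", "pos")
  )
  n_missing <- sum(is.na(m$panel_freq))
  if (n_missing > 0) {
    message(n_missing, " candidate site(s) absent from the panel dropped")
  }
  m[!is.na(m$panel_freq) & m$panel_freq >= min_freq, , drop = FALSE]
}

#' Annotate fixed sites with outlier-region membership
#'
#' @param fixed Fixed-site tibble.
#' @param regions Region tibble (`contig`, `start`, `end`).
#' @return `fixed` with a logical `in_outlier` column.
#' @export
annotate_in_outlier <- function(fixed, regions) {
  in_out <- rep(FALSE, nrow(fixed))
  for (ctg in unique(fixed$contig)) {
    fi <- which(fixed$contig == ctg)
    r <- regions[regions$contig == ctg, , drop = FALSE]
    if (nrow(r) == 0) next
    pr <- IRanges::IRanges(r$start + 1, r$end)
    pp <- IRanges::IRanges(fixed$pos[fi] + 1, fixed$pos[fi] + 1)
    in_out[fi] <- IRanges::overlapsAny(pp, pr)
  }
  fixed$in_outlier <- in_out
  fixed
}

#' Functional-class enrichment of fixed sites in outlier regions
#'
#' Pearson chi-square test (no continuity correction) on the
#' classes-by-stratum contingency table, where the stratum is whether a
#' fixed site falls inside an outlier region. Classes with zero total are
#' dropped with a warning; at least two classes must remain.
#'
#' @param fixed Fixed-site tibble with columns `class` and `in_outlier`
#'   (see [annotate_in_outlier()]).
#' @return List with `statistic`, `df`, `p_value` and the contingency
#'   `table` (classes x outlier/non-outlier).
#' @export
functional_class_chi2 <- function(fixed) {
  stopifnot(all(c("class", "in_outlier") %in% names(fixed)))
  tab <- table(
    class = fixed$class,
    region = factor(ifelse(fixed$in_outlier, "outlier", "non_outlier"),
                    levels = c("outlier", "non_outlier"))
  )
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning("dropping empty class(es): ",
            paste(rownames(tab)[empty], collapse = ", "), call. = FALSE)
    tab <- tab[!empty, , drop = FALSE]
  }
  if (nrow(tab) < 2) {
    stop("need at least two functional classes for the test", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = unname(ct$p.value),
    table = tab
  )
}

#' Read per-site functional-class annotations
#'
#' @param path TSV with columns `contig`, `pos`, `class` (0-based
#'   positions; header expected).
#' @return Tibble of annotations.
#' @export
read_site_classes <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    contig = readr::col_character(),
    pos = readr::col_double(),
    class = readr::col_character()
  ), progress = FALSE)
}
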