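#' Read genotypes from VCF into a site table
#'
#' Retains biallelic SNVs at which every sample in `spec` has a called
#' genotype (the fully-observed rule: the chromosome sample size is then
#' constant across retained sites). Multiallelic records, indels and sites
#' with any missing call are dropped, with counts reported as messages.
#' VCF's 1-based positions are converted to 0-based on read.
#'
#' @param path Path to a VCF file containing all samples in `spec`.
#' @param spec A [pop_spec()]. Haploid samples must be encoded as
#'   single-allele genotype calls (e.g. `0`, `1`).
#' @return A site tibble with columns `contig`, `pos` (0-based), `ref`,
#'   `alt`, and one alternate-allele count column `n_<population>` per
#'   population.
#' @export
read_genotypes <- function(path, spec) {
  stopifnot(inherits(spec, "pop_spec"))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snv <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop_allelic <- sum(!snv)
  if (n_drop_allelic > 0) {
    message(n_drop_allelic, " non-biallelic-SNV record(s) dropped")
  }
  gt <- vcfR::extract.gt(v)
  missing_samples <- setdiff(spec$samples$sample, colnames(gt))
  if (length(missing_samples)) {
    stop("sample(s) missing from VCF: ", paste(missing_samples, collapse = ", "),
         call. = FALSE)
  }
  gt <- gt[, spec$samples$sample, drop = FALSE]
  gt <- gt[snv, , drop = FALSE]
  fix <- fix[snv, , drop = FALSE]
  if (nrow(gt) == 0) {
    return(empty_site_table(spec))
  }

  # per-sample allele matrices: alt count and called-allele count
  n_sites <- nrow(gt)
  alt_cnt <- matrix(0L, n_sites, ncol(gt))
  called <- matrix(0L, n_sites, ncol(gt))
  for (j in seq_len(ncol(gt))) {
    g <- gt[, j]
    g[is.na(g)] <- "."
    parts <- strsplit(g, "[/|]")
    len <- lengths(parts)
    exp_pl <- spec$samples$ploidy[j]
    bad_pl <- len != exp_pl & g != "."
    if (any(bad_pl)) {
      stop("ploidy mismatch for sample '", colnames(gt)[j], "': expected ",
           exp_pl, " allele(s), found ", len[which(bad_pl)[1]],
           call. = FALSE)
    }
    al <- unlist(parts)
    ok <- al %in% c("0", "1")
    av <- ifelse(ok, as.integer(ifelse(al == "1", 1L, 0L)), NA_integer_)
    idx <- rep(seq_len(n_sites), len)
    alt_cnt[, j] <- as.integer(rowsum(ifelse(is.na(av), 0L, av), idx,
                                      reorder = FALSE))
    called[, j] <- as.integer(rowsum(as.integer(!is.na(av)), idx,
                                     reorder = FALSE))
  }
  fully <- rowSums(called) == sum(spec$samples$ploidy)
  n_drop_missing <- sum(!fully)
  if (n_drop_missing > 0) {
    message(n_drop_missing, " site(s) dropped with missing genotypes")
  }
  alt_cnt <- alt_cnt[fully, , drop = FALSE]
  fix <- fix[fully, , drop = FALSE]
  if (nrow(fix) == 0) return(empty_site_table(spec))

  out <- tibble::tibble(
    contig = fix[, "CHROM"],
    pos = as.numeric(fix[, "POS"]) - 1,
    ref = fix[, "REF"],
    alt = fix[, "ALT"]
  )
  for (p in names(spec$n_chrom)) {
    cols <- which(spec$samples$population == p)
    out[[paste0("n_", p)]] <- as.integer(rowSums(alt_cnt[, cols, drop = FALSE]))
  }
  out <- dplyr::arrange(out, .data$contig, .data$pos)
  out
}

empty_site_table <- function(spec) {
  out <- tibble::tibble(contig = character(), pos = numeric(),
                        ref = character(), alt = character())
  for (p in names(spec$n_chrom)) out[[paste0("n_", p)]] <- integer()
  out
}

#' Orient site alleles as ancestral/derived using the outgroup
#'
#' The ancestral allele is the one fixed in the outgroup; sites where the
#' outgroup is polymorphic get `ancestral_known = FALSE`. Orientation does
#' not alter any diversity statistic; it is required for fixed-derived-site
#' analysis.
#'
#' @param sites A site tibble from [read_genotypes()].
#' @param spec A [pop_spec()] with an outgroup configured.
#' @return `sites` with added logical columns `derived_is_alt` and
#'   `ancestral_known`.
#' @export
polarize_sites <- function(sites, spec) {
  stopifnot(inherits(spec, "pop_spec"))
  if (is.null(spec$outgroup)) {
    stop("no outgroup configured in `spec`; cannot polarize", call. = FALSE)
  }
  n_out <- n_chrom(spec, spec$outgroup)
  c_out <- sites[[paste0("n_", spec$outgroup)]]
  sites$derived_is_alt <- dplyr::case_when(
    c_out == 0 ~ TRUE,
    c_out == n_out ~ FALSE,
    TRUE ~ NA
  )
  sites$ancestral_known <- !is.na(sites$derived_is_alt)
  sites
}

#' Write a site table back to VCF
#'
#' Reconstructs genotypes deterministically from per-population alternate
#' allele counts (alt alleles are assigned to the first chromosomes of each
#' population in sample order), so counts round-trip exactly through
#' [read_genotypes()] even though individual genotype layouts need not match
#' the original file.
#'
#' @param sites Site tibble.
#' @param spec A [pop_spec()].
#' @param path Output path.
#' @param contig_lengths Optional named vector used to emit `##contig` header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_site_vcf <- function(sites, spec, path, contig_lengths = NULL) {
  stopifnot(inherits(spec, "pop_spec"))
  ploidy <- spec$samples$ploidy
  pops <- spec$samples$population
  gt_cols <- matrix("", nrow(sites), nrow(spec$samples))
  for (p in unique(pops)) {
    js <- which(pops == p)
    cnt <- sites[[paste0("n_", p)]]
    # chromosome slots of population p, in sample order
    slots <- rep(js, ploidy[js])
    alleles <- outer(seq_along(slots), cnt, FUN = function(i, k) as.integer(i <= k))
    for (idx in seq_along(js)) {
      j <- js[idx]
      rows <- which(slots == j)
      gt_cols[, j] <- apply(alleles[rows, , drop = FALSE], 2, paste, collapse = "/")
    }
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepfdr",
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths))
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", spec$samples$sample), collapse = "\t")
  )
  body <- paste(
    sites$contig, format(sites$pos + 1, scientific = FALSE, trim = TRUE),
    ".", sites$ref, sites$alt, ".", "PASS", ".", "GT",
    apply(gt_cols, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}
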