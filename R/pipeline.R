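#' Run the full demography-aware sweep scan
#'
#' End-to-end driver: reads genotypes and mask, computes window statistics,
#' scores windows against the neutral null, calls and ranks candidate
#' regions, derives the top-k composite-score threshold, classifies
#' windows, and runs the demography-free joint-percentile comparator on the
#' same windows.
#'
#' @param vcf,mask Paths to the genotype VCF and callable-mask BED.
#' @param spec A [pop_spec()].
#' @param null A `null_dist` (see [simulate_null()]).
#' @param wspec A [window_spec()].
#' @param alpha Per-statistic FDR threshold for significance (default 0.01).
#' @param max_gap Region merge gap in bp (default 200 kb).
#' @param top_k Regions defining the composite-score threshold
#'   (default 100).
#' @param top_frac Outlier fraction for the empirical comparator
#'   (default 0.01).
#' @return A `selection_scan` object: list with `windows` (scored and
#'   classified scan tibble, including the joint-percentile columns),
#'   `regions` (ranked FDR-based regions), `regions_empirical` (ranked
#'   joint-percentile regions), `cms_threshold` and `params`.
#' @export
scan_selection <- function(vcf, mask, spec, null, wspec = window_spec(),
                           alpha = 0.01, max_gap = 200000, top_k = 100,
                           top_frac = 0.01) {
  sites <- read_genotypes(vcf, spec)
  mask_iv <- read_mask(mask)
  stats <- window_stats(sites, mask_iv, spec, wspec)
  scan <- scan_windows(stats, null)
  scan <- joint_percentiles(scan, top_frac = top_frac)

  regions <- call_regions(significant_windows(scan, alpha), max_gap)
  regions <- rank_regions(regions, scan, score = "cms")
  cms_thr <- if (nrow(regions) > 0) {
    suppressWarnings(cms_threshold_top_k(regions, top_k))
  } else {
    1
  }
  scan <- suppressMessages(classify_windows(scan, cms_thr, alpha))

  emp_windows <- scan[!is.na(scan$outlier) & scan$outlier,
                      c("contig", "start", "end")]
  regions_emp <- rank_regions(call_regions(emp_windows, max_gap), scan,
                              score = "pct_joint")

  structure(
    list(
      windows = scan,
      regions = regions,
      regions_empirical = regions_emp,
      cms_threshold = cms_thr,
      null = null[c("n_sims", "mode", "seed", "window_bp")],
      params = list(alpha = alpha, max_gap = max_gap, top_k = top_k,
                    top_frac = top_frac, wspec = wspec, spec = spec)
    ),
    class = "selection_scan"
  )
}

#' @export
print.selection_scan <- function(x, ...) {
  g <- glance(x)
  cat("<selection_scan> ", g$n_windows, " windows scanned (null: ",
      x$null$n_sims, " sims, ", x$null$mode, " mode)\n", sep = "")
  cat(sprintf("  significant at q<=%.3g: delta_pi %d, fst %d, delta_td %d (%d unique)\n",
              x$params$alpha, g$n_sig_dpi, g$n_sig_fst, g$n_sig_dtd,
              g$n_sig_windows))
  cat(sprintf("  regions: %d (FDR-based), %d (empirical top %.3g%%); CMS threshold %.4f\n",
              g$n_regions, g$n_regions_empirical, 100 * x$params$top_frac,
              x$cms_threshold))
  invisible(x)
}

#' Stage-wise pipeline driver over a file bundle
#'
#' Convenience orchestrator mirroring the analysis stages: `"null"`
#' simulates (or loads) the neutral null, `"scan"` runs [scan_selection()],
#' `"fixed-sites"` and `"enrich"` run the downstream analyses, `"all"` runs
#' everything. Outputs are written as TSV/BED files under `out_dir`
#' together with a manifest recording seeds and parameters.
#'
#' @param bundle List of input paths as produced by [generate_dataset()]
#'   (`vcf`, `mask`, `genes`, `terms`, `panel_pi`, `panel_freqs`,
#'   `site_classes`), or a bundle directory path.
#' @param out_dir Output directory.
#' @param spec A [pop_spec()].
#' @param model A [demographic_model()] for the null.
#' @param stage One of `"null"`, `"scan"`, `"fixed-sites"`, `"enrich"`,
#'   `"all"`.
#' @param null_reps Simulated null windows (default 5000).
#' @param seed Seed for the null simulation.
#' @param alpha,max_gap,top_k,top_frac,flank,panel_flank,min_panel_freq
#'   Analysis thresholds (defaults: 0.01, 200 kb, 100, 0.01, 25 kb, 500 kb,
#'   0.75).
#' @param wspec A [window_spec()].
#' @return Invisibly, a list of computed objects (`null`, `scan`, `fixed`,
#'   `enrichment`, depending on stage) plus output paths.
#' @export
run_pipeline <- function(bundle, out_dir, spec = default_pop_spec(),
                         model = canid_model(), stage = "all",
                         null_reps = 5000, seed = 1,
                         alpha = 0.01, max_gap = 200000, top_k = 100,
                         top_frac = 0.01, flank = 25000,
                         panel_flank = 500000, min_panel_freq = 0.75,
                         wspec = window_spec()) {
  stage <- match.arg(stage, c("null", "scan", "fixed-sites", "enrich", "all"))
  if (is.character(bundle) && length(bundle) == 1) {
    bundle <- bundle_paths(bundle)
  } else if (is.list(bundle) && !is.null(bundle$paths)) {
    bundle <- bundle$paths
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()

  null_path <- file.path(out_dir, "null.tsv")
  if (stage %in% c("null", "all")) {
    out$null <- simulate_null(model, null_reps, wspec$size, seed,
                              focal = spec$focal)
    write_null(out$null, null_path)
  } else if (file.exists(null_path)) {
    out$null <- read_null(null_path)
  } else {
    stop("no null distribution found at ", null_path,
         "; run stage 'null' first", call. = FALSE)
  }
  if (stage == "null") return(invisible(out))

  scan <- scan_selection(bundle$vcf, bundle$mask, spec, out$null, wspec,
                         alpha = alpha, max_gap = max_gap, top_k = top_k,
                         top_frac = top_frac)
  out$scan <- scan
  readr::write_tsv(scan$windows, file.path(out_dir, "scan_windows.tsv"),
                   progress = FALSE)
  flat_regions <- dplyr::select(scan$regions, -"windows", -"statistics")
  readr::write_tsv(flat_regions, file.path(out_dir, "regions.tsv"),
                   progress = FALSE)
  if (nrow(scan$regions) > 0) {
    write_regions_bed(scan$regions, file.path(out_dir, "regions.bed"))
  }
  if (stage == "scan") return(invisible(out))

  if (stage %in% c("fixed-sites", "all")) {
    sites <- read_genotypes(bundle$vcf, spec)
    sites <- polarize_sites(sites, spec)
    cand <- find_fixed_derived(sites, spec)
    panel <- readr::read_tsv(bundle$panel_freqs, col_types = "cdd",
                             progress = FALSE)
    fixed <- suppressMessages(filter_by_panel(cand, panel, min_panel_freq))
    classes <- read_site_classes(bundle$site_classes)
    fixed <- dplyr::inner_join(fixed,
                               classes, by = c("contig", "pos"))
    fixed <- annotate_in_outlier(fixed, scan$regions)
    out$fixed <- fixed
    out$fixed_test <- tryCatch(functional_class_chi2(fixed),
                               error = function(e) NULL)
    readr::write_tsv(fixed, file.path(out_dir, "fixed_sites.tsv"),
                     progress = FALSE)
  }
  if (stage %in% c("enrich", "all")) {
    genes <- read_genes(bundle$genes)
    terms <- read_term_map(bundle$terms)
    regions <- scan$regions
    if (!is.null(bundle$panel_pi) && file.exists(bundle$panel_pi)) {
      panel_pi <- readr::read_tsv(bundle$panel_pi, col_types = "cddd",
                                  progress = FALSE)
      regions <- validate_with_panel(regions, panel_pi, panel_flank)
      out$regions_validated <- regions
    }
    gs <- genes_near_peaks(regions, genes, flank = flank, top_k = top_k,
                           validated_only = "validation" %in% names(regions))
    enr <- enrichment_test(gs, terms, fdr_max_pct = 100)
    out$gene_set <- gs
    out$enrichment <- enr
    readr::write_tsv(dplyr::mutate(enr, genes = vapply(
      .data$genes, paste, character(1), collapse = ","
    )), file.path(out_dir, "enrichment.tsv"), progress = FALSE)
  }
  manifest <- list(
    seed = seed, null_reps = null_reps, alpha = alpha, max_gap = max_gap,
    top_k = top_k, top_frac = top_frac, flank = flank,
    panel_flank = panel_flank, min_panel_freq = min_panel_freq,
    window = unclass(wspec), stage = stage
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

bundle_paths <- function(dir) {
  list(
    vcf = file.path(dir, "genotypes.vcf"),
    mask = file.path(dir, "mask.bed"),
    genes = file.path(dir, "genes.gff3"),
    terms = file.path(dir, "terms.tsv"),
    panel_pi = file.path(dir, "panel_pi.tsv"),
    panel_freqs = file.path(dir, "panel_freqs.tsv"),
    site_classes = file.path(dir, "site_classes.tsv"),
    truth_sweeps = file.path(dir, "truth_sweeps.tsv"),
    truth_fixed = file.path(dir, "truth_fixed.tsv")
  )
}
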