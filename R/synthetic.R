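#' Configuration for the synthetic dataset generator
#'
#' Describes a complete simulated study: neutral two-population genomes
#' under the bottleneck demography of `model`, with sweep loci injected by
#' locally shrinking the sweep population's effective size (a demographic
#' emulation of hitchhiking: the crash epoch forces rapid coalescence
#' slightly in the past, producing reduced diversity, a rare-variant excess
#' and elevated differentiation in the sweep population), plus callable
#' masks, gene models, term maps, a diversity panel and fixed-site truth.
#'
#' @param contigs Named numeric vector of contig lengths (default two 10-Mb
#'   contigs).
#' @param model A [demographic_model()] (default [canid_model()]).
#' @param spec A [pop_spec()] matching `model$samples`.
#' @param sweeps Tibble `contig`, `center`, `width`, `intensity` of injected
#'   sweep loci (default 10 loci of width 100 kb and intensity 100, five per
#'   contig, 2 Mb apart). Loci must not overlap and must be separated by
#'   more than the merge gap plus window size; `intensity >= 1` is the fold
#'   reduction of the sweep population's size inside the locus (1 =
#'   neutral).
#' @param sweep_target Model population whose size is crashed inside sweep
#'   loci (default `"doganc"`, the dog stem: a domestication-era sweep that
#'   all dog lineages inherit, after which each lineage accumulates only
#'   rare post-sweep variants).
#' @param sweep_time Generations ago at which the emulated sweep completed
#'   (start of the crash epoch, default 820, just after the lineage split
#'   on the dog stem).
#' @param sweep_duration Length of the crash epoch in generations (default
#'   160, several coalescent units at the crashed size, so dog lineages
#'   almost always coalesce inside it).
#' @param mask_dropout Fraction of mask tiles dropped at random
#'   (default 0.15).
#' @param mask_tile Mask tile size in bp (default 2 kb).
#' @param gene_every Mean spacing of generated genes (default 50 kb).
#' @param gene_width Range of gene lengths (default 2-30 kb).
#' @param n_terms Number of annotation terms (default 40).
#' @param panel_chrom Chromosomes in the diversity panel (default 24, i.e.
#'   12 diploid genomes).
#' @param n_planted_fixed Number of planted sweep-lineage fixed sites
#'   (default 80; half inside sweep loci, panel frequencies straddling the
#'   0.75 retention threshold).
#' @param wspec A [window_spec()] used for the panel diversity grid.
#' @param seed Integer seed; the emitted bundle is byte-identical given the
#'   seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(contigs = c(chr1 = 1e7, chr2 = 1e7),
                             model = canid_model(),
                             spec = default_pop_spec(),
                             sweeps = default_sweeps(contigs),
                             sweep_target = "doganc",
                             sweep_time = 820,
                             sweep_duration = 160,
                             mask_dropout = 0.15,
                             mask_tile = 2000,
                             gene_every = 50000,
                             gene_width = c(2000, 30000),
                             n_terms = 40,
                             panel_chrom = 24,
                             n_planted_fixed = 80,
                             wspec = window_spec(),
                             seed = 1) {
  sweeps <- tibble::as_tibble(sweeps)
  if (nrow(sweeps) > 0) {
    stopifnot(all(sweeps$contig %in% names(contigs)),
              all(sweeps$intensity >= 1), all(sweeps$width > 0))
    for (ctg in unique(sweeps$contig)) {
      s <- sweeps[sweeps$contig == ctg, ]
      s <- s[order(s$center), ]
      lo <- s$center - s$width / 2
      hi <- s$center + s$width / 2
      if (any(lo < 0) || any(hi > contigs[[ctg]])) {
        stop("sweep locus outside contig ", ctg, call. = FALSE)
      }
      if (nrow(s) > 1 && any(lo[-1] < hi[-nrow(s)])) {
        stop("overlapping sweep loci on ", ctg, call. = FALSE)
      }
      min_sep <- 200000 + wspec$size
      if (nrow(s) > 1 && any(lo[-1] - hi[-nrow(s)] <= min_sep)) {
        stop("sweep loci on ", ctg, " closer than the merge gap plus window size",
             call. = FALSE)
      }
    }
  }
  if (!sweep_target %in% names(model$populations)) {
    stop("sweep_target '", sweep_target, "' is not a model population",
         call. = FALSE)
  }
  structure(
    list(contigs = contigs, model = model, spec = spec, sweeps = sweeps,
         sweep_target = sweep_target,
         sweep_time = sweep_time, sweep_duration = sweep_duration,
         mask_dropout = mask_dropout, mask_tile = mask_tile,
         gene_every = gene_every, gene_width = gene_width,
         n_terms = n_terms, panel_chrom = panel_chrom,
         n_planted_fixed = n_planted_fixed, wspec = wspec, seed = seed),
    class = "synthetic_config"
  )
}

#' Default injected sweep layout: five 100-kb loci per contig, 2 Mb apart
#'
#' @param contigs Named contig lengths.
#' @param intensity Fold size reduction inside each locus (default 100).
#' @param width Locus width in bp (default 100 kb).
#' @return Tibble `contig`, `center`, `width`, `intensity`.
#' @export
default_sweeps <- function(contigs, intensity = 100, width = 100000) {
  dplyr::bind_rows(lapply(names(contigs), function(ctg) {
    centers <- seq(1.5e6, contigs[[ctg]] - 0.5e6, by = 2e6)
    tibble::tibble(contig = ctg, center = centers, width = width,
                   intensity = intensity)
  }))
}

# Insert the crash epoch emulating a completed sweep into the model's
# sweep population.
sweep_model <- function(model, sweep_pop, intensity, t0, dur) {
  p <- model$populations[[sweep_pop]]
  n0 <- p$sizes[1]
  later <- p$times > t0 + dur
  model$populations[[sweep_pop]] <- list(
    times = c(0, t0, t0 + dur, p$times[later]),
    sizes = c(n0, n0 / intensity, n0, p$sizes[later])
  )
  model
}

job_seed <- function(seed, idx) {
  s <- (as.numeric(seed) * 10007 + idx * 7919) %% 2147483646
  as.integer(s) + 1L
}

#' Generate a complete synthetic study bundle
#'
#' Simulates genotypes for every contig (neutral background plus sweep
#' segments under the locally modified model), plants additional
#' sweep-lineage fixed sites, and writes the full file bundle the pipeline
#' consumes: `genotypes.vcf`, `mask.bed`, `genes.gff3`, `terms.tsv`,
#' `panel_pi.tsv`, `panel_freqs.tsv`, `site_classes.tsv`,
#' `truth_sweeps.tsv`, `truth_fixed.tsv` and `manifest.json`.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file `paths`, the `truth_sweeps` and
#'   `truth_fixed` tibbles and the config.
#' @export
generate_dataset <- function(cfg, dir = tempfile("synthdata")) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::local_seed(cfg$seed)
  spec <- cfg$spec
  sweep_pop <- spec$focal[1]

  # ---- simulation jobs: per-contig segments, sweeps under modified model
  segs <- list()
  for (ctg in names(cfg$contigs)) {
    L <- cfg$contigs[[ctg]]
    s <- cfg$sweeps[cfg$sweeps$contig == ctg, , drop = FALSE]
    s <- s[order(s$center), , drop = FALSE]
    bounds <- c(0, as.vector(rbind(s$center - s$width / 2,
                                   s$center + s$width / 2)), L)
    for (i in seq_len(length(bounds) - 1)) {
      if (bounds[i] >= bounds[i + 1]) next
      is_sweep <- i %% 2 == 0
      segs[[length(segs) + 1]] <- list(
        contig = ctg, start = bounds[i], end = bounds[i + 1],
        intensity = if (is_sweep) s$intensity[i / 2] else 1
      )
    }
  }
  jobs <- lapply(seq_along(segs), function(i) {
    sg <- segs[[i]]
    m <- if (sg$intensity > 1) {
      sweep_model(cfg$model, cfg$sweep_target, sg$intensity, cfg$sweep_time,
                  cfg$sweep_duration)
    } else {
      cfg$model
    }
    list(id = paste0("seg", i), model = m, n_reps = 1,
         sequence_length = sg$end - sg$start, seed = job_seed(cfg$seed, i))
  })
  sim <- run_sim_jobs(jobs, mode = "haplotypes", discrete = TRUE)

  # ---- assemble the haplotype matrix with global coordinates
  seg_idx <- as.integer(sub("^seg", "", sim$job))
  sim$contig <- vapply(segs, `[[`, character(1), "contig")[seg_idx]
  sim$gpos <- sim$pos + vapply(segs, `[[`, numeric(1), "start")[seg_idx]
  n_hap <- sum(spec$samples$ploidy)
  H <- matrix(as.integer(unlist(strsplit(sim$gt, ""), use.names = FALSE)),
              ncol = n_hap, byrow = TRUE)
  sites <- tibble::tibble(contig = sim$contig, pos = sim$gpos)

  # ---- planted sweep-lineage fixed sites
  pops_order <- names(cfg$model$samples)
  hap_model_pop <- rep(pops_order, as.integer(cfg$model$samples[pops_order]))
  # map model populations to statistic populations
  stat_of <- stats::setNames(pops_order, pops_order)
  if (!is.null(cfg$model$stat_groups)) {
    for (g in names(cfg$model$stat_groups)) {
      stat_of[cfg$model$stat_groups[[g]]] <- g
    }
  }
  hap_pop <- unname(stat_of[hap_model_pop])
  in_sweep_locus <- function(ctg, pos) {
    out <- rep(FALSE, length(pos))
    s <- cfg$sweeps
    for (i in seq_len(nrow(s))) {
      out <- out | (ctg == s$contig[i] &
                      pos >= s$center[i] - s$width[i] / 2 &
                      pos < s$center[i] + s$width[i] / 2)
    }
    out
  }
  n_plant <- cfg$n_planted_fixed
  if (n_plant > 0) {
    n_in <- if (nrow(cfg$sweeps) > 0) floor(n_plant / 2) else 0L
    plant_pos <- function(n, inside) {
      got <- tibble::tibble(contig = character(), pos = numeric())
      while (nrow(got) < n) {
        ctg <- sample(names(cfg$contigs), n, replace = TRUE)
        pos <- floor(stats::runif(n, 0, cfg$contigs[ctg]))
        keep <- in_sweep_locus(ctg, pos) == inside
        cand <- tibble::tibble(contig = ctg[keep], pos = pos[keep])
        got <- dplyr::distinct(dplyr::bind_rows(got, cand))
        got <- dplyr::anti_join(got, sites, by = c("contig", "pos"))
      }
      got[seq_len(n), ]
    }
    planted <- dplyr::bind_rows(
      if (n_in > 0) plant_pos(n_in, TRUE),
      plant_pos(n_plant - n_in, FALSE)
    )
    Hp <- matrix(rep(as.integer(hap_pop == sweep_pop), each = n_plant),
                 nrow = n_plant)
    sites <- dplyr::bind_rows(sites, planted)
    H <- rbind(H, Hp)
  }
  ord <- order(sites$contig, sites$pos)
  sites <- sites[ord, ]
  H <- H[ord, , drop = FALSE]

  # ---- REF/ALT bases (allele 0 is always REF; outgroup carries 0 except
  # where back-structure arose in simulation)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nrow(sites), replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  sites$ref <- ref
  sites$alt <- unname(alt)

  # ---- VCF
  vcf_path <- file.path(dir, "genotypes.vcf")
  write_hap_vcf(sites, H, spec, hap_pop, vcf_path, cfg$contigs)

  # ---- fixed-site truth from the haplotype matrix
  per_pop <- lapply(unique(hap_pop), function(p) H[, hap_pop == p, drop = FALSE])
  names(per_pop) <- unique(hap_pop)
  mono <- function(M) {
    rng <- row_range(M)
    ifelse(rng[, 1] == rng[, 2], rng[, 1], NA_integer_)
  }
  a_sweep <- mono(per_pop[[sweep_pop]])
  a_ref <- mono(per_pop[[spec$focal[2]]])
  a_out <- mono(per_pop[[spec$outgroup]])
  is_fixed <- !is.na(a_sweep) & !is.na(a_ref) & !is.na(a_out) &
    a_ref == a_out & a_sweep != a_ref
  truth_fixed <- sites[is_fixed, c("contig", "pos", "ref", "alt")]
  truth_fixed$derived <- ifelse(a_sweep[is_fixed] == 1L,
                                truth_fixed$alt, truth_fixed$ref)
  truth_fixed$in_sweep <- in_sweep_locus(truth_fixed$contig, truth_fixed$pos)
  is_planted <- !is.na(dplyr::left_join(
    truth_fixed[c("contig", "pos")],
    if (n_plant > 0) dplyr::mutate(planted, .pl = TRUE)
      else tibble::tibble(contig = character(), pos = numeric(), .pl = logical()),
    by = c("contig", "pos")
  )$.pl)
  # panel frequencies: planted sites straddle the 0.75 threshold, natural
  # fixed sites sit high (they are fixed in the basal sweep lineage)
  nf <- nrow(truth_fixed)
  k_panel <- integer(nf)
  k_panel[is_planted] <- sample(
    rep(c(18L, 21L, 24L, 10L, 14L, 17L), length.out = sum(is_planted))
  )
  k_panel[!is_planted] <- pmin(
    cfg$panel_chrom,
    stats::rbinom(sum(!is_planted), cfg$panel_chrom, 0.88)
  )
  truth_fixed$panel_freq <- k_panel / cfg$panel_chrom
  # functional classes: 10-class vocabulary, shifted inside sweep loci
  classes <- c("upstream_1kb", "utr5", "synonymous", "non_synonymous",
               "intron", "utr3", "downstream_1kb", "splice_region",
               "intergenic", "ncRNA")
  p_out <- c(0.5, 1, 2, 1, 29, 1, 0.5, 0.5, 62, 2.5)
  p_in <- c(2, 2, 3, 3, 38, 2, 1.5, 1, 44, 3.5)
  truth_fixed$class <- ifelse(
    truth_fixed$in_sweep,
    sample(classes, nf, replace = TRUE, prob = p_in),
    sample(classes, nf, replace = TRUE, prob = p_out)
  )
  truth_fixed$retained <- truth_fixed$panel_freq >= 0.75
  readr::write_tsv(truth_fixed, file.path(dir, "truth_fixed.tsv"),
                   progress = FALSE)
  readr::write_tsv(truth_fixed[c("contig", "pos", "panel_freq")] |>
                     dplyr::rename(freq = "panel_freq"),
                   file.path(dir, "panel_freqs.tsv"), progress = FALSE)
  readr::write_tsv(truth_fixed[c("contig", "pos", "class")],
                   file.path(dir, "site_classes.tsv"), progress = FALSE)

  # ---- callable mask: random tile dropout
  mask <- dplyr::bind_rows(lapply(names(cfg$contigs), function(ctg) {
    L <- cfg$contigs[[ctg]]
    starts <- seq(0, L - 1, by = cfg$mask_tile)
    keep <- stats::runif(length(starts)) >= cfg$mask_dropout
    tibble::tibble(contig = ctg, start = starts[keep],
                   end = pmin(starts[keep] + cfg$mask_tile, L))
  }))
  mask <- normalize_intervals(mask)
  mask_path <- file.path(dir, "mask.bed")
  writeLines(sprintf("%s\t%d\t%d", mask$contig, as.integer(mask$start),
                     as.integer(mask$end)), mask_path)

  # ---- gene models and term map
  genes <- dplyr::bind_rows(lapply(names(cfg$contigs), function(ctg) {
    L <- cfg$contigs[[ctg]]
    centers <- seq(cfg$gene_every / 2, L - cfg$gene_every / 2,
                   by = cfg$gene_every)
    centers <- centers + floor(stats::runif(length(centers),
                                            -cfg$gene_every / 5,
                                            cfg$gene_every / 5))
    len <- floor(stats::runif(length(centers), cfg$gene_width[1],
                              cfg$gene_width[2]))
    start <- pmax(0, floor(centers - len / 2))
    tibble::tibble(contig = ctg, start = start,
                   end = pmin(start + len, L))
  }))
  genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
  gff_path <- file.path(dir, "genes.gff3")
  writeLines(c(
    "##gff-version 3",
    sprintf("%s\tsweepfdr\tgene\t%d\t%d\t.\t+\t.\tID=%s;Name=%s",
            genes$contig, as.integer(genes$start + 1), as.integer(genes$end),
            genes$gene_id, genes$gene_id)
  ), gff_path)
  terms <- sprintf("T%03d", seq_len(cfg$n_terms))
  gene_in_sweep <- in_sweep_locus(genes$contig, (genes$start + genes$end) / 2)
  term_rows <- lapply(seq_len(nrow(genes)), function(i) {
    t <- sample(terms, sample(1:3, 1))
    if (gene_in_sweep[i] && stats::runif(1) < 0.8) t <- unique(c(t, terms[1]))
    tibble::tibble(gene_id = genes$gene_id[i], term_id = t)
  })
  term_path <- file.path(dir, "terms.tsv")
  tm <- dplyr::bind_rows(term_rows)
  readr::write_tsv(tm, term_path, col_names = FALSE, progress = FALSE)

  # ---- panel window diversity: lognormal baseline, reduced in sweep loci
  grid <- sliding_windows(cfg$contigs, cfg$wspec)
  base_pi <- 6e-4
  grid$pi <- base_pi * exp(stats::rnorm(nrow(grid), 0, 0.3))
  mid_in <- in_sweep_locus(grid$contig, (grid$start + grid$end) / 2)
  grid$pi[mid_in] <- grid$pi[mid_in] * 0.15
  panel_path <- file.path(dir, "panel_pi.tsv")
  readr::write_tsv(grid, panel_path, progress = FALSE)

  # ---- sweep truth and manifest
  truth_sweeps <- dplyr::mutate(
    cfg$sweeps,
    start = .data$center - .data$width / 2,
    end = .data$center + .data$width / 2
  )
  readr::write_tsv(truth_sweeps, file.path(dir, "truth_sweeps.tsv"),
                   progress = FALSE)
  paths <- list(
    vcf = vcf_path, mask = mask_path, genes = gff_path, terms = term_path,
    panel_pi = panel_path,
    panel_freqs = file.path(dir, "panel_freqs.tsv"),
    site_classes = file.path(dir, "site_classes.tsv"),
    truth_sweeps = file.path(dir, "truth_sweeps.tsv"),
    truth_fixed = file.path(dir, "truth_fixed.tsv")
  )
  manifest <- list(
    seed = cfg$seed,
    config_hash = rlang::hash(unclass(cfg)),
    n_sites = nrow(sites),
    files = vapply(paths, basename, character(1))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = dir, paths = paths, truth_sweeps = truth_sweeps,
                 truth_fixed = truth_fixed, config = cfg))
}

# rowRanges for an integer matrix without extra deps
row_range <- function(M) {
  cbind(apply(M, 1, min), apply(M, 1, max))
}

#' Fixed-site truth table of a generated bundle
#'
#' Lists, by construction at generation time, every site in the bundle that
#' satisfies the sweep-lineage fixed-derived criteria together with its
#' planted panel frequency, functional class and whether the 0.75 panel
#' filter retains it.
#'
#' @param bundle Either the list returned by [generate_dataset()] or a
#'   bundle directory path.
#' @return Tibble of fixed-site truth records.
#' @export
generate_fixed_site_truth <- function(bundle) {
  path <- if (is.list(bundle)) bundle$paths$truth_fixed
    else file.path(bundle, "truth_fixed.tsv")
  readr::read_tsv(path, col_types = readr::cols(
    contig = readr::col_character(), pos = readr::col_double(),
    .default = readr::col_guess()
  ), progress = FALSE)
}

# Write a VCF from a 0/1 haplotype matrix (rows = sites, columns =
# chromosomes in model sample order). `hap_pop` labels each column with
# its statistic population; the samples of each population consume its
# columns in order.
write_hap_vcf <- function(sites, H, spec, hap_pop, path, contig_lengths) {
  col_of <- integer(0)
  sample_names <- character(0)
  ploidies <- integer(0)
  used <- stats::setNames(rep(0L, length(unique(hap_pop))), unique(hap_pop))
  for (r in seq_len(nrow(spec$samples))) {
    p <- spec$samples$population[r]
    pl <- spec$samples$ploidy[r]
    cols_p <- which(hap_pop == p)
    take <- cols_p[used[[p]] + seq_len(pl)]
    if (anyNA(take)) {
      stop("sample ploidies exceed simulated chromosomes for population ", p,
           call. = FALSE)
    }
    used[[p]] <- used[[p]] + pl
    col_of <- c(col_of, take)
    sample_names <- c(sample_names, spec$samples$sample[r])
    ploidies <- c(ploidies, pl)
  }
  gts <- matrix("", nrow(sites), length(sample_names))
  ci <- 1L
  for (k in seq_along(sample_names)) {
    if (ploidies[k] == 2) {
      gts[, k] <- paste0(H[, col_of[ci]], "/", H[, col_of[ci + 1]])
      ci <- ci + 2L
    } else {
      gts[, k] <- as.character(H[, col_of[ci]])
      ci <- ci + 1L
    }
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepfdr-synthetic",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            as.integer(contig_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  body <- paste(
    sites$contig, format(sites$pos + 1, scientific = FALSE, trim = TRUE),
    ".", sites$ref, sites$alt, ".", "PASS", ".", "GT",
    do.call(paste, c(split(gts, col(gts)), sep = "\t")),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}
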