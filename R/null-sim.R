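#' Specify a demographic model for neutral simulations
#'
#' Piecewise-constant population sizes with population splits and optional
#' migration, in backward time (generation 0 = present). Each population has
#' parallel `times`/`sizes` vectors: the size applies from that time
#' backward until the next epoch. Split events move derived populations into
#' an ancestral one.
#'
#' @param populations Named list; each element is `list(times =, sizes =)`
#'   with `times[1] == 0`, strictly increasing times, positive sizes
#'   (diploid effective sizes).
#' @param splits List of `list(time =, derived = c(...), ancestral =)`.
#' @param mutation_rate Per-bp, per-generation mutation rate.
#' @param recombination_rate Per-bp, per-generation recombination rate.
#' @param samples Named integer vector: chromosomes sampled per population;
#'   must match the population specification of the observed data when the
#'   null is used to calibrate a scan.
#' @param pulses Optional list of mass-migration pulses
#'   `list(time =, source =, dest =, proportion =)` (backward-time source).
#' @param migrations Optional list of continuous rates
#'   `list(source =, dest =, rate =)`.
#' @param stat_groups Optional named list pooling several sampled model
#'   populations into one statistic population (e.g. three basal dog
#'   lineages pooled as `dog`); `NULL` means model populations are used
#'   as-is.
#' @return A `demographic_model` list.
#' @export
demographic_model <- function(populations, splits = list(),
                              mutation_rate, recombination_rate,
                              samples, pulses = NULL, migrations = NULL,
                              stat_groups = NULL) {
  stopifnot(is.list(populations), length(populations) > 0,
            !is.null(names(populations)))
  for (nm in names(populations)) {
    p <- populations[[nm]]
    if (!all(c("times", "sizes") %in% names(p)) ||
        length(p$times) != length(p$sizes)) {
      stop("population '", nm, "': need parallel `times` and `sizes`",
           call. = FALSE)
    }
    if (p$times[1] != 0 || is.unsorted(p$times, strictly = TRUE)) {
      stop("population '", nm, "': times must start at 0 and increase",
           call. = FALSE)
    }
    if (any(p$sizes <= 0)) {
      stop("population '", nm, "': sizes must be positive", call. = FALSE)
    }
  }
  if (mutation_rate < 0 || recombination_rate < 0) {
    stop("rates must be non-negative", call. = FALSE)
  }
  if (!all(names(samples) %in% names(populations))) {
    stop("sampled population(s) missing from model: ",
         paste(setdiff(names(samples), names(populations)), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(stat_groups)) {
    members <- unlist(stat_groups)
    if (!all(members %in% names(samples))) {
      stop("stat_groups refer to unsampled population(s): ",
           paste(setdiff(members, names(samples)), collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(populations = populations, splits = splits,
         mutation_rate = mutation_rate,
         recombination_rate = recombination_rate,
         samples = samples, pulses = pulses, migrations = migrations,
         stat_groups = stat_groups),
    class = "demographic_model"
  )
}

# Pool per-model-population counts into statistic populations.
group_sites_counts <- function(sites, model) {
  if (is.null(model$stat_groups)) return(sites)
  for (g in names(model$stat_groups)) {
    cols <- paste0("n_", model$stat_groups[[g]])
    sites[[paste0("n_", g)]] <- as.integer(
      rowSums(as.matrix(sites[cols]))
    )
  }
  sites
}

# Chromosome sample size of a statistic population under the model.
group_n <- function(model, g) {
  if (is.null(model$stat_groups) || is.null(model$stat_groups[[g]])) {
    return(as.integer(model$samples[[g]]))
  }
  sum(as.integer(model$samples[model$stat_groups[[g]]]))
}

#' Bundled canid-style divergence-with-bottleneck model
#'
#' A desk-scale stylized model of the study design: three basal dog
#' lineages (two diploid breeds plus the haploid reference chromosome set)
#' that split from a bottlenecked dog stem shortly after domestication, a
#' wolf population, their large common ancestor, and a deeper outgroup
#' split. The three dog lineages are pooled into one `dog` statistic
#' population (`stat_groups`), mirroring a pooled multi-breed sample: their
#' long-separated branches mean a neutral window essentially never loses
#' all dog variation at once, so sweep-like nulls are rare — the regime the
#' calibrated scan assumes. Sizes and times are round numbers; an inferred
#' model for a real study should be supplied in its place.
#'
#' @param samples Chromosomes per model population (default 2 + 2 + 1 dog
#'   lineages, 6 wolf, 2 jackal, matching [default_pop_spec()]).
#' @param mutation_rate,recombination_rate Per-bp per-generation rates.
#' @return A [demographic_model()].
#' @export
canid_model <- function(samples = c(basenji = 2, dingo = 2, boxer = 1,
                                    wolf = 6, jackal = 2),
                        mutation_rate = 1e-8, recombination_rate = 1e-8) {
  demographic_model(
    populations = list(
      basenji = list(times = 0, sizes = 10000),
      dingo   = list(times = 0, sizes = 10000),
      boxer   = list(times = 0, sizes = 10000),
      doganc  = list(times = 0, sizes = 2500),
      wolf    = list(times = 0, sizes = 15000),
      anc     = list(times = 0, sizes = 35000),
      jackal  = list(times = 0, sizes = 15000),
      root    = list(times = 0, sizes = 30000)
    ),
    splits = list(
      list(time = 800, derived = c("basenji", "dingo", "boxer"),
           ancestral = "doganc"),
      list(time = 1000, derived = c("doganc", "wolf"), ancestral = "anc"),
      list(time = 25000, derived = c("anc", "jackal"), ancestral = "root")
    ),
    mutation_rate = mutation_rate,
    recombination_rate = recombination_rate,
    samples = samples,
    stat_groups = list(dog = c("basenji", "dingo", "boxer"),
                       wolf = "wolf", jackal = "jackal")
  )
}

# ---- python/msprime bridge ---------------------------------------------

python_binary <- function() {
  cand <- getOption("sweepfdr.python",
                    Sys.getenv("SWEEPFDR_PYTHON", unset = ""))
  if (nzchar(cand)) return(cand)
  for (p in c("python", "python3")) {
    if (nzchar(Sys.which(p))) return(Sys.which(p))
  }
  stop("no python interpreter found; set option 'sweepfdr.python'",
       call. = FALSE)
}

model_for_json <- function(model) {
  list(
    populations = lapply(model$populations, function(p) {
      list(times = as.list(p$times), sizes = as.list(p$sizes))
    }),
    splits = lapply(model$splits, function(s) {
      list(time = s$time, derived = as.list(s$derived), ancestral = s$ancestral)
    }),
    pulses = model$pulses,
    migrations = model$migrations,
    mutation_rate = model$mutation_rate,
    recombination_rate = model$recombination_rate,
    samples = as.list(model$samples)
  )
}

# Run a batch of simulation jobs through the bundled msprime script.
# jobs: list of list(id, model, n_reps, sequence_length, seed)
run_sim_jobs <- function(jobs, mode = c("counts", "haplotypes"),
                         discrete = FALSE) {
  mode <- match.arg(mode)
  script <- system.file("python", "sim_windows.py", package = "sweepfdr")
  if (!nzchar(script)) stop("bundled simulator script not found", call. = FALSE)
  out_tsv <- tempfile(fileext = ".tsv")
  cfg <- list(
    mode = mode, discrete = discrete, out = out_tsv,
    jobs = lapply(jobs, function(j) {
      list(id = j$id, n_reps = j$n_reps, sequence_length = j$sequence_length,
           seed = j$seed, model = model_for_json(j$model))
    })
  )
  cfg_json <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, cfg_json, auto_unbox = TRUE, digits = NA)
  status <- system2(python_binary(), c(script, cfg_json),
                    stdout = "", stderr = "")
  if (status != 0) stop("coalescent simulation failed (see stderr)", call. = FALSE)
  spec_cols <- if (mode == "haplotypes") {
    readr::cols(job = readr::col_character(), rep = readr::col_integer(),
                pos = readr::col_double(), gt = readr::col_character())
  } else {
    readr::cols(job = readr::col_character(), rep = readr::col_integer(),
                pos = readr::col_double(), .default = readr::col_integer())
  }
  res <- readr::read_tsv(out_tsv, progress = FALSE, col_types = spec_cols)
  unlink(c(out_tsv, cfg_json))
  res
}

# ---- null distributions ------------------------------------------------

# Compute the three scan statistics for many fully-callable windows given a
# long table of per-site counts (columns n_<pop>), grouped by `rep`.
# Uses the same per-site contribution kernels and statistic definitions as
# window_stats().
stats_by_rep <- function(sites, sweep_pop, ref_pop, n_s, n_r, window_bp,
                         n_reps) {
  cs <- sites[[paste0("n_", sweep_pop)]]
  cr <- sites[[paste0("n_", ref_pop)]]
  g <- factor(sites$rep, levels = 0:(n_reps - 1))
  agg <- function(x) as.numeric(tapply(x, g, sum, default = 0))
  pis_sum <- agg(site_pi_contrib(cs, n_s))
  pir_sum <- agg(site_pi_contrib(cr, n_r))
  dxy_sum <- agg(site_dxy_contrib(cs, n_s, cr, n_r))
  S_s <- agg(as.numeric(cs > 0 & cs < n_s))
  S_r <- agg(as.numeric(cr > 0 & cr < n_r))
  pi_s <- pis_sum / window_bp
  pi_r <- pir_sum / window_bp
  pi_b <- dxy_sum / window_bp
  tibble::tibble(
    rep = 0:(n_reps - 1),
    S_sweep = S_s, S_ref = S_r,
    pi_sweep = pi_s, pi_ref = pi_r, pi_between = pi_b,
    fst = fst_from_pi(pi_b, pi_s, pi_r),
    td_sweep = tajimas_d(S_s, pis_sum, n_s),
    td_ref = tajimas_d(S_r, pir_sum, n_r),
    delta_pi = delta_pi_log(pi_r, pi_s, window_bp, n_s),
    delta_td = tajimas_d(S_r, pir_sum, n_r) - tajimas_d(S_s, pis_sum, n_s)
  )
}

new_null_dist <- function(per_rep, mode, seed, model, window_bp) {
  stats <- list(
    delta_pi = sort(per_rep$delta_pi[!is.na(per_rep$delta_pi)]),
    fst = sort(per_rep$fst[!is.na(per_rep$fst)]),
    delta_td = sort(per_rep$delta_td[!is.na(per_rep$delta_td)])
  )
  structure(
    list(
      stats = stats,
      n_sims = nrow(per_rep),
      n_excluded = vapply(per_rep[c("delta_pi", "fst", "delta_td")],
                          function(x) sum(is.na(x)), integer(1)),
      mode = mode, seed = seed, window_bp = window_bp,
      sample_config = model$samples
    ),
    class = "null_dist"
  )
}

#' Simulate the neutral null distribution of the scan statistics
#'
#' Simulates independent, fully-callable neutral windows under the
#' demographic model (coalescent with recombination, infinite-sites
#' mutations via the bundled msprime bridge) and computes the log diversity
#' ratio, FST and the Tajima's D difference for each window with the same
#' statistic definitions applied to observed data. Windows where the
#' Tajima's D difference is undefined (no segregating sites in a focal
#' population) are excluded from that statistic's null, with the count
#' recorded in `n_excluded`.
#'
#' @param model A [demographic_model()]; must have a positive mutation rate
#'   and include both focal populations.
#' @param n_reps Number of simulated windows.
#' @param window_bp Window length in bp (default 100 kb).
#' @param seed Integer seed; results are reproducible given the seed.
#' @param focal Sweep and reference population names in the model.
#' @return A `null_dist` object: sorted statistic vectors plus provenance
#'   (`n_sims`, `n_excluded`, `mode = "fixed"`, `seed`).
#' @export
simulate_null <- function(model, n_reps, window_bp = 100000, seed = 1,
                          focal = c("dog", "wolf")) {
  stopifnot(inherits(model, "demographic_model"), n_reps >= 1)
  if (model$mutation_rate <= 0) {
    stop("mutation rate must be positive to simulate a null", call. = FALSE)
  }
  sites <- group_sites_counts(
    run_sim_jobs(list(list(id = "null", model = model, n_reps = n_reps,
                           sequence_length = window_bp, seed = seed))),
    model
  )
  per_rep <- stats_by_rep(sites, focal[1], focal[2],
                          group_n(model, focal[1]), group_n(model, focal[2]),
                          window_bp, n_reps)
  new_null_dist(per_rep, "fixed", seed, model, window_bp)
}

# Apply one row of posterior draws to a model template. Recognized names:
# N_<pop> (first-epoch size), N_<pop>_<k> (k-th epoch), T_split_<k>
# (k-th split time), mu, rec.
apply_draw <- function(model, draw, row_id) {
  bad <- function(msg) {
    stop("posterior draw row ", row_id, ": ", msg, call. = FALSE)
  }
  for (nm in names(draw)) {
    val <- draw[[nm]]
    if (is.na(val)) bad(paste0("NA value for ", nm))
    if (nm == "mu") {
      if (val <= 0) bad("mutation rate must be positive")
      model$mutation_rate <- val
    } else if (nm == "rec") {
      if (val < 0) bad("recombination rate must be non-negative")
      model$recombination_rate <- val
    } else if (grepl("^T_split_", nm)) {
      k <- as.integer(sub("^T_split_", "", nm))
      if (is.na(k) || k > length(model$splits)) bad(paste0("no split ", k))
      if (val <= 0) bad("split time must be positive")
      model$splits[[k]]$time <- val
    } else if (grepl("^N_", nm)) {
      rest <- sub("^N_", "", nm)
      k <- 1L
      pop <- rest
      if (grepl("_[0-9]+$", rest)) {
        k <- as.integer(sub("^.*_", "", rest))
        pop <- sub("_[0-9]+$", "", rest)
      }
      if (!pop %in% names(model$populations)) bad(paste0("unknown population ", pop))
      if (k > length(model$populations[[pop]]$sizes)) bad(paste0("no epoch ", k))
      if (val <= 0) bad("population size must be positive")
      model$populations[[pop]]$sizes[k] <- val
    } else {
      bad(paste0("unrecognized parameter ", nm))
    }
  }
  # epoch/split ordering must survive the draw
  times <- vapply(model$splits, `[[`, numeric(1), "time")
  if (is.unsorted(times)) bad("split times out of order")
  model
}

#' Simulate a null distribution integrating over posterior parameter draws
#'
#' Each row of `draws` overrides named parameters of the model template
#' (`N_<pop>`, `N_<pop>_<epoch>`, `T_split_<k>`, `mu`, `rec`) and is
#' simulated `reps_per_draw` times; the statistics are pooled across draws.
#'
#' @param model Model template ([demographic_model()]).
#' @param draws Data frame of parameter draws, one row per draw.
#' @param reps_per_draw Simulated windows per draw.
#' @inheritParams simulate_null
#' @return A `null_dist` with `mode = "posterior"`.
#' @export
simulate_null_posterior <- function(model, draws, reps_per_draw,
                                    window_bp = 100000, seed = 1,
                                    focal = c("dog", "wolf")) {
  stopifnot(inherits(model, "demographic_model"))
  draws <- tibble::as_tibble(draws)
  if (nrow(draws) == 0) stop("`draws` must have at least one row", call. = FALSE)
  jobs <- lapply(seq_len(nrow(draws)), function(i) {
    m <- apply_draw(model, as.list(draws[i, ]), i)
    list(id = paste0("draw", i), model = m, n_reps = reps_per_draw,
         sequence_length = window_bp, seed = seed + i)
  })
  sites <- run_sim_jobs(jobs)
  per_rep <- dplyr::bind_rows(lapply(seq_len(nrow(draws)), function(i) {
    s <- group_sites_counts(sites[sites$job == paste0("draw", i), ,
                                  drop = FALSE], jobs[[i]]$model)
    m <- jobs[[i]]$model
    stats_by_rep(s, focal[1], focal[2],
                 group_n(m, focal[1]), group_n(m, focal[2]),
                 window_bp, reps_per_draw)
  }))
  new_null_dist(per_rep, "posterior", seed, model, window_bp)
}

#' @export
print.null_dist <- function(x, ...) {
  cat("<null_dist> ", x$n_sims, " simulated ", x$window_bp, "-bp windows (",
      x$mode, " mode, seed ", x$seed, ")\n", sep = "")
  for (s in names(x$stats)) {
    cat(sprintf("  %-9s n=%d excluded=%d range=[%.3g, %.3g]\n", s,
                length(x$stats[[s]]), x$n_excluded[[s]],
                min(x$stats[[s]]), max(x$stats[[s]])))
  }
  invisible(x)
}

#' Write / read a null distribution as TSV plus a JSON provenance sidecar
#'
#' @param null A `null_dist`.
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @return `path` (write) or a `null_dist` (read).
#' @export
write_null <- function(null, path) {
  n <- max(lengths(null$stats))
  pad <- function(x) c(x, rep(NA_real_, n - length(x)))
  readr::write_tsv(tibble::tibble(
    delta_pi = pad(null$stats$delta_pi),
    fst = pad(null$stats$fst),
    delta_td = pad(null$stats$delta_td)
  ), path, progress = FALSE)
  meta <- null[c("n_sims", "n_excluded", "mode", "seed", "window_bp",
                 "sample_config")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_null
#' @export
read_null <- function(path) {
  tab <- readr::read_tsv(path, col_types = "ddd", progress = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(
      stats = lapply(tab, function(x) sort(x[!is.na(x)])),
      n_sims = meta$n_sims,
      n_excluded = unlist(meta$n_excluded),
      mode = meta$mode, seed = meta$seed, window_bp = meta$window_bp,
      sample_config = meta$sample_config
    ),
    class = "null_dist"
  )
}
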