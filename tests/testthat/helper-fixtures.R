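# Shared heavy fixtures, built once per test run and cached. All problem
# sizes here are the package's default desk-scale study conditions: a
# 5000-window neutral null, a 20-Mb genome with ten injected sweeps, and 50
# neutral replicate genomes for calibration checks.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

FX_NULL_SEED <- 101L
FX_DATA_SEED <- 42L
FX_NEUTRAL_SEED <- 7000L

# 5000 simulated neutral 100-kb windows under the bundled model.
fx_null <- function() {
  fx_get("null5000", function() {
    sweepfdr::simulate_null(sweepfdr::canid_model(), 5000, 100000,
                            seed = FX_NULL_SEED)
  })
}

# Small null for unit tests that only need a sane reference distribution.
fx_null_small <- function() {
  fx_get("null500", function() {
    sweepfdr::simulate_null(sweepfdr::canid_model(), 500, 100000,
                            seed = FX_NULL_SEED + 1)
  })
}

# Default sweep-injected synthetic study bundle (2 x 10 Mb, 10 sweeps).
fx_sweep_dataset <- function() {
  fx_get("sweep_ds", function() {
    dir <- file.path(tempdir(), "sweepfdr-fx-dataset")
    cfg <- sweepfdr::synthetic_config(seed = FX_DATA_SEED)
    suppressMessages(sweepfdr::generate_dataset(cfg, dir))
  })
}

# Full model-based + empirical scan of the sweep bundle.
fx_sweep_scan <- function() {
  fx_get("sweep_scan", function() {
    ds <- fx_sweep_dataset()
    suppressMessages(sweepfdr::scan_selection(
      ds$paths$vcf, ds$paths$mask, sweepfdr::default_pop_spec(), fx_null()
    ))
  })
}

# Ten independent 5000-window nulls used for the neutral-calibration
# replicates, so the realized false-trigger fraction estimates the design
# rate instead of a quantity conditional on a single null realization.
fx_calibration_nulls <- function(k = 10) {
  fx_get("calib_nulls", function() {
    model <- sweepfdr::canid_model()
    jobs <- lapply(seq_len(k), function(i) {
      list(id = paste0("null", i), model = model, n_reps = 5000,
           sequence_length = 100000, seed = 200 + i)
    })
    sites <- sweepfdr:::group_sites_counts(sweepfdr:::run_sim_jobs(jobs),
                                           model)
    lapply(seq_len(k), function(i) {
      per_rep <- sweepfdr:::stats_by_rep(
        sites[sites$job == paste0("null", i), ], "dog", "wolf",
        sweepfdr:::group_n(model, "dog"), sweepfdr:::group_n(model, "wolf"),
        100000, 5000
      )
      sweepfdr:::new_null_dist(per_rep, "fixed", 200 + i, model, 100000)
    })
  })
}

# Default-scale dataset with a single injected sweep: the few-sweeps
# regime in which the empirical top-1% is mostly neutral windows.
fx_single_sweep_scan <- function() {
  fx_get("single_sweep_scan", function() {
    dir <- file.path(tempdir(), "sweepfdr-fx-single")
    cfg <- sweepfdr::synthetic_config(
      sweeps = tibble::tibble(contig = "chr1", center = 5e6, width = 1e5,
                              intensity = 100),
      seed = FX_DATA_SEED + 1
    )
    ds <- suppressMessages(sweepfdr::generate_dataset(cfg, dir))
    suppressMessages(sweepfdr::scan_selection(
      ds$paths$vcf, ds$paths$mask, sweepfdr::default_pop_spec(), fx_null()
    ))
  })
}

# 50 fully neutral replicate genomes simulated under the same demographic
# model as the nulls (different seeds), scan r calibrated against null
# ((r - 1) mod 10) + 1. Simulated at the site-count level (two 10.2-Mb
# contigs, fully callable) and pushed through the same window/scan
# operations as observed data.
fx_neutral_scans <- function(n_reps = 50) {
  fx_get(paste0("neutral", n_reps), function() {
    model <- sweepfdr::canid_model()
    contigs <- c(chr1 = 10.2e6, chr2 = 10.2e6)
    jobs <- list()
    for (r in seq_len(n_reps)) {
      for (ci in seq_along(contigs)) {
        jobs[[length(jobs) + 1]] <- list(
          id = sprintf("g%d_%s", r, names(contigs)[ci]),
          model = model, n_reps = 1,
          sequence_length = contigs[[ci]],
          seed = FX_NEUTRAL_SEED + r * 10L + ci
        )
      }
    }
    sites_all <- sweepfdr:::group_sites_counts(
      sweepfdr:::run_sim_jobs(jobs), model
    )
    mask <- tibble::tibble(
      contig = names(contigs), start = 0, end = unname(contigs)
    )
    spec <- sweepfdr::default_pop_spec()
    nulls <- fx_calibration_nulls()
    lapply(seq_len(n_reps), function(r) {
      tabs <- lapply(seq_along(contigs), function(ci) {
        s <- sites_all[sites_all$job == sprintf("g%d_%s", r, names(contigs)[ci]), ]
        tibble::tibble(contig = names(contigs)[ci], pos = s$pos,
                       n_dog = s$n_dog, n_wolf = s$n_wolf,
                       n_jackal = s$n_jackal)
      })
      st <- sweepfdr::window_stats(dplyr::bind_rows(tabs), mask, spec)
      sweepfdr::scan_windows(st, nulls[[(r - 1) %% length(nulls) + 1]])
    })
  })
}
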