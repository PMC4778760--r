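test_that("demographic model construction validates its invariants", {
  expect_error(demographic_model(
    populations = list(a = list(times = c(5, 0), sizes = c(1, 2))),
    mutation_rate = 1e-8, recombination_rate = 1e-8, samples = c(a = 2)
  ), "times")
  expect_error(demographic_model(
    populations = list(a = list(times = 0, sizes = -5)),
    mutation_rate = 1e-8, recombination_rate = 1e-8, samples = c(a = 2)
  ), "positive")
  expect_error(demographic_model(
    populations = list(a = list(times = 0, sizes = 10)),
    mutation_rate = -1, recombination_rate = 1e-8, samples = c(a = 2)
  ), "non-negative")
  expect_error(demographic_model(
    populations = list(a = list(times = 0, sizes = 10)),
    mutation_rate = 1e-8, recombination_rate = 1e-8, samples = c(b = 2)
  ), "missing")

  m <- canid_model(mutation_rate = 0)
  expect_error(simulate_null(m, 10), "mutation rate")
})

test_that("neutral simulations match closed-form single-population expectations", {
  # two identical populations splitting one generation ago behave as one
  # panmictic population of size N: E[pi] = 4*N*mu per bp, E[TD] ~ 0,
  # E[FST] ~ 0
  N <- 10000
  mu <- 1e-8
  model <- demographic_model(
    populations = list(
      dog = list(times = 0, sizes = N),
      wolf = list(times = 0, sizes = N),
      anc = list(times = 0, sizes = N)
    ),
    splits = list(list(time = 1, derived = c("dog", "wolf"),
                       ancestral = "anc")),
    mutation_rate = mu, recombination_rate = 1e-8,
    samples = c(dog = 5, wolf = 6)
  )
  n_reps <- 400
  L <- 100000
  sites <- sweepfdr:::run_sim_jobs(list(list(
    id = "j", model = model, n_reps = n_reps, sequence_length = L, seed = 5
  )))
  per_rep <- sweepfdr:::stats_by_rep(sites, "dog", "wolf", 5, 6, L, n_reps)
  theta <- 4 * N * mu
  se_pi <- stats::sd(per_rep$pi_sweep) / sqrt(n_reps)
  expect_lt(abs(mean(per_rep$pi_sweep) - theta), 3 * se_pi + 1e-7)
  se_td <- stats::sd(per_rep$td_sweep, na.rm = TRUE) / sqrt(n_reps)
  expect_lt(abs(mean(per_rep$td_sweep, na.rm = TRUE)), 3 * se_td + 0.05)
  se_fst <- stats::sd(per_rep$fst) / sqrt(n_reps)
  expect_lt(abs(mean(per_rep$fst)), 3 * se_fst + 0.01)
})

test_that("per-replicate null statistics equal window_stats on the same sites", {
  model <- canid_model()
  n_reps <- 25
  L <- 100000
  sites <- sweepfdr:::group_sites_counts(sweepfdr:::run_sim_jobs(list(list(
    id = "j", model = model, n_reps = n_reps, sequence_length = L, seed = 9
  ))), model)
  per_rep <- sweepfdr:::stats_by_rep(sites, "dog", "wolf", 5, 6, L, n_reps)
  spec <- toy_spec()
  mask <- tibble::tibble(contig = "w", start = 0, end = L)
  for (r in c(0, 7, 24)) {
    s <- sites[sites$rep == r, ]
    tab <- tibble::tibble(contig = "w", pos = s$pos, n_dog = s$n_dog,
                          n_wolf = s$n_wolf, n_jackal = s$n_jackal)
    ws <- window_stats(tab, mask, spec, window_spec(L, L, L))
    expect_equal(ws$delta_pi, per_rep$delta_pi[r + 1], tolerance = 1e-12)
    expect_equal(ws$fst, per_rep$fst[r + 1], tolerance = 1e-12)
    expect_equal(ws$delta_td, per_rep$delta_td[r + 1], tolerance = 1e-12)
  }
})

test_that("null simulation is reproducible and records exclusions", {
  model <- canid_model()
  a <- simulate_null(model, 150, 50000, seed = 33)
  b <- simulate_null(model, 150, 50000, seed = 33)
  expect_identical(a$stats, b$stats)
  expect_equal(a$n_sims, 150)
  expect_equal(length(a$stats$delta_td) + a$n_excluded[["delta_td"]], 150L)

  # TSV + sidecar round trip
  path <- tempfile(fileext = ".tsv")
  write_null(a, path)
  back <- read_null(path)
  expect_equal(back$stats, a$stats)
  expect_equal(back$mode, "fixed")
  expect_equal(back$n_sims, a$n_sims)
})

test_that("posterior-draw mode pools draws and validates them", {
  model <- canid_model()
  draws <- tibble::tibble(N_doganc = c(2500, 2600))
  nd <- simulate_null_posterior(model, draws, reps_per_draw = 3, seed = 2)
  expect_equal(nd$n_sims, 6)
  expect_equal(nd$mode, "posterior")

  expect_error(simulate_null_posterior(model, draws[0, ], 3), "at least one")
  expect_error(
    simulate_null_posterior(model, tibble::tibble(N_doganc = c(2500, -1)), 2),
    "row 2"
  )
  expect_error(
    simulate_null_posterior(model, tibble::tibble(N_moose = 1), 2),
    "unknown population"
  )
})

test_that("a degenerate posterior reproduces the fixed-parameter null", {
  model <- canid_model()
  R <- 2000
  fixed <- simulate_null(model, R, 100000, seed = 71)
  post <- simulate_null_posterior(
    model, tibble::tibble(N_doganc = 2500), reps_per_draw = R,
    window_bp = 100000, seed = 72
  )
  for (s in c("delta_pi", "fst", "delta_td")) {
    ks <- suppressWarnings(stats::ks.test(fixed$stats[[s]], post$stats[[s]]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("FDR estimates from fixed and concentrated-posterior nulls agree", {
  # q-values for the same observed windows, against two independent nulls:
  # fixed parameters vs draws tightly concentrated around them. Nulls of
  # 20,000 windows keep Monte Carlo noise well below the q-value spread.
  model <- canid_model()
  fixed <- simulate_null(model, 20000, 100000, seed = 55)
  withr::local_seed(56)
  draws <- tibble::tibble(
    N_doganc = 2500 * exp(stats::rnorm(40, 0, 0.02)),
    N_wolf = 15000 * exp(stats::rnorm(40, 0, 0.02))
  )
  post <- simulate_null_posterior(model, draws, reps_per_draw = 500,
                                  window_bp = 100000, seed = 57)
  obs_tab <- fx_sweep_scan()$windows
  for (s in c("delta_pi", "fst", "delta_td")) {
    obs <- obs_tab[[s]]
    qf <- bh_adjust(empirical_pvalues(obs, fixed$stats[[s]]))
    qp <- bh_adjust(empirical_pvalues(obs, post$stats[[s]]))
    ok <- !is.na(qf) & !is.na(qp)
    expect_gt(stats::cor(qf[ok], qp[ok], method = "pearson"), 0.99)
  }
})

test_that("a harsher recent bottleneck right-shifts the null log diversity ratio", {
  mild <- canid_model()
  harsh <- canid_model()
  harsh$populations$doganc$sizes <- 250
  a <- simulate_null(mild, 2000, 100000, seed = 91)
  b <- simulate_null(harsh, 2000, 100000, seed = 92)
  expect_gt(mean(b$stats$delta_pi), mean(a$stats$delta_pi))
})
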