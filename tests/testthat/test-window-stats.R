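test_that("sliding windows tile contigs with clipped trailing partials", {
  w <- sliding_windows(c(c1 = 120000), window_spec())
  expect_equal(w$start, seq(0, 110000, 10000))
  expect_equal(max(w$end), 120000)

  w1 <- sliding_windows(c(c1 = 100000), window_spec())
  expect_equal(nrow(w1), 10L)            # one full window plus partials
  expect_equal(w1$end[1] - w1$start[1], 100000)

  expect_error(window_spec(size = 5, step = 10), "step")
  expect_error(window_spec(min_callable = 0), "min_callable")
})

test_that("diversity kernels agree with brute-force pair enumeration", {
  expect_equal(
    pi_within(tibble::tibble(contig = "c", pos = 0, n_popA = 2),
              "popA", 5, c(0, 10), 10),
    (2 * 3 / 10) / 10
  )
  mono <- tibble::tibble(contig = "c", pos = 0:4, n_popA = c(0, 0, 5, 5, 0))
  expect_equal(pi_within(mono, "popA", 5, c(0, 10), 10), 0)

  # fixed difference between populations over 1 callable bp
  fixed <- tibble::tibble(contig = "c", pos = 0, n_popA = 4, n_popB = 0)
  expect_equal(pi_between(fixed, "popA", 4, "popB", 6, c(0, 1), 1), 1)

  withr::local_seed(31)
  for (i in 1:50) {
    n_a <- sample(2:8, 1)
    n_b <- sample(2:8, 1)
    rs <- random_sites(sample(5:200, 1), n_a, n_b)
    L <- 1000
    expect_equal(
      pi_within(rs$sites, "popA", n_a, c(0, L), L),
      oracle_pi_within(rs$HA, L), tolerance = 1e-12
    )
    expect_equal(
      pi_between(rs$sites, "popA", n_a, "popB", n_b, c(0, L), L),
      oracle_pi_between(rs$HA, rs$HB, L), tolerance = 1e-12
    )
    S <- sum(rs$sites$n_popA > 0 & rs$sites$n_popA < n_a)
    pi_sum <- sum(rs$sites$n_popA * (n_a - rs$sites$n_popA) / choose(n_a, 2))
    td <- tajimas_d(S, pi_sum, n_a)
    td_oracle <- oracle_tajimas_d(rs$HA)
    if (!is.na(td_oracle) && is.finite(td_oracle)) {
      expect_equal(td, td_oracle, tolerance = 1e-12)
    } else {
      expect_true(is.na(td))   # D undefined: S = 0 or n <= 3
    }
  }
})

test_that("FST follows the diversity-ratio definition and its edge cases", {
  expect_equal(fst_from_pi(0.2, 0.1, 0.1), 0.5)
  expect_equal(fst_from_pi(0.2, 0.2, 0.2), 0)
  expect_equal(fst_from_pi(0.2, 0, 0), 1)   # only fixed differences
  expect_true(is.na(fst_from_pi(0, 0, 0)))
  expect_error(fst_from_pi(-0.1, 0.1, 0.1), "non-negative")
})

test_that("Tajima's D matches the independent constant-by-constant oracle", {
  expect_true(is.na(tajimas_d(0, 0, 6)))
  a1 <- sum(1 / 1:5)
  expect_equal(tajimas_d(10, 10 / a1, 6), 0)
  expect_equal(tajimas_d(10, 3.0, 6), -1.8919, tolerance = 1e-4)
  expect_error(tajimas_d(5, 1, 1), "n >= 2")
})

test_that("the log diversity ratio uses the half-difference floor", {
  expect_equal(delta_pi_log(0.002, 0.001, 10000, 5), log(2))
  expect_equal(delta_pi_log(0.003, 0.003, 10000, 5), 0)
  # pi_sweep = 0: denominator is 0.5 / (callable * C(n,2)) = 5e-6
  expect_equal(delta_pi_log(1, 0, 10000, 5), log(1 / 5e-6))
  expect_true(is.na(delta_pi_log(0, 0.001, 10000, 5)))
  expect_error(delta_pi_log(0.1, 0.1, 0, 5), "positive")
})

make_block_sites <- function(spec) {
  # 1 Mb contig, sites every 100 bp; a fully differentiated block in
  # [500kb, 600kb): dogs fixed derived, wolves fixed ancestral
  pos <- seq(0, 999900, by = 100)
  in_block <- pos >= 5e5 & pos < 6e5
  withr::local_seed(17)
  tibble::tibble(
    contig = "chr1", pos = pos,
    n_dog = ifelse(in_block, 5L, rbinom(length(pos), 5, 0.3)),
    n_wolf = ifelse(in_block, 0L, rbinom(length(pos), 6, 0.3)),
    n_jackal = 0L
  )
}

test_that("window_stats applies the callable filter at the 30-kb boundary", {
  spec <- toy_spec()
  sites <- make_block_sites(spec)
  # two disconnected contig-level masks: 29999 vs 30000 callable in window 1
  m1 <- tibble::tibble(contig = "chr1", start = 0, end = 29999)
  m2 <- tibble::tibble(contig = "chr1", start = 0, end = 30000)
  w1 <- suppressWarnings(window_stats(sites, m1, spec,
                                      window_spec(100000, 100000, 30000),
                                      contig_lengths = c(chr1 = 1e5)))
  w2 <- window_stats(sites, m2, spec, window_spec(100000, 100000, 30000),
                     contig_lengths = c(chr1 = 1e5))
  expect_equal(nrow(w1), 0L)
  expect_equal(nrow(w2), 1L)
  expect_equal(w2$callable_bp, 30000)
})

test_that("a fully differentiated block attains the maximum FST", {
  spec <- toy_spec()
  sites <- make_block_sites(spec)
  mask <- tibble::tibble(contig = "chr1", start = 0, end = 1e6)
  ws <- window_stats(sites, mask, spec)
  block <- ws$start >= 5e5 & ws$end <= 6e5
  expect_true(any(block))
  expect_equal(max(ws$fst), 1)
  expect_true(all(ws$fst[block] == max(ws$fst)))
  # direct recomputation of one block window via the scalar kernels
  i <- which(block)[1]
  expect_equal(
    ws$fst[i],
    fst_from_pi(
      pi_between(sites, "dog", 5, "wolf", 6, c(ws$start[i], ws$end[i]),
                 ws$callable_bp[i]),
      pi_within(sites, "dog", 5, c(ws$start[i], ws$end[i]), ws$callable_bp[i]),
      pi_within(sites, "wolf", 6, c(ws$start[i], ws$end[i]), ws$callable_bp[i])
    )
  )
})

test_that("statistics are invariant to sample order and antisymmetric in the focal pair", {
  spec <- toy_spec()
  sites <- make_block_sites(spec)
  mask <- tibble::tibble(contig = "chr1", start = 0, end = 1e6)
  ws <- window_stats(sites, mask, spec)

  # permuting samples within a population permutes genotype columns only;
  # counts (and hence every statistic) are unchanged
  perm <- spec$samples[c(2, 1, 3, 6, 4, 5, 7), ]
  spec_perm <- pop_spec(perm, focal = spec$focal, outgroup = spec$outgroup)
  ws_perm <- window_stats(sites, mask, spec_perm)
  expect_equal(ws_perm, ws)

  # swapping the focal pair negates the contrasts and preserves FST
  spec_swap <- pop_spec(spec$samples, focal = rev(spec$focal),
                        outgroup = spec$outgroup)
  ws_swap <- window_stats(sites, mask, spec_swap)
  expect_equal(ws_swap$fst, ws$fst)
  both <- !is.na(ws$delta_td)
  expect_equal(ws_swap$delta_td[both], -ws$delta_td[both])
  # delta_pi negates wherever neither diversity needed the zero floor
  clean <- ws$pi_sweep > 0 & ws$pi_ref > 0
  expect_equal(ws_swap$delta_pi[clean], -ws$delta_pi[clean])
})
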