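win <- function(contig, start, end, statistic = NA_character_) {
  tibble::tibble(contig = contig, start = start, end = end,
                 statistic = statistic)
}

test_that("region merging honors the gap rule at its boundary", {
  # gap 190 kb -> one region spanning the envelope
  r1 <- call_regions(dplyr::bind_rows(win("c", 0, 1e5), win("c", 2.9e5, 3.9e5)))
  expect_equal(nrow(r1), 1L)
  expect_equal(c(r1$start, r1$end), c(0, 3.9e5))

  # gap 210 kb -> two regions
  r2 <- call_regions(dplyr::bind_rows(win("c", 0, 1e5), win("c", 3.1e5, 4.1e5)))
  expect_equal(nrow(r2), 2L)

  # exactly 200 kb joins; one bp more splits
  expect_equal(nrow(call_regions(dplyr::bind_rows(
    win("c", 0, 1e5), win("c", 3e5, 4e5)))), 1L)
  expect_equal(nrow(call_regions(dplyr::bind_rows(
    win("c", 0, 1e5), win("c", 3e5 + 1, 4e5)))), 2L)

  # adjacent windows significant for different statistics merge, with both
  # statistics recorded
  r3 <- call_regions(dplyr::bind_rows(
    win("c", 0, 1e5, "delta_pi"), win("c", 1e5, 2e5, "delta_td")
  ))
  expect_equal(nrow(r3), 1L)
  expect_equal(r3$statistics[[1]], c("delta_pi", "delta_td"))
})

test_that("region calling is idempotent, order-invariant and transitive", {
  withr::local_seed(41)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    starts <- sort(sample(seq(0, 5e6, 1e4), n))
    w <- win(sample(c("c1", "c2"), n, replace = TRUE), starts, starts + 1e5,
             sample(c("delta_pi", "fst", "delta_td"), n, replace = TRUE))
    r <- call_regions(w)
    r_shuf <- call_regions(w[sample(nrow(w)), ])
    expect_equal(r_shuf, r)
    # every member window in exactly one region; regions mutually > gap apart
    expect_equal(sum(r$n_windows), nrow(dplyr::distinct(w)))
    for (ctg in unique(r$contig)) {
      rc <- r[r$contig == ctg, ]
      if (nrow(rc) > 1) {
        expect_true(all(rc$start[-1] - rc$end[-nrow(rc)] > 2e5))
      }
    }
    # re-merging the called regions changes nothing
    again <- call_regions(r[c("contig", "start", "end")])
    expect_equal(again[c("contig", "start", "end")],
                 r[c("contig", "start", "end")])
  }
})

test_that("regions rank by maximum member score with documented tie handling", {
  scan <- tibble::tibble(
    contig = "c", start = c(0, 1e4, 6e5, 1.2e6, 2.0e6),
    end = start + 1e5,
    cms = c(0.99, 0.95, 0.90, 0.90, 0.50)
  )
  regions <- call_regions(scan[c("contig", "start", "end")][c(1, 2), ])
  regions <- dplyr::bind_rows(
    regions,
    call_regions(scan[c("contig", "start", "end")][3, ]),
    call_regions(scan[c("contig", "start", "end")][4, ]),
    call_regions(scan[c("contig", "start", "end")][5, ])
  )
  ranked <- rank_regions(regions, scan)
  expect_equal(ranked$score, c(0.99, 0.90, 0.90, 0.50))
  expect_equal(ranked$rank, 1:4)
  # two regions tied at 0.90 display the average rank 2.5
  expect_equal(ranked$display_rank, c(1, 2.5, 2.5, 4))
  # the peak is the member window attaining the maximum, not the midpoint
  expect_equal(ranked$peak_start[1], 0)

  # the top-k threshold is the minimum among the k best region maxima
  expect_equal(cms_threshold_top_k(ranked, 2), 0.90)
  expect_equal(cms_threshold_top_k(ranked, 1), 0.99)
  expect_warning(thr <- cms_threshold_top_k(ranked, 10), "using all")
  expect_equal(thr, 0.50)
})

test_that("region-set comparison matches a brute-force all-pairs check", {
  a <- tibble::tibble(contig = "c", start = 0, end = 100)
  b <- tibble::tibble(contig = "c", start = 50, end = 150)
  cmp <- compare_region_sets(a, b)
  expect_equal(cmp$summary$frac_no_overlap, c(0, 0))
  expect_equal(cmp$a$overlap_bp, 50)

  disjoint <- compare_region_sets(a, tibble::tibble(contig = "c",
                                                    start = 500, end = 600))
  expect_equal(disjoint$summary$frac_no_overlap, c(1, 1))

  withr::local_seed(43)
  for (i in 1:20) {
    mk <- function(n) {
      s <- sample(0:2000, n)
      tibble::tibble(contig = sample(c("c1", "c2"), n, replace = TRUE),
                     start = s, end = s + sample(10:300, n, replace = TRUE))
    }
    A <- mk(sample(3:15, 1))
    B <- mk(sample(3:15, 1))
    got <- compare_region_sets(A, B)
    brute <- vapply(seq_len(nrow(A)), function(i) {
      any(B$contig == A$contig[i] & B$start < A$end[i] & B$end > A$start[i])
    }, logical(1))
    expect_equal(got$a$any_overlap, brute)
    expect_equal(got$summary$frac_no_overlap[1], mean(!brute))
  }
})

test_that("panel validation compares region to flank diversity", {
  grid <- tibble::tibble(
    contig = "c", start = seq(0, 1.9e6, 1e5), end = seq(0, 1.9e6, 1e5) + 1e5,
    pi = 0.002
  )
  region_of <- function(s, e) {
    r <- call_regions(tibble::tibble(contig = "c", start = s, end = e))
    r
  }
  r <- region_of(1e6, 1.1e6)
  # localized reduction: pass
  g1 <- dplyr::mutate(grid, pi = ifelse(start == 1e6, 5e-4, pi))
  expect_equal(validate_with_panel(r, g1)$validation, "pass")
  # equal diversity: "greater or equal" fails
  expect_equal(validate_with_panel(r, grid)$validation, "fail")
  # no flank windows inside the flank span -> untested
  tiny <- grid[grid$start == 1e6, ]
  expect_equal(validate_with_panel(r, tiny, flank_bp = 5e4)$validation,
               "untested")
  # grid mismatch is fatal
  off <- dplyr::mutate(grid, start = start + 1, end = end + 1)
  expect_error(validate_with_panel(r, off), "grid")
})
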