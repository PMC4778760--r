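test_that("pop_spec enforces the sample/population invariants", {
  tab <- tibble::tibble(
    sample = c("a", "b", "c"), population = c("p1", "p1", "p2"),
    ploidy = c(2, 2, 2)
  )
  spec <- pop_spec(tab, focal = c("p1", "p2"))
  expect_equal(n_chrom(spec, "p1"), 4L)
  expect_equal(n_chrom(spec, "p2"), 2L)

  expect_error(pop_spec(rbind(tab, tab[1, ]), focal = c("p1", "p2")),
               "more than once")
  expect_error(pop_spec(dplyr::mutate(tab, ploidy = c(2, 3, 2)),
                        focal = c("p1", "p2")), "ploidy")
  expect_error(pop_spec(tab, focal = c("p1", "p3")), "absent")
  expect_error(pop_spec(tab, focal = c("p1", "p2"), outgroup = "p2"),
               "outgroup")
  # one haploid sample alone is not a scannable population
  solo <- tibble::tibble(sample = c("a", "b"), population = c("p1", "p2"),
                         ploidy = c(1, 2))
  expect_error(pop_spec(solo, focal = c("p1", "p2")), "at least 2")
})

test_that("read_genotypes applies the biallelic-SNV and fully-observed rules", {
  spec <- toy_spec()
  full <- "0/1\t1/1\t1\t0/0\t0/0\t0/0\t0/0"
  vcf <- write_toy_vcf(tempfile(fileext = ".vcf"), c(
    paste0("chr1\t11\t.\tA\tG\t.\tPASS\t.\tGT\t", full),
    paste0("chr1\t21\t.\tC\tT\t.\tPASS\t.\tGT\t", full),
    paste0("chr1\t31\t.\tG\tA\t.\tPASS\t.\tGT\t", full)
  ))
  sites <- read_genotypes(vcf, spec)
  expect_equal(nrow(sites), 3L)
  expect_equal(sites$pos, c(10, 20, 30))      # 0-based conversion
  expect_equal(sites$n_dog, rep(4L, 3))
  expect_equal(sites$n_wolf, rep(0L, 3))

  # any missing genotype drops the site
  vcf2 <- write_toy_vcf(tempfile(fileext = ".vcf"),
    "chr1\t11\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t./.\t1\t0/0\t0/0\t0/0\t0/0")
  expect_message(s2 <- read_genotypes(vcf2, spec), "missing")
  expect_equal(nrow(s2), 0L)

  # triallelic dropped with a logged count, biallelic kept
  vcf3 <- write_toy_vcf(tempfile(fileext = ".vcf"), c(
    paste0("chr1\t11\t.\tA\tG,T\t.\tPASS\t.\tGT\t", full),
    paste0("chr1\t21\t.\tC\tT\t.\tPASS\t.\tGT\t", full),
    paste0("chr1\t31\t.\tG\tA\t.\tPASS\t.\tGT\t", full)
  ))
  expect_message(s3 <- read_genotypes(vcf3, spec), "1 non-biallelic")
  expect_equal(nrow(s3), 2L)

  # fatal errors: absent sample, ploidy mismatch
  vcf4 <- write_toy_vcf(tempfile(fileext = ".vcf"),
    "chr1\t11\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1\t1\t0/0\t0/0\t0/0",
    samples = c("dog1", "dog2", "boxer", "wolf1", "wolf2", "wolf3"))
  expect_error(read_genotypes(vcf4, spec), "jackal")
  vcf5 <- write_toy_vcf(tempfile(fileext = ".vcf"),
    "chr1\t11\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1\t1/1\t0/0\t0/0\t0/0\t0/0")
  expect_error(read_genotypes(vcf5, spec), "ploidy mismatch.*boxer")
})

test_that("polarization follows the outgroup's fixed allele", {
  spec <- toy_spec()
  vcf <- write_toy_vcf(tempfile(fileext = ".vcf"), c(
    "chr1\t11\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1\t1\t0/0\t0/0\t0/0\t0/0",
    "chr1\t21\t.\tC\tT\t.\tPASS\t.\tGT\t0/1\t1/1\t1\t0/0\t0/0\t0/0\t0/1",
    "chr1\t31\t.\tG\tA\t.\tPASS\t.\tGT\t0/1\t1/1\t1\t0/0\t0/0\t0/0\t1/1"
  ))
  s <- polarize_sites(read_genotypes(vcf, spec), spec)
  expect_equal(s$derived_is_alt, c(TRUE, NA, FALSE))
  expect_equal(s$ancestral_known, c(TRUE, FALSE, TRUE))

  no_out <- pop_spec(spec$samples, focal = c("dog", "wolf"))
  expect_error(polarize_sites(read_genotypes(vcf, no_out), no_out),
               "outgroup")
})

test_that("site tables round-trip through VCF with identical counts", {
  spec <- toy_spec()
  withr::local_seed(11)
  sites <- tibble::tibble(
    contig = "chr1", pos = sort(sample(0:9999, 40)),
    ref = "A", alt = "G",
    n_dog = sample(0:5, 40, replace = TRUE),
    n_wolf = sample(0:6, 40, replace = TRUE),
    n_jackal = sample(0:2, 40, replace = TRUE)
  )
  # keep only genuinely variant rows so the VCF is well formed
  sites <- sites[sites$n_dog + sites$n_wolf + sites$n_jackal > 0 &
                   sites$n_dog + sites$n_wolf + sites$n_jackal < 13, ]
  path <- tempfile(fileext = ".vcf")
  write_site_vcf(sites, spec, path, contig_lengths = c(chr1 = 10000))
  back <- read_genotypes(path, spec)
  expect_equal(back$pos, sites$pos)
  expect_equal(back$n_dog, as.integer(sites$n_dog))
  expect_equal(back$n_wolf, as.integer(sites$n_wolf))
  expect_equal(back$n_jackal, as.integer(sites$n_jackal))
})

test_that("mask normalization merges, is idempotent and order-invariant", {
  m <- tibble::tibble(contig = "chr1", start = c(0, 50), end = c(100, 150))
  norm <- normalize_intervals(m)
  expect_equal(nrow(norm), 1L)
  expect_equal(c(norm$start, norm$end), c(0, 150))
  expect_equal(normalize_intervals(norm), norm)

  # empty mask file
  empty <- tempfile(fileext = ".bed")
  file.create(empty)
  expect_equal(interval_length(read_mask(empty)), 0)

  # degenerate interval is fatal, with the line number
  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t10\t10"), bad)
  expect_error(read_mask(bad), "line 2")

  withr::local_seed(5)
  for (i in 1:20) {
    iv <- tibble::tibble(
      contig = sample(c("c1", "c2"), 30, replace = TRUE),
      start = sample(0:500, 30, replace = TRUE)
    )
    iv$end <- iv$start + sample(1:100, 30, replace = TRUE)
    shuffled <- iv[sample(nrow(iv)), ]
    expect_equal(normalize_intervals(iv), normalize_intervals(shuffled))
    expect_equal(interval_length(iv), interval_length(shuffled))
  }
})

test_that("callable_length matches direct interval intersection", {
  withr::local_seed(9)
  mask <- normalize_intervals(tibble::tibble(
    contig = "chr1", start = seq(0, 900, 100), end = seq(0, 900, 100) + 60
  ))
  w <- tibble::tibble(contig = "chr1", start = c(0, 50, 130, 990),
                      end = c(100, 250, 140, 1200))
  direct <- vapply(seq_len(nrow(w)), function(i) {
    pos <- seq(w$start[i], w$end[i] - 1)
    sum(vapply(pos, function(p) any(p >= mask$start & p < mask$end),
               logical(1)))
  }, numeric(1))
  expect_equal(callable_length(mask, w), direct)
})
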