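#' Define the population and ploidy layout of a sample panel
#'
#' A population specification maps every sample to exactly one population and
#' records its ploidy, so that mixed panels (for example two diploid dogs plus
#' the haploid reference chromosome set in one population) contribute the
#' correct number of chromosomes to every statistic.
#'
#' @param samples A data frame with columns `sample`, `population` and
#'   `ploidy` (1 or 2), one row per sample.
#' @param focal Character vector of length two: the population scanned for
#'   sweeps followed by the reference population it is contrasted against
#'   (e.g. `c("dog", "wolf")`).
#' @param outgroup Name of the outgroup population used to orient alleles as
#'   ancestral/derived, or `NULL` if none.
#'
#' @return An object of class `pop_spec`: a list with elements `samples`
#'   (tibble), `focal`, `outgroup` and `n_chrom` (named integer vector of
#'   chromosome counts per population).
#'
#' @examples
#' canid_panel <- tibble::tibble(
#'   sample     = c("basenji", "dingo", "boxer", "wolf1", "wolf2", "wolf3", "jackal"),
#'   population = c("dog", "dog", "dog", "wolf", "wolf", "wolf", "jackal"),
#'   ploidy     = c(2, 2, 1, 2, 2, 2, 2)
#' )
#' pop_spec(canid_panel, focal = c("dog", "wolf"), outgroup = "jackal")
#' @export
pop_spec <- function(samples, focal, outgroup = NULL) {
  samples <- tibble::as_tibble(samples)
  req <- c("sample", "population", "ploidy")
  if (!all(req %in% names(samples))) {
    stop("`samples` must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(samples$sample)) {
    dup <- unique(samples$sample[duplicated(samples$sample)])
    stop("sample(s) assigned more than once: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!all(samples$ploidy %in% c(1L, 2L))) {
    stop("`ploidy` must be 1 or 2 for every sample", call. = FALSE)
  }
  if (length(focal) != 2L || anyDuplicated(focal)) {
    stop("`focal` must name two distinct populations (sweep, reference)", call. = FALSE)
  }
  n_chrom <- vapply(
    split(as.integer(samples$ploidy), samples$population), sum, integer(1)
  )
  missing_focal <- setdiff(focal, names(n_chrom))
  if (length(missing_focal)) {
    stop("focal population(s) absent from `samples`: ",
         paste(missing_focal, collapse = ", "), call. = FALSE)
  }
  if (any(n_chrom[focal] < 2L)) {
    stop("each focal population needs at least 2 chromosomes", call. = FALSE)
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% names(n_chrom)) {
      stop("outgroup population '", outgroup, "' absent from `samples`", call. = FALSE)
    }
    if (outgroup %in% focal) {
      stop("outgroup may not be a focal population", call. = FALSE)
    }
  }
  structure(
    list(
      samples = samples[, req],
      focal = as.character(focal),
      outgroup = outgroup,
      n_chrom = n_chrom
    ),
    class = "pop_spec"
  )
}

#' Number of chromosomes sampled per population
#'
#' @param spec A [pop_spec()].
#' @param pop Optional population name; if omitted, the full named vector.
#' @return Integer chromosome count(s).
#' @export
n_chrom <- function(spec, pop = NULL) {
  stopifnot(inherits(spec, "pop_spec"))
  if (is.null(pop)) return(spec$n_chrom)
  out <- spec$n_chrom[pop]
  if (anyNA(out)) stop("unknown population: ", pop[is.na(out)][1], call. = FALSE)
  unname(out)
}

#' The default canid-style study panel
#'
#' Two diploid basal dogs plus a haploid reference chromosome set in the
#' sweep population, three diploid wolves in the reference population, and a
#' diploid outgroup: 5 + 6 + 2 chromosomes.
#'
#' @return A [pop_spec()].
#' @export
default_pop_spec <- function() {
  pop_spec(
    tibble::tibble(
      sample     = c("dog1", "dog2", "boxer", "wolf1", "wolf2", "wolf3", "jackal"),
      population = c("dog", "dog", "dog", "wolf", "wolf", "wolf", "jackal"),
      ploidy     = c(2L, 2L, 1L, 2L, 2L, 2L, 2L)
    ),
    focal = c("dog", "wolf"),
    outgroup = "jackal"
  )
}

#' @export
print.pop_spec <- function(x, ...) {
  cat("<pop_spec>\n")
  for (p in names(x$n_chrom)) {
    tag <- if (p == x$focal[1]) " [sweep]"
      else if (p == x$focal[2]) " [reference]"
      else if (identical(p, x$outgroup)) " [outgroup]"
      else ""
    cat(sprintf("  %s: %d sample(s), %d chromosome(s)%s\n",
                p, sum(x$samples$population == p), x$n_chrom[[p]], tag))
  }
  invisible(x)
}
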