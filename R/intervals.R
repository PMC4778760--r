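#' Normalize a set of genomic intervals
#'
#' Sorts intervals and merges overlapping or bookended ones per contig.
#' All intervals in this package are 0-based, half-open.
#'
#' @param x Data frame with columns `contig`, `start`, `end`.
#' @return A tibble of sorted, disjoint intervals.
#' @export
normalize_intervals <- function(x) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("contig", "start", "end") %in% names(x)))
  if (nrow(x) == 0) {
    return(tibble::tibble(contig = character(), start = numeric(), end = numeric()))
  }
  if (any(x$start >= x$end)) {
    stop("degenerate interval(s): start >= end", call. = FALSE)
  }
  out <- lapply(split(x, x$contig), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
    tibble::tibble(
      contig = d$contig[1],
      start = IRanges::start(ir) - 1,
      end = as.numeric(IRanges::end(ir))
    )
  })
  out <- dplyr::bind_rows(out)
  dplyr::arrange(out, .data$contig, .data$start)
}

#' Read a callable-site mask from BED
#'
#' The mask externalizes upstream genome- and sample-level filters: only
#' positions inside mask intervals count toward a window's callable length.
#'
#' @param path Path to a BED file (0-based, half-open; first three columns
#'   used).
#' @return A normalized interval tibble (`contig`, `start`, `end`).
#' @export
read_mask <- function(path) {
  empty <- tibble::tibble(contig = character(), start = numeric(), end = numeric())
  if (file.size(path) == 0) return(empty)
  bed <- utils::read.table(path, sep = "\t", header = FALSE)[, 1:3]
  names(bed) <- c("contig", "start", "end")
  bed$contig <- as.character(bed$contig)
  bed <- tibble::as_tibble(bed)
  if (nrow(bed) == 0) return(empty)
  bad <- which(bed$start >= bed$end)
  if (length(bad)) {
    stop("BED line ", bad[1], ": start >= end (", bed$start[bad[1]], " >= ",
         bed$end[bad[1]], ")", call. = FALSE)
  }
  normalize_intervals(bed)
}

#' Total length of an interval set
#'
#' @param x Interval tibble.
#' @return Total bp covered (after normalization).
#' @export
interval_length <- function(x) {
  x <- normalize_intervals(x)
  sum(x$end - x$start)
}

# Coverage of `mask` (normalized, single contig) on [0, x) for each x.
# Vectorized prefix-coverage used for per-window callable lengths.
coverage_before <- function(x, starts, ends) {
  if (length(starts) == 0) return(rep(0, length(x)))
  cum <- cumsum(ends - starts)
  i <- findInterval(x, starts)
  out <- numeric(length(x))
  hit <- i > 0
  out[hit] <- cum[i[hit]] - pmax(0, ends[i[hit]] - x[hit])
  out
}

#' Callable length of query windows under a mask
#'
#' @param mask Normalized interval tibble.
#' @param windows Tibble with `contig`, `start`, `end`.
#' @return Numeric vector of callable bp per window row.
#' @export
callable_length <- function(mask, windows) {
  out <- numeric(nrow(windows))
  for (ctg in unique(windows$contig)) {
    wi <- windows$contig == ctg
    m <- mask[mask$contig == ctg, ]
    out[wi] <- coverage_before(windows$end[wi], m$start, m$end) -
      coverage_before(windows$start[wi], m$start, m$end)
  }
  out
}

#' Read gene annotations from GFF3
#'
#' @param path Path to a GFF3 file. Records of type `gene` are used when
#'   present, otherwise all records.
#' @return Tibble with `contig`, `start` (0-based), `end`, `gene_id`.
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if ("type" %in% names(df) && any(df$type == "gene")) {
    df <- df[df$type == "gene", ]
  }
  id <- if ("ID" %in% names(df)) as.character(df$ID)
    else if ("Name" %in% names(df)) as.character(df$Name)
    else paste0("gene", seq_len(nrow(df)))
  tibble::tibble(
    contig = as.character(df$seqnames),
    start = df$start - 1,      # GFF3 is 1-based closed
    end = as.numeric(df$end),
    gene_id = id
  )
}

#' Read a flat gene-to-term map
#'
#' @param path Path to a headerless two-column TSV: `gene_id<TAB>term_id`.
#'   A gene may appear on several lines (one per term).
#' @return Tibble with columns `gene_id`, `term_id`.
#' @export
read_term_map <- function(path) {
  readr::read_tsv(path, col_names = c("gene_id", "term_id"),
                  col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Write regions to BED
#'
#' The BED score column carries the region score (maximum composite score of
#' member windows) rescaled to 0--1000 per BED convention.
#'
#' @param regions Ranked region tibble (see [rank_regions()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  score <- if ("score" %in% names(regions)) round(regions$score * 1000) else 0L
  lines <- sprintf("%s\t%d\t%d\tregion_%d\t%d\t.",
                   regions$contig, as.integer(regions$start),
                   as.integer(regions$end),
                   seq_len(nrow(regions)), pmin(pmax(score, 0), 1000))
  writeLines(lines, path)
  invisible(path)
}
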