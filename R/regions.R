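#' Merge significant windows into candidate regions
#'
#' Windows (from any statistic) are merged transitively whenever the gap
#' between one interval's end and the next interval's start is at most
#' `max_gap`, measured on the growing region envelope; the region span is
#' the union envelope of its members. The result is independent of input
#' order and idempotent.
#'
#' @param windows Tibble of significant windows with `contig`, `start`,
#'   `end` and optionally a `statistic` column tagging which contrast made
#'   each window significant (a window may appear once per statistic).
#' @param max_gap Maximum gap joined, in bp (default 200 kb).
#' @return Region tibble with `contig`, `start`, `end`, `n_windows`,
#'   `statistics` (list of tags seen among members) and `windows` (list
#'   column of distinct member-window intervals).
#' @export
call_regions <- function(windows, max_gap = 200000) {
  windows <- tibble::as_tibble(windows)
  if (nrow(windows) == 0) {
    return(tibble::tibble(contig = character(), start = numeric(),
                          end = numeric(), n_windows = integer(),
                          statistics = list(), windows = list()))
  }
  if (!"statistic" %in% names(windows)) windows$statistic <- NA_character_
  windows <- dplyr::arrange(windows, .data$contig, .data$start, .data$end)
  out <- windows |>
    dplyr::group_by(.data$contig) |>
    dplyr::mutate(
      envelope = cummax(.data$end),
      new_region = .data$start > dplyr::lag(.data$envelope, default = -Inf) + max_gap,
      region_id = cumsum(.data$new_region),
      win_start = .data$start,
      win_end = .data$end
    ) |>
    dplyr::group_by(.data$contig, .data$region_id) |>
    dplyr::summarise(
      start = min(.data$win_start),
      end = max(.data$win_end),
      n_windows = dplyr::n_distinct(paste(.data$win_start, .data$win_end)),
      statistics = list(sort(unique(stats::na.omit(.data$statistic)))),
      windows = {
        ws <- .data$win_start
        we <- .data$win_end
        list(dplyr::distinct(tibble::tibble(start = ws, end = we)))
      },
      .groups = "drop"
    ) |>
    dplyr::select(-"region_id") |>
    dplyr::arrange(.data$contig, .data$start)
  out
}

#' Extract significant windows from a scored scan
#'
#' @param scan Scored window tibble from [scan_windows()].
#' @param alpha Per-statistic FDR threshold (default 0.01).
#' @return Long tibble of windows with `q <= alpha`, tagged by `statistic`
#'   (one of `delta_pi`, `fst`, `delta_td`); input to [call_regions()].
#' @export
significant_windows <- function(scan, alpha = 0.01) {
  pick <- function(qcol, tag) {
    keep <- !is.na(scan[[qcol]]) & scan[[qcol]] <= alpha
    tibble::tibble(contig = scan$contig[keep], start = scan$start[keep],
                   end = scan$end[keep], statistic = tag)
  }
  dplyr::bind_rows(
    pick("q_dpi", "delta_pi"),
    pick("q_fst", "fst"),
    pick("q_dtd", "delta_td")
  )
}

#' Rank regions by their maximum member-window score
#'
#' Each region's score is the maximum composite score (`cms`, or another
#' score column such as `pct_joint` for the empirical method) over its
#' member windows; the peak window attaining it is recorded. Regions are
#' ordered by descending score, ties broken by longer span then by
#' coordinates; `display_rank` additionally reports the average-rank tie
#' convention used for presentation (e.g. two regions tied across ranks 2
#' and 3 both display 2.5).
#'
#' @param regions Region tibble from [call_regions()].
#' @param scan Scored window tibble containing the score column.
#' @param score Name of the score column in `scan` (default `"cms"`).
#' @return Ranked region tibble with `score`, `peak_start`, `peak_end`,
#'   `rank`, `display_rank`.
#' @export
rank_regions <- function(regions, scan, score = "cms") {
  if (nrow(regions) == 0) {
    return(dplyr::mutate(regions, score = numeric(0), peak_start = numeric(0),
                         peak_end = numeric(0), rank = integer(0),
                         display_rank = numeric(0)))
  }
  scored <- purrr::map2(regions$windows, regions$contig, function(w, ctg) {
    sc <- scan[scan$contig == ctg, c("start", "end", score)]
    m <- dplyr::inner_join(w, sc, by = c("start", "end"))
    vals <- m[[score]]
    if (all(is.na(vals))) return(list(score = NA_real_, peak = c(NA, NA)))
    i <- which.max(vals)
    list(score = vals[i], peak = c(m$start[i], m$end[i]))
  })
  regions$score <- vapply(scored, `[[`, numeric(1), "score")
  regions$peak_start <- vapply(scored, function(x) x$peak[1], numeric(1))
  regions$peak_end <- vapply(scored, function(x) x$peak[2], numeric(1))
  dropped <- is.na(regions$score)
  if (any(dropped)) {
    warning(sum(dropped), " region(s) without any scored member window excluded",
            call. = FALSE)
    regions <- regions[!dropped, , drop = FALSE]
  }
  regions <- dplyr::arrange(regions, dplyr::desc(.data$score),
                            dplyr::desc(.data$end - .data$start),
                            .data$contig, .data$start)
  regions$rank <- seq_len(nrow(regions))
  regions$display_rank <- rank(-regions$score, ties.method = "average")
  regions
}

#' Composite-score threshold defined by the top-k regions
#'
#' The minimum, over the `k` best-ranked regions, of each region's maximum
#' member-window composite score; used as the "high-CMS" cut in
#' [classify_windows()].
#'
#' @param regions Ranked region tibble from [rank_regions()].
#' @param k Number of top regions (default 100). With fewer regions, all
#'   are used with a warning.
#' @return Numeric threshold.
#' @export
cms_threshold_top_k <- function(regions, k = 100) {
  if (nrow(regions) == 0) stop("no regions", call. = FALSE)
  if (nrow(regions) < k) {
    warning("only ", nrow(regions), " region(s) available; using all",
            call. = FALSE)
    k <- nrow(regions)
  }
  min(regions$score[order(-regions$score)][seq_len(k)])
}

#' Overlap summary between two region sets
#'
#' @param a,b Region tibbles (`contig`, `start`, `end`).
#' @return List with `a` and `b` (per-region `any_overlap` flag and total
#'   `overlap_bp` against the other set) and `summary` (one row per
#'   direction with the fraction of regions having no overlap).
#' @export
compare_region_sets <- function(a, b) {
  one_way <- function(x, y) {
    ov <- rep(0, nrow(x))
    for (ctg in unique(x$contig)) {
      xi <- which(x$contig == ctg)
      yi <- y$contig == ctg
      if (!any(yi)) next
      xr <- IRanges::IRanges(x$start[xi] + 1, x$end[xi])
      yr <- IRanges::reduce(IRanges::IRanges(y$start[yi] + 1, y$end[yi]))
      hits <- IRanges::findOverlaps(xr, yr)
      if (length(hits) == 0) next
      w <- IRanges::width(IRanges::pintersect(
        xr[S4Vectors::queryHits(hits)], yr[S4Vectors::subjectHits(hits)]
      ))
      agg <- tapply(w, S4Vectors::queryHits(hits), sum)
      ov[xi[as.integer(names(agg))]] <- as.numeric(agg)
    }
    dplyr::mutate(x, overlap_bp = ov, any_overlap = ov > 0)
  }
  a2 <- one_way(tibble::as_tibble(a), tibble::as_tibble(b))
  b2 <- one_way(tibble::as_tibble(b), tibble::as_tibble(a))
  list(
    a = a2, b = b2,
    summary = tibble::tibble(
      direction = c("a_vs_b", "b_vs_a"),
      n = c(nrow(a2), nrow(b2)),
      frac_no_overlap = c(
        if (nrow(a2)) mean(!a2$any_overlap) else NA_real_,
        if (nrow(b2)) mean(!b2$any_overlap) else NA_real_
      )
    )
  )
}

#' Validate regions against a diversity panel
#'
#' A region fails when mean panel diversity over its member windows is
#' greater than or equal to the mean over non-member windows of the
#' surrounding flanks (a candidate sweep should show a localized diversity
#' reduction in the independent panel); it is untested when the flanks
#' contain no usable windows.
#'
#' @param regions Region tibble (with `windows` list column from
#'   [call_regions()]).
#' @param panel_pi Tibble `contig`, `start`, `end`, `pi`: panel diversity on
#'   the same window grid as the scan.
#' @param flank_bp Flank span on each side (default 500 kb).
#' @return `regions` with added `panel_pi_region`, `panel_pi_flank` and
#'   `validation` (`pass`, `fail` or `untested`).
#' @export
validate_with_panel <- function(regions, panel_pi, flank_bp = 500000) {
  res <- purrr::pmap(
    list(regions$contig, regions$start, regions$end, regions$windows),
    function(ctg, rs, re, w) {
      grid <- panel_pi[panel_pi$contig == ctg, , drop = FALSE]
      memb <- dplyr::inner_join(w, grid, by = c("start", "end"))
      if (nrow(memb) < nrow(w)) {
        stop("panel grid does not cover the scan windows (contig ", ctg, ")",
             call. = FALSE)
      }
      fl <- grid[grid$start >= rs - flank_bp & grid$end <= re + flank_bp, ,
                 drop = FALSE]
      # flank = windows clear of the region span, not members
      fl <- fl[fl$end <= rs | fl$start >= re, , drop = FALSE]
      m_reg <- mean(memb$pi)
      if (nrow(fl) == 0) {
        return(list(reg = m_reg, fl = NA_real_, status = "untested"))
      }
      m_fl <- mean(fl$pi)
      list(reg = m_reg, fl = m_fl,
           status = if (m_reg >= m_fl) "fail" else "pass")
    }
  )
  regions$panel_pi_region <- vapply(res, `[[`, numeric(1), "reg")
  regions$panel_pi_flank <- vapply(res, `[[`, numeric(1), "fl")
  regions$validation <- vapply(res, `[[`, character(1), "status")
  regions
}
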