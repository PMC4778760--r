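#' Genes near the peak signal of top-ranked regions
#'
#' Collects genes whose span intersects the peak window of each selected
#' region, extended by `flank` bp on both sides, and deduplicates.
#'
#' @param regions Ranked region tibble from [rank_regions()] (optionally
#'   validated, see [validate_with_panel()]).
#' @param genes Gene tibble from [read_genes()].
#' @param flank Flank around the peak window (default 25 kb).
#' @param top_k Number of top-ranked regions considered (default 100).
#' @param validated_only If `TRUE`, drop regions whose `validation` column
#'   is `"fail"` before taking the top `top_k`.
#' @return Character vector of unique gene ids.
#' @export
genes_near_peaks <- function(regions, genes, flank = 25000, top_k = 100,
                             validated_only = FALSE) {
  if (nrow(genes) == 0) stop("no gene annotation supplied", call. = FALSE)
  r <- regions
  if (validated_only) {
    if (!"validation" %in% names(r)) {
      stop("`validated_only = TRUE` needs a `validation` column", call. = FALSE)
    }
    r <- r[r$validation != "fail", , drop = FALSE]
  }
  r <- r[order(r$rank), , drop = FALSE]
  r <- utils::head(r, top_k)
  hits <- character(0)
  for (i in seq_len(nrow(r))) {
    lo <- r$peak_start[i] - flank
    hi <- r$peak_end[i] + flank
    g <- genes[genes$contig == r$contig[i] &
                 genes$start < hi & genes$end > lo, , drop = FALSE]
    hits <- c(hits, g$gene_id)
  }
  unique(hits)
}

#' Fold enrichment of a term in a gene set
#'
#' `(k / n) / (K / N)`: the proportion of input genes in the term over the
#' proportion of background genes in the term.
#'
#' @param k Input genes in the term.
#' @param n Input gene total (> 0).
#' @param K Background genes in the term (> 0).
#' @param N Background gene total (> 0).
#' @return Fold enrichment (vectorized).
#' @export
fold_enrichment <- function(k, n, K, N) {
  stopifnot(all(n > 0), all(K > 0), all(N > 0))
  (k / n) / (K / N)
}

#' Term enrichment of a gene set by hypergeometric test
#'
#' For every term with background membership, tests over-representation of
#' the input gene set with the hypergeometric upper tail
#' `P(X >= k)` (population `N`, `K` successes, `n` draws), then adjusts
#' across terms with the Benjamini-Hochberg procedure. Terms are reported
#' when the adjusted FDR (percent) is at most `fdr_max_pct`; set it to 100
#' to keep everything.
#'
#' @param gene_set Character vector of input gene ids.
#' @param term_map Tibble `gene_id`, `term_id` ([read_term_map()]).
#' @param background_N Background gene total; defaults to the number of
#'   distinct genes in `term_map`.
#' @param fdr_max_pct Report terms with FDR percentage at most this value
#'   (default 10).
#' @return Tibble with `term_id`, `k`, `n`, `K`, `N`, `fold`, `p`,
#'   `p_corrected`, `fdr_pct` and the input genes per term, sorted by `p`.
#' @export
enrichment_test <- function(gene_set, term_map, background_N = NULL,
                            fdr_max_pct = 10) {
  gene_set <- unique(gene_set)
  bg_genes <- unique(term_map$gene_id)
  N <- if (is.null(background_N)) length(bg_genes) else background_N
  n <- length(intersect(gene_set, bg_genes))
  if (n == 0) {
    return(tibble::tibble(term_id = character(), k = integer(), n = integer(),
                          K = integer(), N = integer(), fold = numeric(),
                          p = numeric(), p_corrected = numeric(),
                          fdr_pct = numeric(), genes = list()))
  }
  by_term <- split(term_map$gene_id, term_map$term_id)
  rows <- purrr::imap(by_term, function(g, term) {
    g <- unique(g)
    K <- length(g)
    if (K == 0) return(NULL)
    in_term <- intersect(gene_set, g)
    k <- length(in_term)
    tibble::tibble(
      term_id = term, k = k, n = n, K = K, N = N,
      fold = fold_enrichment(k, n, K, N),
      p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      genes = list(sort(in_term))
    )
  })
  res <- dplyr::bind_rows(rows)
  res$p_corrected <- bh_adjust(res$p)
  res$fdr_pct <- res$p_corrected * 100
  res <- res[res$fdr_pct <= fdr_max_pct, , drop = FALSE]
  dplyr::arrange(res, .data$p)[, c("term_id", "k", "n", "K", "N", "fold",
                                   "p", "p_corrected", "fdr_pct", "genes")]
}
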