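#' Hypergeometric over-representation of gene sets
#'
#' For each term with `K` background members out of a background of `N`
#' genes, and `k` of the `n` query genes in the term, reports the fold
#' enrichment `(k/n) / (K/N)` and the hypergeometric upper-tail p-value
#' `P[X >= k]` (so `k = 0` gives p = 1).  Multiple-testing correction is
#' Bonferroni by default, mirroring common online term-finder behaviour;
#' Benjamini-Hochberg is available.
#'
#' @param query Character vector of query gene ids (must be a subset of
#'   `background`).
#' @param background Character vector defining the test universe —
#'   conventionally all genes with a TE result, not the whole annotation.
#' @param terms Long tibble `term_id`, `term_name`, `gene_id` (one member
#'   per row); members outside the background are ignored.
#' @param correction `"bonferroni"` (default) or `"bh"`.
#' @return A tibble sorted by p-value: `term_id`, `term_name`, `K`, `N`,
#'   `n`, `k`, `fold_enrichment`, `p_value`, `p_adjusted`.
#' @export
enrich <- function(query, background, terms,
                   correction = c("bonferroni", "bh")) {
  correction <- match.arg(correction)
  assert_cols(terms, c("term_id", "gene_id"), "term table")
  if (!"term_name" %in% names(terms)) terms$term_name <- terms$term_id
  if (nrow(terms) == 0) abort("`terms` is empty")
  query <- unique(query)
  background <- unique(background)
  stray <- setdiff(query, background)
  if (length(stray)) {
    abort(sprintf("query gene(s) absent from background: %s",
                  paste(sort(stray), collapse = ", ")))
  }
  N <- length(background)
  n <- length(query)
  out <- terms %>%
    dplyr::filter(.data$gene_id %in% background) %>%
    dplyr::group_by(.data$term_id, .data$term_name) %>%
    dplyr::summarise(K = dplyr::n_distinct(.data$gene_id),
                     k = dplyr::n_distinct(intersect(.data$gene_id, query)),
                     .groups = "drop") %>%
    dplyr::mutate(
      N = N, n = n,
      fold_enrichment = ifelse(n > 0 & .data$K > 0,
                               (.data$k / n) / (.data$K / N), 0),
      p_value = stats::phyper(.data$k - 1, .data$K, N - .data$K, n,
                              lower.tail = FALSE))
  out$p_adjusted <- if (correction == "bonferroni") {
    pmin(1, nrow(out) * out$p_value)
  } else {
    stats::p.adjust(out$p_value, method = "BH")
  }
  out %>%
    dplyr::select("term_id", "term_name", "K", "N", "n", "k",
                  "fold_enrichment", "p_value", "p_adjusted") %>%
    dplyr::arrange(.data$p_value)
}
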