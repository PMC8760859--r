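#' Hypergeometric term over-representation test
#'
#' Classic one-sided over-representation analysis: for each term, the
#' p-value is the upper-tail hypergeometric probability of drawing at least
#' the observed number of term genes when `n_query` genes are sampled from
#' the universe. Terms are intersected with the universe before testing,
#' and BH FDR is computed across the tested terms.
#'
#' @param query Character vector of genes of interest (must be a subset of
#'   `universe`; genes outside it are dropped with a message).
#' @param term_map Tibble `term_id, gene_id` (optionally `term_name`,
#'   `namespace`, carried through).
#' @param universe Character vector of background genes (e.g. all features
#'   tested for differential expression).
#' @return Tibble `term_id, (term_name, namespace,) n_query_in_term,
#'   n_term, n_query, n_universe, p_value, fdr`, sorted by `p_value`.
#' @examples
#' tm <- tibble::tibble(term_id = "T1", gene_id = paste0("g", 1:5))
#' enrichment_test(paste0("g", 1:5), tm, paste0("g", 1:20))
#' @export
enrichment_test <- function(query, term_map, universe) {
  assert_columns(term_map, c("term_id", "gene_id"), "term_map")
  universe <- unique(universe)
  if (length(universe) == 0) abort("`universe` is empty")
  query <- unique(query)
  if (length(query) == 0) abort("`query` is empty")
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    rlang::inform(sprintf(
      "%d query gene(s) outside the universe were dropped", length(outside)
    ))
    query <- intersect(query, universe)
    if (length(query) == 0) abort("no query genes remain inside the universe")
  }

  tm <- term_map |>
    dplyr::filter(.data$gene_id %in% universe) |>
    dplyr::distinct(.data$term_id, .data$gene_id)
  sidecar <- term_map |>
    dplyr::select(dplyr::any_of(c("term_id", "term_name", "namespace"))) |>
    dplyr::distinct(.data$term_id, .keep_all = TRUE)

  n_u <- length(universe)
  n_q <- length(query)
  res <- tm |>
    dplyr::group_by(.data$term_id) |>
    dplyr::summarise(
      n_term = dplyr::n(),
      n_query_in_term = sum(.data$gene_id %in% query)
    ) |>
    dplyr::mutate(
      n_query = n_q,
      n_universe = n_u,
      p_value = phyper(
        .data$n_query_in_term - 1, .data$n_term,
        n_u - .data$n_term, n_q,
        lower.tail = FALSE
      ),
      fdr = bh_adjust(.data$p_value)
    ) |>
    dplyr::relocate("n_query_in_term", .before = "n_term")

  dplyr::left_join(res, sidecar, by = "term_id") |>
    dplyr::relocate(dplyr::any_of(c("term_name", "namespace")), .after = "term_id") |>
    dplyr::arrange(.data$p_value, .data$term_id)
}

#' Top enriched terms
#'
#' Within an optional namespace, terms sorted by p-value ascending (ties by
#' term id); at most `k` returned.
#'
#' @param results Tibble from [enrichment_test()].
#' @param k Number of terms (default 20, the usual figure panel size).
#' @param namespace Optional namespace filter (requires a `namespace`
#'   column).
#' @return The selected rows of `results`, best first.
#' @export
top_terms <- function(results, k = 20, namespace = NULL) {
  assert_scalar_number(k, "k", lower = 1)
  assert_columns(results, c("term_id", "p_value"), "results")
  if (!is.null(namespace)) {
    assert_columns(results, "namespace", "results")
    results <- results[results$namespace == namespace, , drop = FALSE]
  }
  utils::head(
    dplyr::arrange(results, .data$p_value, .data$term_id),
    k
  )
}
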