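#' Hypergeometric GO term enrichment
#'
#' Upper-tail hypergeometric test per GO term: the probability of
#' drawing at least `k` term genes when drawing the test set from the
#' background. The annotated universe is the intersection of the
#' background with the genes present in the GO map; unannotated genes
#' contribute to neither the population `N` nor the draw count `n`.
#' A term is reported when `p < p_threshold` and its background gene-set
#' size `m` strictly exceeds `min_set`.
#'
#' @param test_genes Gene ids to test (must be a subset of
#'   `background`), e.g. a trans-band's member genes.
#' @param go_map Tibble `gene`, `term` (see [read_go_map()]).
#' @param background Background gene ids (the expression-filtered set).
#' @param p_threshold Significance cutoff (default 1e-5, strict `<`).
#' @param min_set Minimum background term size, strict `>` (default 3).
#' @param keep_all Return all tested terms with a `significant` flag
#'   instead of only the reported ones.
#' @return Tibble `term`, `k` (overlap), `m` (term size in background),
#'   `n` (annotated test-set size), `N` (annotated background size),
#'   `p`.
#' @export
go_enrichment <- function(test_genes, go_map, background,
                          p_threshold = 1e-5, min_set = 3, keep_all = FALSE) {
  background <- unique(background)
  if (!length(background)) abort("Empty background gene set")
  test_genes <- unique(test_genes)
  if (!all(test_genes %in% background)) {
    abort("`test_genes` must be a subset of `background`")
  }
  go <- go_map[go_map$gene %in% background, ]
  universe <- unique(go$gene)
  N <- length(universe)
  test_u <- intersect(test_genes, universe)
  n <- length(test_u)
  rows <- go |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(m = dplyr::n_distinct(.data$gene),
                     k = sum(unique(.data$gene) %in% test_u),
                     .groups = "drop")
  rows$n <- n
  rows$N <- N
  rows$p <- phyper(rows$k - 1, rows$m, N - rows$m, n, lower.tail = FALSE)
  rows$significant <- rows$p < p_threshold & rows$m > min_set
  rows <- rows[order(rows$p), c("term", "k", "m", "n", "N", "p", "significant")]
  if (!keep_all) rows <- rows[rows$significant, names(rows) != "significant"]
  rows
}
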