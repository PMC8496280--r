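#' Normalize fpkm to per-million per sample
#'
#' Rescales each sample (column) so that its gene fpkm values sum to one
#' million: `out[g, s] = raw[g, s] / sum_g raw[g, s] * 1e6`. This is the
#' per-sample depth normalization applied after restricting to the
#' consistently detected transcripts.
#'
#' @param raw An [expression_matrix()] with layer `"raw_fpkm"`.
#' @return An `expression_matrix` with layer `"normalized"`; every sample
#'   column sums to `1e6`.
#' @export
normalize_expression <- function(raw) {
  stopifnot(inherits(raw, "expression_matrix"))
  if (raw$layer != "raw_fpkm") abort("`raw` must carry the raw_fpkm layer")
  totals <- colSums(raw$values)
  bad <- which(totals <= 0)
  if (length(bad)) {
    abort(paste0("Sample(s) with zero total fpkm: ",
                 paste(colnames(raw$values)[bad], collapse = ", ")))
  }
  out <- sweep(raw$values, 2, totals, "/") * 1e6
  set_layer(raw, out, "normalized")
}

#' Log2 transform and per-gene log2 ratios
#'
#' Computes the log2 layer and the log2 ratio with the gene's mean:
#' `ratio[g, s] = log2[g, s] - mean_s(log2[g, .])`. Every gene's ratio row
#' has mean zero. The pseudocount replaces exact zeros only (non-zero
#' values are logged as-is); with `pseudocount = 0` a zero value is an
#' error.
#'
#' @param norm An [expression_matrix()] with layer `"normalized"` (or
#'   `"raw_fpkm"`, e.g. when computing the pre-normalization log2 used by
#'   the expression filter).
#' @param pseudocount Replacement for exact zeros before logging
#'   (default `2^-10`).
#' @return A list with elements `log2` and `ratio`, both
#'   `expression_matrix` objects.
#' @export
log2_and_ratio <- function(norm, pseudocount = 2^-10) {
  stopifnot(inherits(norm, "expression_matrix"))
  if (!norm$layer %in% c("normalized", "raw_fpkm")) {
    abort("`norm` must carry the normalized (or raw_fpkm) layer")
  }
  if (pseudocount < 0) abort("`pseudocount` must be >= 0")
  v <- norm$values
  if (any(v == 0)) {
    if (pseudocount == 0) abort("Zero expression value with pseudocount 0")
    v[v == 0] <- pseudocount
  }
  l2 <- log2(v)
  ratio <- l2 - rowMeans(l2)
  list(log2 = set_layer(norm, l2, "log2"),
       ratio = set_layer(norm, ratio, "log2_ratio"))
}

#' Filter to consistently expressed genes
#'
#' Keeps genes whose mean log2 expression over all samples is strictly
#' greater than `threshold` (default -5, the consistently-detected
#' cutoff).
#'
#' @param log2m An [expression_matrix()] with layer `"log2"`.
#' @param threshold Mean log2 cutoff (strict `>`).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed_genes <- function(log2m, threshold = -5) {
  stopifnot(inherits(log2m, "expression_matrix"))
  if (log2m$layer != "log2") abort("`log2m` must carry the log2 layer")
  keep <- rowMeans(log2m$values) > threshold
  rownames(log2m$values)[keep]
}

#' Sample-level PCA of log2 ratios
#'
#' Projects samples onto the top principal axes of the sample covariance
#' of the gene-centered expression matrix, the standard QC view used to
#' spot batch effects and the developmental axis.
#'
#' @param ratios An [expression_matrix()] with layer `"log2_ratio"`.
#' @param n_components Number of components to return.
#' @return An object of class `expr_pca`: list with `scores` (tibble:
#'   `sample`, `role`, `line`, `PC1`..) and `var_explained` (fractions,
#'   non-increasing, summing to at most 1).
#' @export
pca_qc <- function(ratios, n_components = 2) {
  stopifnot(inherits(ratios, "expression_matrix"))
  n_samp <- ncol(ratios$values)
  if (n_samp < 2) abort("PCA needs at least 2 samples")
  if (n_components > n_samp) {
    abort(sprintf("n_components (%d) exceeds the number of samples (%d)",
                  n_components, n_samp))
  }
  p <- prcomp(t(ratios$values), center = TRUE, scale. = FALSE)
  tot <- sum(p$sdev^2)
  ve <- if (tot > 0) p$sdev^2 / tot else rep(0, length(p$sdev))
  k <- min(n_components, ncol(p$x))
  scores <- p$x[, seq_len(k), drop = FALSE]
  # pad when the rank is below n_components (e.g. identical samples)
  if (k < n_components) {
    pad <- matrix(0, nrow(scores), n_components - k)
    colnames(pad) <- paste0("PC", (k + 1):n_components)
    scores <- cbind(scores, pad)
  }
  out <- dplyr::bind_cols(
    ratios$samples[, c("sample", "role", "line")],
    tibble::as_tibble(scores))
  structure(list(scores = out,
                 var_explained = c(ve, rep(0, n_components))[seq_len(n_components)]),
            class = "expr_pca")
}

#' @export
print.expr_pca <- function(x, ...) {
  cat("<expr_pca>\n  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.expr_pca <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.expr_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$var_explained),
                 var_explained = x$var_explained)
}

#' Prepare expression layers for mapping
#'
#' Pipeline helper fixing the stage order: genes are filtered on the mean
#' log2 of the *raw* fpkm, then the surviving genes are depth-normalized
#' and the log2 and log2-ratio layers computed.
#'
#' @param raw An [expression_matrix()] with layer `"raw_fpkm"`.
#' @param threshold Expression filter cutoff on mean log2 raw fpkm.
#' @param pseudocount Zero replacement for the log transform.
#' @return List with `genes` (kept ids), `norm`, `log2`, `ratio`.
#' @export
prepare_expression <- function(raw, threshold = -5, pseudocount = 2^-10) {
  pre <- log2_and_ratio(raw, pseudocount)$log2
  genes <- filter_expressed_genes(pre, threshold)
  norm <- normalize_expression(subset_expression(raw, genes = genes))
  lr <- log2_and_ratio(norm, pseudocount)
  list(genes = genes, norm = norm, log2 = lr$log2, ratio = lr$ratio)
}
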