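#' All-pairs Tukey HSD across the four parental lines
#'
#' One-way ANOVA per gene over the parental samples; the pooled residual
#' variance feeds Tukey–Kramer studentized-range p-values for all six
#' founder pairs. Vectorized over genes.
#'
#' @param values Numeric matrix, genes x parental samples (log2 scale).
#' @param labels Parental line per sample column (4 groups, >= 2
#'   replicates each).
#' @return Tibble `gene`, `pair` (e.g. `"JU1511-JU1926"`), `p_adj`.
#' @export
tukey_pairwise <- function(values, labels) {
  values <- rbind(values)
  labels <- as.character(labels)
  if (length(labels) != ncol(values)) abort("One label per sample column required")
  groups <- sort(unique(labels))
  k <- length(groups)
  n_i <- table(factor(labels, levels = groups))
  if (any(n_i < 2)) {
    abort(paste0("Group(s) with fewer than 2 replicates: ",
                 paste(groups[n_i < 2], collapse = ", ")))
  }
  N <- length(labels)
  ind <- outer(labels, groups, "==") * 1          # samples x groups
  colnames(ind) <- groups
  means <- values %*% sweep(ind, 2, n_i, "/")     # genes x groups
  fitted <- means %*% t(ind)
  sse <- rowSums((values - fitted)^2)
  df <- N - k
  s2 <- sse / df

  pairs <- utils::combn(groups, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(s2 / 2 * (1 / n_i[[a]] + 1 / n_i[[b]]))
    diff <- abs(means[, a] - means[, b])
    q <- ifelse(se > 0, diff / se, ifelse(diff > 0, Inf, NaN))
    p <- ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    p[is.nan(q)] <- 1  # identical constant groups: no evidence
    tibble::tibble(gene = rownames(values) %||% as.character(seq_len(nrow(values))),
                   pair = paste(a, b, sep = "-"), p_adj = p)
  })
  out
}

#' Parental differential expression summary
#'
#' Runs [tukey_pairwise()] on the parental samples of a log2 expression
#' matrix and summarises genes differentially expressed in at least one
#' founder pair, with per-pair counts and UpSet-style intersection
#' counts over the six pairs.
#'
#' @param log2m An [expression_matrix()] with layer `"log2"`.
#' @param p_threshold Tukey-adjusted significance cutoff (default 0.001,
#'   strict `<`).
#' @return List of class `parental_de`: `pairwise` (long tibble with
#'   `significant` flag), `deg_genes` (ids significant in >= 1 pair),
#'   `pair_counts`, `intersections` (membership pattern x count).
#' @export
parental_de <- function(log2m, p_threshold = 0.001) {
  stopifnot(inherits(log2m, "expression_matrix"))
  ps <- parent_samples(log2m)
  pw <- tukey_pairwise(log2m$values[, ps$sample, drop = FALSE], ps$line)
  pw$significant <- pw$p_adj < p_threshold
  sig <- pw |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(any_sig = any(.data$significant), .groups = "drop")
  deg <- sig$gene[sig$any_sig]
  pair_counts <- pw |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(n_deg = sum(.data$significant), .groups = "drop")
  inter <- pw |>
    dplyr::filter(.data$gene %in% deg) |>
    dplyr::mutate(flag = as.integer(.data$significant)) |>
    tidyr::pivot_wider(id_cols = "gene", names_from = "pair",
                       values_from = "flag") |>
    dplyr::group_by(dplyr::across(-"gene")) |>
    dplyr::summarise(n_genes = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_genes))
  structure(list(pairwise = pw, deg_genes = deg, pair_counts = pair_counts,
                 intersections = inter, p_threshold = p_threshold),
            class = "parental_de")
}

#' @export
print.parental_de <- function(x, ...) {
  cat(sprintf("<parental_de> %d DEG at Tukey p < %g\n",
              length(x$deg_genes), x$p_threshold))
  print(x$pair_counts)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.parental_de <- function(x, ...) x$pairwise

#' @exportS3Method generics::glance
glance.parental_de <- function(x, ...) {
  tibble::tibble(n_deg = length(x$deg_genes), p_threshold = x$p_threshold)
}

# Per-gene DEG indicator without per-gene ptukey calls: a pair is
# significant at level alpha iff its studentized range statistic exceeds
# the single critical value qtukey(1 - alpha, k, df). Exactly equivalent
# to p_adj < alpha since ptukey is strictly decreasing in q.
tukey_deg_any <- function(values, labels, alpha) {
  values <- rbind(values)
  groups <- sort(unique(labels))
  k <- length(groups)
  n_i <- table(factor(labels, levels = groups))
  N <- length(labels)
  ind <- outer(labels, groups, "==") * 1
  colnames(ind) <- groups
  means <- values %*% sweep(ind, 2, n_i, "/")
  fitted <- means %*% t(ind)
  s2 <- rowSums((values - fitted)^2) / (N - k)
  qcrit <- stats::qtukey(1 - alpha, nmeans = k, df = N - k)
  pairs <- utils::combn(groups, 2)
  any_sig <- rep(FALSE, nrow(values))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(s2 / 2 * (1 / n_i[[a]] + 1 / n_i[[b]]))
    diff <- abs(means[, a] - means[, b])
    q <- ifelse(se > 0, diff / se, ifelse(diff > 0, Inf, 0))
    any_sig <- any_sig | (q > qcrit)
  }
  any_sig
}

#' Permutation false-positive rate for the parental DEG count
#'
#' Permutes the parental line labels over the eight parental samples,
#' recomputes the DEG count per permutation, and reports
#' `FPR = mean(permuted count) / observed count`.
#'
#' @inheritParams parental_de
#' @param n_perm Number of permutations.
#' @param seed Seed.
#' @return List `fpr`, `n_observed`, `n_permuted` (per-permutation
#'   counts). `fpr` is `NA` with a warning when the observed count is 0.
#' @export
deg_fpr <- function(log2m, p_threshold = 0.001, n_perm = 100, seed = 1L) {
  stopifnot(n_perm >= 1)
  ps <- parent_samples(log2m)
  v <- log2m$values[, ps$sample, drop = FALSE]
  count_deg <- function(labels) sum(tukey_deg_any(v, labels, p_threshold))
  observed <- count_deg(ps$line)
  set.seed(seed)
  permuted <- vapply(seq_len(n_perm),
                     function(i) count_deg(sample(ps$line)), numeric(1))
  if (observed == 0) {
    warn("Observed DEG count is 0; FPR undefined")
    fpr <- NA_real_
  } else {
    fpr <- mean(permuted) / observed
  }
  list(fpr = fpr, n_observed = observed, n_permuted = permuted)
}

#' Replicate correlation per parental line
#'
#' Pearson correlation over genes between the two replicates of each
#' parental line, the basic reproducibility check.
#'
#' @param log2m An [expression_matrix()] with layer `"log2"`.
#' @return Tibble `line`, `r`.
#' @export
replicate_correlation <- function(log2m) {
  stopifnot(inherits(log2m, "expression_matrix"))
  ps <- parent_samples(log2m)
  purrr::map_dfr(split(ps, ps$line), function(s) {
    if (nrow(s) != 2) abort(paste0("Line ", s$line[1], " does not have 2 replicates"))
    tibble::tibble(line = s$line[1],
                   r = cor(log2m$values[, s$sample[1]],
                           log2m$values[, s$sample[2]]))
  })
}
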