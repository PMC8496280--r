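#' Transgressive segregation per gene
#'
#' A gene shows transgression when many mpRILs express it beyond the
#' envelope of the most extreme parental lines. The envelope is the
#' highest (lowest) parental line mean plus (minus) `k_sd` pooled
#' within-line standard deviations; the pooled SD uses the within-line
#' variation of the parental replicates,
#' `sqrt(sum(squared deviations) / (n_parent_samples - n_lines))`.
#' mpRILs strictly beyond a bound count as over/under; a gene is
#' transgressive when `n_over + n_under` strictly exceeds
#' `count_threshold`.
#'
#' @param log2m An [expression_matrix()] with layer `"log2"` (or
#'   `"log2_ratio"`), containing the parental and mpRIL samples.
#' @param k_sd Envelope width in pooled SDs (default 2).
#' @param count_threshold Minimum count of transgressive mpRILs, strict
#'   `>` (default 50, i.e. a quarter of 200 lines).
#' @return Tibble of class `transgression_result`: `gene`, `n_over`,
#'   `n_under`, `lower`, `upper`, `transgressive`.
#' @export
transgression <- function(log2m, k_sd = 2, count_threshold = 50) {
  stopifnot(inherits(log2m, "expression_matrix"))
  ps <- parent_samples(log2m)
  transgression_counts(log2m$values, parent_cols = ps$sample,
                       parent_lines = ps$line,
                       mpril_cols = mpril_samples(log2m),
                       k_sd = k_sd, count_threshold = count_threshold)
}

# matrix-level worker, also used by the permutation FPR
transgression_counts <- function(values, parent_cols, parent_lines,
                                 mpril_cols, k_sd, count_threshold) {
  pv <- values[, parent_cols, drop = FALSE]
  lines <- sort(unique(parent_lines))
  n_i <- table(factor(parent_lines, levels = lines))
  ind <- outer(parent_lines, lines, "==") * 1
  means <- pv %*% sweep(ind, 2, n_i, "/")           # genes x lines
  fitted <- means %*% t(ind)
  pooled_sd <- sqrt(rowSums((pv - fitted)^2) / (length(parent_cols) - length(lines)))
  upper <- apply(means, 1, max) + k_sd * pooled_sd
  lower <- apply(means, 1, min) - k_sd * pooled_sd
  mp <- values[, mpril_cols, drop = FALSE]
  n_over <- rowSums(mp > upper)
  n_under <- rowSums(mp < lower)
  tibble::new_tibble(tibble::tibble(
    gene = rownames(values) %||% as.character(seq_len(nrow(values))),
    n_over = unname(n_over), n_under = unname(n_under),
    lower = unname(lower), upper = unname(upper),
    transgressive = unname((n_over + n_under) > count_threshold)),
    class = "transgression_result")
}

#' Permutation false-positive rate for the transgressive-gene count
#'
#' Each permutation relabels eight randomly chosen samples as the four
#' parental lines with two replicates each (all remaining samples act as
#' mpRILs), recomputes the transgressive-gene count, and reports
#' `FPR = mean(permuted count) / observed count`.
#'
#' @inheritParams transgression
#' @param n_perm Number of permutations.
#' @param seed Seed.
#' @return List `fpr`, `n_observed`, `n_permuted`.
#' @export
transgression_fpr <- function(log2m, k_sd = 2, count_threshold = 50,
                              n_perm = 100, seed = 1L) {
  stopifnot(n_perm >= 1)
  ps <- parent_samples(log2m)
  observed <- sum(transgression(log2m, k_sd, count_threshold)$transgressive)
  all_samp <- log2m$samples$sample
  lines4 <- sort(unique(ps$line))
  set.seed(seed)
  permuted <- vapply(seq_len(n_perm), function(i) {
    fake_parents <- sample(all_samp, 8)
    fake_mprils <- setdiff(all_samp, fake_parents)
    res <- transgression_counts(log2m$values, parent_cols = fake_parents,
                                parent_lines = rep(lines4, each = 2),
                                mpril_cols = fake_mprils,
                                k_sd = k_sd, count_threshold = count_threshold)
    sum(res$transgressive)
  }, numeric(1))
  if (observed == 0) {
    warn("Observed transgressive-gene count is 0; FPR undefined")
    fpr <- NA_real_
  } else {
    fpr <- mean(permuted) / observed
  }
  list(fpr = fpr, n_observed = observed, n_permuted = permuted)
}

#' Transgression count histogram
#'
#' Distribution of the per-gene number of transgressive mpRILs, split
#' into over (above the upper envelope), under, and total.
#'
#' @param x A `transgression_result` tibble from [transgression()].
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.transgression_result <- function(x, ...) {
  long <- tibble::tibble(gene = rep(x$gene, 3),
                         side = rep(c("over", "under", "total"), each = nrow(x)),
                         count = c(x$n_over, x$n_under, x$n_over + x$n_under))
  long <- long[long$count > 0, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$count, colour = .data$side)) +
    ggplot2::geom_freqpoly(binwidth = 5, boundary = 0) +
    ggplot2::scale_colour_manual(values = c(over = "darkgreen", under = "steelblue",
                                            total = "black")) +
    ggplot2::labs(x = "mpRILs beyond the parental envelope", y = "genes",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
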