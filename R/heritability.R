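#' Allele-sharing kinship matrix
#'
#' `K[i, j]` is the mean, over markers with non-missing data in both
#' lines, of `1 - |x_i - x_j|` for the binary alleles — the proportion of
#' shared alleles. Small negative eigenvalues arising from missing-data
#' patterns are clipped at zero with re-symmetrization, so the result can
#' serve as an additive-genetic covariance structure.
#'
#' @param genos A [genotype_matrix()].
#' @param lines Optional subset of line ids (default: all lines).
#' @return A `kinship_matrix`: symmetric numeric matrix with unit
#'   diagonal, values in `[0, 1]`.
#' @export
kinship <- function(genos, lines = NULL) {
  stopifnot(inherits(genos, "genotype_matrix"))
  X <- genos$alleles
  if (!is.null(lines)) X <- X[, lines, drop = FALSE]
  if (ncol(X) < 2) abort("Kinship needs at least 2 lines")
  P <- (!is.na(X)) * 1
  A <- X; A[is.na(A)] <- 0
  B <- (1 - X); B[is.na(B)] <- 0
  shared <- crossprod(P)
  if (any(shared == 0)) {
    idx <- which(shared == 0, arr.ind = TRUE)[1, ]
    abort(paste0("Lines ", colnames(X)[idx[1]], " and ", colnames(X)[idx[2]],
                 " share no non-missing markers"))
  }
  K <- (crossprod(A) + crossprod(B)) / shared
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-12) {
    K <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    K <- (K + t(K)) / 2
    dimnames(K) <- list(colnames(X), colnames(X))
  }
  structure(K, class = c("kinship_matrix", class(K)))
}

#' Shared eigendecomposition for REML heritability
#'
#' Restricted maximum likelihood for the model `y = mu + g + e`,
#' `g ~ N(0, sg2 * K)`, `e ~ N(0, se2 * I)`, works in the contrast space
#' orthogonal to the intercept. This helper eigendecomposes the centered
#' kinship once so that thousands of genes (and their permutations) can
#' be fitted against the same decomposition.
#'
#' @param K A [kinship()] matrix.
#' @return An object of class `kinship_eigen` to pass to
#'   [estimate_h2()].
#' @export
kinship_eigen <- function(K) {
  n <- nrow(K)
  S <- diag(n) - matrix(1 / n, n, n)
  e <- eigen(S %*% K %*% S, symmetric = TRUE)
  q <- n - 1
  xi <- pmax(e$values[seq_len(q)], 0)
  W <- e$vectors[, seq_len(q), drop = FALSE]
  # precomputed profile-REML grid over lambda = sg2/se2
  lambda_grid <- 10^seq(-5, 5, length.out = 41)
  D <- 1 / (outer(xi, lambda_grid) + 1)            # q x grid
  logdet <- colSums(log(outer(xi, lambda_grid) + 1))
  structure(list(n = n, q = q, xi = xi, W = W, lines = colnames(K),
                 lambda_grid = lambda_grid, D = D, logdet = logdet),
            class = "kinship_eigen")
}

# profile REML log-likelihood at ratio lambda given eta^2 in contrast space
reml_loglik <- function(lambda, eta2, xi) {
  q <- length(eta2)
  denom <- lambda * xi + 1
  se2 <- mean(eta2 / denom)
  -0.5 * (q * log(2 * pi * se2) + sum(log(denom)) + q)
}

#' Narrow-sense heritability by REML
#'
#' Maximizes the restricted likelihood over the variance ratio
#' `lambda = sg2 / se2` on a log grid refined by bounded scalar
#' optimization (search range `[1e-5, 1e5]`), then reports
#' `h2 = sg2 / (sg2 + se2) = lambda / (1 + lambda)`.
#'
#' @param y Phenotype per line (length `n_lines`), here a gene's log2
#'   expression ratio across the mpRILs.
#' @param K A [kinship()] matrix or a [kinship_eigen()] decomposition.
#' @return An object of class `h2_fit`: list with `h2`, `sigma_g2`,
#'   `sigma_e2`, `lambda`, `loglik`.
#' @export
estimate_h2 <- function(y, K) {
  dec <- if (inherits(K, "kinship_eigen")) K else kinship_eigen(K)
  if (length(y) != dec$n) abort("`y` must have one value per line")
  if (var(y) == 0) {
    warn("Constant phenotype; h2 set to 0")
    return(structure(list(h2 = 0, sigma_g2 = 0, sigma_e2 = 0,
                          lambda = 0, loglik = NA_real_), class = "h2_fit"))
  }
  eta2 <- drop(crossprod(dec$W, y))^2
  q <- dec$q
  # vectorized grid evaluation via the precomputed 1/(lambda*xi + 1)
  se2_grid <- drop(crossprod(eta2, dec$D)) / q
  ll_grid <- -0.5 * (q * log(2 * pi * se2_grid) + dec$logdet + q)
  i <- which.max(ll_grid)
  lo <- log10(dec$lambda_grid[max(i - 1, 1)])
  hi <- log10(dec$lambda_grid[min(i + 1, length(ll_grid))])
  opt <- optimize(function(l10) reml_loglik(10^l10, eta2, dec$xi),
                  interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
  cand_l10 <- c(opt$maximum, log10(dec$lambda_grid[i]))
  cand_ll <- c(opt$objective, ll_grid[i])
  best <- which.max(cand_ll)
  lambda <- 10^cand_l10[best]
  se2 <- mean(eta2 / (lambda * dec$xi + 1))
  sg2 <- lambda * se2
  structure(list(h2 = lambda / (1 + lambda), sigma_g2 = sg2, sigma_e2 = se2,
                 lambda = lambda, loglik = cand_ll[best]),
            class = "h2_fit")
}

#' @export
print.h2_fit <- function(x, ...) {
  cat(sprintf("<h2_fit> h2 = %.3f (sg2 = %.3g, se2 = %.3g)\n",
              x$h2, x$sigma_g2, x$sigma_e2))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.h2_fit <- function(x, ...) {
  tibble::tibble(term = c("genetic", "residual"),
                 variance = c(x$sigma_g2, x$sigma_e2))
}

#' @exportS3Method generics::glance
glance.h2_fit <- function(x, ...) {
  tibble::tibble(h2 = x$h2, lambda = x$lambda, loglik = x$loglik)
}

#' Permutation significance threshold for h2
#'
#' Permutes the phenotype across lines `n_perm` times, re-estimates the
#' heritability each time, and returns the empirical upper quantile: with
#' the defaults (100 permutations, 0.95), the 5th largest permuted value,
#' the per-gene 0.05 false-discovery threshold. A gene is called
#' significant when its observed h2 strictly exceeds the threshold.
#'
#' @inheritParams estimate_h2
#' @param n_perm Number of permutations (default 100; below 20 triggers
#'   an instability warning).
#' @param prob Quantile level (default 0.95).
#' @param seed Seed.
#' @return The threshold (scalar in `[0, 1]`).
#' @export
h2_permutation_threshold <- function(y, K, n_perm = 100, prob = 0.95, seed = 1L) {
  if (n_perm < 20) warn("Fewer than 20 permutations; threshold will be unstable")
  dec <- if (inherits(K, "kinship_eigen")) K else kinship_eigen(K)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm),
                 function(b) estimate_h2(sample(y), dec)$h2, numeric(1))
  sort(perm, decreasing = TRUE)[max(1L, ceiling(n_perm * (1 - prob)))]
}

#' Per-gene heritability scan
#'
#' Fits [estimate_h2()] for every gene against one shared
#' [kinship_eigen()] decomposition and, optionally, computes the
#' per-gene permutation threshold.
#'
#' @param Y Matrix genes x lines (log2 ratios), columns matching the
#'   kinship lines.
#' @param K [kinship()] matrix over the same lines.
#' @param n_perm Permutations per gene for the significance threshold
#'   (0 skips the permutation step).
#' @param prob Quantile level for the threshold.
#' @param seed Seed; per-gene permutation seeds are derived from it.
#' @return Tibble `gene`, `h2`, `sigma_g2`, `sigma_e2`, `loglik`,
#'   and when permuted `threshold` and `significant`.
#' @export
h2_scan <- function(Y, K, n_perm = 100, prob = 0.95, seed = 1L) {
  dec <- kinship_eigen(K)
  if (!is.null(colnames(Y)) && !is.null(dec$lines)) {
    if (!all(dec$lines %in% colnames(Y))) abort("`Y` lacks columns for some kinship lines")
    Y <- Y[, dec$lines, drop = FALSE]
  }
  genes <- rownames(Y) %||% as.character(seq_len(nrow(Y)))
  fits <- purrr::map(seq_len(nrow(Y)), function(i) estimate_h2(Y[i, ], dec))
  out <- tibble::tibble(
    gene = genes,
    h2 = vapply(fits, `[[`, numeric(1), "h2"),
    sigma_g2 = vapply(fits, `[[`, numeric(1), "sigma_g2"),
    sigma_e2 = vapply(fits, `[[`, numeric(1), "sigma_e2"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"))
  if (n_perm > 0) {
    out$threshold <- vapply(seq_len(nrow(Y)), function(i) {
      h2_permutation_threshold(Y[i, ], dec, n_perm = n_perm, prob = prob,
                               seed = seed + i)
    }, numeric(1))
    out$significant <- out$h2 > out$threshold
  }
  out
}

#' Heritability distribution by eQTL status
#'
#' Density of per-gene h2 for genes with and without a significant eQTL.
#'
#' @param h2_table Output of [h2_scan()].
#' @param records eQTL record tibble with `gene` and `significant`.
#' @export
plot_h2_by_eqtl <- function(h2_table, records) {
  with_eqtl <- records$gene[records$significant]
  d <- dplyr::mutate(h2_table, eqtl = .data$gene %in% with_eqtl)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$h2, fill = .data$eqtl)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0, position = "identity",
                            alpha = 0.6) +
    ggplot2::labs(x = expression(h^2), y = "genes", fill = "eQTL") +
    ggplot2::theme_minimal()
}
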