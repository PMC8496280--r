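#' Single-marker eQTL scan for one gene
#'
#' Per marker, ordinary least squares `y = b0 + b1 * x` over the lines
#' with a non-missing genotype; the p-value is the `F(1, n - 2)` test of
#' the marker term. Markers where either genotype class holds fewer than
#' `min_class` lines (including monomorphic markers) are reported with
#' `-log10(p) = 0` and `NA` slope.
#'
#' @param y Named phenotype per line (log2 expression ratio).
#' @param genos A [genotype_matrix()]; only columns named in `y` are
#'   used.
#' @param min_class Minimum lines per genotype class (default 5).
#' @return Tibble `marker`, `chromosome`, `position`, `sdp`,
#'   `neg_log10p`, `slope` in genome order.
#' @export
scan_gene <- function(y, genos, min_class = 5) {
  stopifnot(inherits(genos, "genotype_matrix"))
  lines <- names(y) %||% genotype_lines(genos)
  Y <- matrix(y, nrow = 1, dimnames = list("y", lines))
  sc <- scan_eqtl_matrix(Y, genos, min_class)
  out <- genos$markers
  out$neg_log10p <- unname(sc$neg_log10p[, 1])
  out$slope <- unname(sc$slope[, 1])
  if (all(out$neg_log10p == 0)) warn("All markers degenerate; profile is all zero")
  out
}

# Core vectorized scan: Y genes x lines, X markers x lines.
# Returns markers x genes matrices of -log10(p) and slope.
scan_eqtl_matrix <- function(Y, genos, min_class = 5) {
  X <- genos$alleles[, colnames(Y), drop = FALSE]
  n_all <- ncol(Y)
  complete <- !apply(is.na(X), 1, any)
  nl10p <- matrix(0, nrow(X), nrow(Y), dimnames = list(rownames(X), rownames(Y)))
  slope <- matrix(NA_real_, nrow(X), nrow(Y), dimnames = dimnames(nl10p))

  fill <- function(x_rows, idx) {
    # x_rows: markers x lines (no NA), all genes share the same line set
    n <- ncol(x_rows)
    if (n < 3) return()
    ones <- rowSums(x_rows)
    ok <- pmin(ones, n - ones) >= min_class
    if (!any(ok)) return()
    xc <- x_rows[ok, , drop = FALSE] - ones[ok] / n
    Yc <- Y[, colnames(x_rows), drop = FALSE]
    Yc <- Yc - rowMeans(Yc)
    sxx <- rowSums(xc^2)
    sxy <- xc %*% t(Yc)                      # markers_ok x genes
    syy <- rowSums(Yc^2)                     # genes
    ssr <- sxy^2 / sxx
    sse <- pmax(sweep(-ssr, 2, syy, "+"), 0)
    Fst <- ssr * (n - 2) / sse
    Fst[sse == 0] <- Inf
    p <- pf(Fst, 1, n - 2, lower.tail = FALSE)
    nl10p[idx[ok], ] <<- -log10(pmax(p, .Machine$double.xmin))
    slope[idx[ok], ] <<- sxy / sxx
  }

  if (any(complete)) fill(X[complete, , drop = FALSE], which(complete))
  for (m in which(!complete)) {
    obs <- !is.na(X[m, ])
    x <- X[m, obs]
    n <- sum(obs)
    if (n < 3) next
    if (min(sum(x), n - sum(x)) < min_class) next
    Yo <- Y[, obs, drop = FALSE]
    xc <- x - mean(x)
    yc <- Yo - rowMeans(Yo)
    sxx <- sum(xc^2)
    sxy <- drop(yc %*% xc)
    ssr <- sxy^2 / sxx
    sse <- pmax(rowSums(yc^2) - ssr, 0)
    Fst <- ifelse(sse == 0, Inf, ssr * (n - 2) / sse)
    p <- pf(Fst, 1, n - 2, lower.tail = FALSE)
    nl10p[m, ] <- -log10(pmax(p, .Machine$double.xmin))
    slope[m, ] <- sxy / sxx
  }
  list(neg_log10p = nl10p, slope = slope)
}

#' Genome-wide eQTL scan over all genes
#'
#' Runs the single-marker scan for every gene and records each gene's
#' peak: the most significant marker, ties broken by chromosome order
#' (I < II < III < IV < V < X) then lowest position.
#'
#' @param ratios Matrix genes x lines of log2 expression ratios (or an
#'   [expression_matrix()] with layer `"log2_ratio"`, whose mpRIL
#'   columns are used).
#' @param genos A [genotype_matrix()].
#' @param min_class Minimum lines per genotype class (default 5).
#' @param keep_profiles Keep the full markers x genes `-log10(p)` matrix
#'   (memory heavy at full scale; default `FALSE`).
#' @param chunk_size Genes per block for the matrix products.
#' @return Object of class `eqtl_scan`: `peaks` tibble (`gene`,
#'   `marker`, `chromosome`, `position`, `sdp`, `neg_log10p`, `slope`),
#'   `markers`, and optionally `profiles`.
#' @export
scan_eqtl <- function(ratios, genos, min_class = 5, keep_profiles = FALSE,
                      chunk_size = 1000) {
  if (inherits(ratios, "expression_matrix")) {
    mp <- mpril_samples(ratios)
    Y <- ratios$values[, mp, drop = FALSE]
    colnames(Y) <- names(mp)  # sample ids -> line ids
  } else {
    Y <- as.matrix(ratios)
  }
  lines <- intersect(colnames(Y), genotype_lines(genos))
  if (!length(lines)) abort("No shared lines between `ratios` and `genos`")
  Y <- Y[, lines, drop = FALSE]
  genes <- rownames(Y) %||% as.character(seq_len(nrow(Y)))
  rownames(Y) <- genes

  peak_idx <- integer(nrow(Y))
  peak_val <- numeric(nrow(Y))
  peak_slope <- numeric(nrow(Y))
  profiles <- if (keep_profiles) {
    matrix(0, nrow(genos$alleles), nrow(Y),
           dimnames = list(rownames(genos$alleles), genes))
  }
  for (start in seq(1, nrow(Y), by = chunk_size)) {
    rows <- start:min(start + chunk_size - 1, nrow(Y))
    sc <- scan_eqtl_matrix(Y[rows, , drop = FALSE], genos, min_class)
    # markers are genome-ordered, so the first argmax realizes the
    # declared tie-break (chromosome order, then lowest position)
    peak_idx[rows] <- apply(sc$neg_log10p, 2, which.max)
    peak_val[rows] <- sc$neg_log10p[cbind(peak_idx[rows], seq_along(rows))]
    peak_slope[rows] <- sc$slope[cbind(peak_idx[rows], seq_along(rows))]
    if (keep_profiles) profiles[, rows] <- sc$neg_log10p
  }
  peaks <- dplyr::bind_cols(
    tibble::tibble(gene = genes),
    genos$markers[peak_idx, c("marker", "chromosome", "position", "sdp")])
  peaks$neg_log10p <- peak_val
  peaks$slope <- peak_slope
  structure(list(peaks = peaks, markers = genos$markers, lines = lines,
                 profiles = profiles, min_class = min_class),
            class = "eqtl_scan")
}

#' @export
print.eqtl_scan <- function(x, ...) {
  cat(sprintf("<eqtl_scan> %d genes x %d markers over %d lines\n",
              nrow(x$peaks), nrow(x$markers), length(x$lines)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.eqtl_scan <- function(x, ...) x$peaks

#' @exportS3Method generics::glance
glance.eqtl_scan <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$peaks), n_markers = nrow(x$markers),
                 n_lines = length(x$lines))
}

#' Peak call from a single-gene profile
#'
#' The peak is the argmax of `-log10(p)` over the genome-ordered
#' profile, ties broken by chromosome order then lowest position; it is
#' significant when strictly above `threshold` (one eQTL per gene).
#'
#' @param profile Tibble from [scan_gene()].
#' @param threshold Significance cutoff on `-log10(p)` (strict `>`).
#' @return One-row tibble `marker`, `chromosome`, `position`, `sdp`,
#'   `neg_log10p`, `slope`, `significant`.
#' @export
call_peak <- function(profile, threshold) {
  ord <- order(match(profile$chromosome, mp_chromosomes()), profile$position)
  profile <- profile[ord, ]
  i <- which.max(profile$neg_log10p)
  out <- profile[i, c("marker", "chromosome", "position", "sdp",
                      "neg_log10p", "slope")]
  out$significant <- out$neg_log10p > threshold
  out
}

#' Permutation FP/TP significance threshold
#'
#' One permutation round: each gene's phenotype is independently
#' permuted across lines, the scan repeated, and permuted peaks
#' collected. For candidate thresholds `T` on a grid,
#' `FP(T) = #permuted peaks >= T` and `TP(T) = #observed peaks >= T`;
#' the threshold is the smallest grid `T` with `FP / TP < ratio`. The
#' ratio is only considered attainable where `TP >= 1/ratio`: with fewer
#' positives than that, `FP = 0` would satisfy any target vacuously, and
#' on null data a single lucky observed peak above the permuted maximum
#' would pass. Additional rounds (averaging FP) can be requested since
#' one round is noisy.
#'
#' @param scan An [scan_eqtl()] result (observed peaks).
#' @param ratios,genos The inputs used for the observed scan.
#' @param fp_tp_ratio Target FP/TP ratio (default 0.01, strict `<`).
#' @param grid_step Threshold grid step (default 0.05).
#' @param n_rounds Permutation rounds (default 1).
#' @param seed Seed.
#' @return List of class `eqtl_threshold`: `threshold`, `fp`, `tp`,
#'   `ratio`, `permuted_peaks`. Errors reporting the best achievable
#'   ratio when no grid point satisfies the target.
#' @export
eqtl_threshold <- function(scan, ratios, genos, fp_tp_ratio = 0.01,
                           grid_step = 0.05, n_rounds = 1, seed = 1L) {
  stopifnot(inherits(scan, "eqtl_scan"))
  if (inherits(ratios, "expression_matrix")) {
    mp <- mpril_samples(ratios)
    Y <- ratios$values[, mp, drop = FALSE]
    colnames(Y) <- names(mp)
  } else {
    Y <- as.matrix(ratios)
  }
  Y <- Y[, scan$lines, drop = FALSE]
  set.seed(seed)
  perm_peaks <- numeric(0)
  for (r in seq_len(n_rounds)) {
    Yp <- t(apply(Y, 1, sample))
    colnames(Yp) <- colnames(Y)
    rownames(Yp) <- rownames(Y)
    ps <- scan_eqtl(Yp, genos, min_class = scan$min_class)
    perm_peaks <- c(perm_peaks, ps$peaks$neg_log10p)
  }
  obs <- scan$peaks$neg_log10p
  grid <- seq(0, ceiling(max(obs) / grid_step) * grid_step, by = grid_step)
  fp <- vapply(grid, function(T) sum(perm_peaks >= T) / n_rounds, numeric(1))
  tp <- vapply(grid, function(T) sum(obs >= T), numeric(1))
  ok <- tp >= 1 / fp_tp_ratio & (fp / tp) < fp_tp_ratio
  if (!any(ok)) {
    usable <- tp >= 1 / fp_tp_ratio
    best <- if (any(usable)) min((fp / tp)[usable]) else NA_real_
    abort(sprintf(paste0(
      "No threshold reaches FP/TP < %g with TP >= %d; ",
      "best achievable ratio at a supported threshold is %s"),
      fp_tp_ratio, ceiling(1 / fp_tp_ratio),
      ifelse(is.na(best), "undefined (too few positives)",
             sprintf("%.3g", best))))
  }
  i <- which(ok)[1]
  structure(list(threshold = grid[i], fp = fp[i], tp = tp[i],
                 ratio = fp[i] / tp[i], permuted_peaks = perm_peaks),
            class = "eqtl_threshold")
}

#' @export
print.eqtl_threshold <- function(x, ...) {
  cat(sprintf("<eqtl_threshold> -log10(p) > %.2f (FP %d / TP %d = %.4f)\n",
              x$threshold, round(x$fp), x$tp, x$ratio))
  invisible(x)
}

#' Classify eQTLs as cis or trans
#'
#' An eQTL is *cis* when its peak lies on the gene's chromosome within
#' `window` bp of the gene start (inclusive), *trans* otherwise. The
#' type is only defined for significant records; others get `NA`.
#'
#' @param records Peak tibble with `gene`, `chromosome`, `position`,
#'   `significant` (e.g. [eqtl_records()] input).
#' @param annotation Tibble `gene`, `chromosome`, `start`.
#' @param window Cis window in bp (default 1e6).
#' @return `records` with a `type` column (`"cis"`, `"trans"`, or `NA`).
#' @export
classify_cis_trans <- function(records, annotation, window = 1e6) {
  missing <- setdiff(records$gene, annotation$gene)
  if (length(missing)) {
    abort(paste0("No annotation for gene(s): ",
                 paste(head(missing, 10), collapse = ", ")))
  }
  ann <- annotation[match(records$gene, annotation$gene), ]
  is_cis <- records$chromosome == ann$chromosome &
    abs(records$position - ann$start) <= window
  type <- ifelse(is_cis, "cis", "trans")
  if ("significant" %in% names(records)) type[!records$significant] <- NA
  records$type <- type
  records
}

#' Significant eQTL records with cis/trans types
#'
#' Applies the significance threshold to the scan peaks and classifies
#' the significant records.
#'
#' @param scan An [scan_eqtl()] result.
#' @param threshold Numeric cutoff or an [eqtl_threshold()] object.
#' @param annotation Gene annotation.
#' @param window Cis window in bp.
#' @param significant_only Drop non-significant genes (default `TRUE`).
#' @return Tibble of eQTL records.
#' @export
eqtl_records <- function(scan, threshold, annotation, window = 1e6,
                         significant_only = TRUE) {
  thr <- if (inherits(threshold, "eqtl_threshold")) threshold$threshold else threshold
  recs <- scan$peaks
  recs$significant <- recs$neg_log10p > thr
  recs <- classify_cis_trans(recs, annotation, window)
  if (significant_only) recs <- recs[recs$significant, ]
  recs
}

#' Tabulate significant eQTLs by SDP, chromosome and type
#'
#' The Table-1 aggregation: counts over the full 7 SDP x 6 chromosome x
#' {cis, trans} grid (zero cells included).
#'
#' @param records Significant, classified eQTL records.
#' @return Tibble `sdp`, `chromosome`, `type`, `n` covering every cell.
#' @export
tabulate_sdp <- function(records) {
  skeleton <- tidyr::expand_grid(sdp = sdp_levels(),
                                 chromosome = mp_chromosomes(),
                                 type = c("cis", "trans"))
  if (!nrow(records)) return(dplyr::mutate(skeleton, n = 0L))
  counts <- records |>
    dplyr::filter(!is.na(.data$type)) |>
    dplyr::count(.data$sdp, .data$chromosome, .data$type)
  skeleton |>
    dplyr::left_join(counts, by = c("sdp", "chromosome", "type")) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
}

#' Marginal totals of an SDP table
#'
#' @param sdp_table Output of [tabulate_sdp()].
#' @return List with `by_chromosome` (type x chromosome totals) and
#'   `grand` (type totals).
#' @export
sdp_table_totals <- function(sdp_table) {
  by_chr <- sdp_table |>
    dplyr::group_by(.data$type, .data$chromosome) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  grand <- sdp_table |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  list(by_chromosome = by_chr, grand = grand)
}

#' Cis/trans eQTL map
#'
#' eQTL peak position against gene position, coloured by SDP — the
#' classic cis-diagonal / trans-band view.
#'
#' @param records Significant eQTL records.
#' @param annotation Gene annotation.
#' @export
plot_eqtl_map <- function(records, annotation) {
  d <- dplyr::inner_join(records,
                         dplyr::rename(annotation, gene_chromosome = "chromosome",
                                       gene_start = "start"),
                         by = "gene")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position / 1e6,
                                  y = .data$gene_start / 1e6,
                                  colour = .data$sdp)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$gene_chromosome),
                        cols = ggplot2::vars(.data$chromosome),
                        scales = "free", space = "free") +
    ggplot2::labs(x = "eQTL position (Mbp)", y = "gene position (Mbp)",
                  colour = "SDP") +
    ggplot2::theme_minimal()
}
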