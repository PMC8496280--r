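#' Genotype matrix container
#'
#' Binary marker-by-line genotypes (1 = non-reference allele present, 0 =
#' absent, `NA` = missing) together with per-marker metadata. Markers are
#' stored sorted by (chromosome, position); the allele matrix rows are
#' reordered to match.
#'
#' @param alleles Numeric or integer matrix, markers x lines, values in
#'   `{0, 1, NA}`. Row names are marker ids, column names line ids.
#' @param markers Tibble/data frame with columns `marker`, `chromosome`
#'   (one of [mp_chromosomes()]), `position` (bp, 1-based integer), `sdp`
#'   (a label from [sdp_levels()]).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `alleles` (matrix) and `markers` (tibble).
#' @export
genotype_matrix <- function(alleles, markers) {
  markers <- tibble::as_tibble(markers)
  stopifnot(all(c("marker", "chromosome", "position", "sdp") %in% names(markers)))
  alleles <- as.matrix(alleles)
  if (is.null(rownames(alleles))) rownames(alleles) <- markers$marker
  if (!identical(sort(rownames(alleles)), sort(as.character(markers$marker)))) {
    abort("Row names of `alleles` must match `markers$marker`")
  }
  if (anyDuplicated(colnames(alleles))) abort("Line identifiers must be unique")
  if (!all(markers$chromosome %in% mp_chromosomes())) {
    abort("`chromosome` must be one of I, II, III, IV, V, X")
  }
  if (!all(markers$sdp %in% sdp_levels())) {
    abort("`sdp` must be one of the 7 informative SDP labels")
  }
  if (any(markers$position < 1)) abort("Marker positions must be >= 1")
  vals <- alleles[!is.na(alleles)]
  if (!all(vals %in% c(0, 1))) abort("Alleles must be 0, 1 or NA")
  ord <- order(match(markers$chromosome, mp_chromosomes()), markers$position)
  markers <- markers[ord, ]
  alleles <- alleles[as.character(markers$marker), , drop = FALSE]
  structure(list(alleles = alleles, markers = markers),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d markers x %d lines\n",
              nrow(x$alleles), ncol(x$alleles)))
  cat("SDP classes:",
      paste(names(table(x$markers$sdp)), table(x$markers$sdp),
            sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$alleles)

#' Line identifiers of a genotype matrix
#' @param genos A [genotype_matrix()].
#' @export
genotype_lines <- function(genos) colnames(genos$alleles)

#' Expression matrix container
#'
#' Gene-by-sample expression values with per-sample metadata and an
#' explicit layer tag recording what the values are.
#'
#' @param values Numeric matrix, genes x samples; row names are gene ids,
#'   column names sample ids.
#' @param samples Tibble with columns `sample`, `role` (`"mpRIL"` or
#'   `"parent"`), `line`, `replicate`. Parent lines must have exactly 2
#'   replicates, mpRILs exactly 1.
#' @param layer One of `"raw_fpkm"`, `"normalized"`, `"log2"`,
#'   `"log2_ratio"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples,
                              layer = c("raw_fpkm", "normalized", "log2", "log2_ratio")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("sample", "role", "line", "replicate") %in% names(samples)))
  if (anyDuplicated(samples$sample)) abort("Sample ids must be unique")
  if (!identical(colnames(values), as.character(samples$sample))) {
    samples <- samples[match(colnames(values), samples$sample), ]
    if (anyNA(samples$sample)) abort("Column names of `values` must match `samples$sample`")
  }
  if (!all(samples$role %in% c("mpRIL", "parent"))) {
    abort("Sample roles must be 'mpRIL' or 'parent'")
  }
  reps <- table(samples$line[samples$role == "parent"])
  if (length(reps) && !all(reps == 2)) {
    abort("Parental lines must have exactly 2 replicates")
  }
  mreps <- table(samples$line[samples$role == "mpRIL"])
  if (length(mreps) && !all(mreps == 1)) abort("mpRILs must have exactly 1 replicate")
  if (layer %in% c("raw_fpkm", "normalized") && any(values < 0, na.rm = TRUE)) {
    abort(sprintf("Negative values are not allowed in the %s layer", layer))
  }
  structure(list(values = values, samples = samples, layer = layer),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, layer '%s'\n",
              nrow(x$values), ncol(x$values), x$layer))
  cat(sprintf("  %d mpRIL sample(s), %d parental sample(s)\n",
              sum(x$samples$role == "mpRIL"), sum(x$samples$role == "parent")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# Replace the value matrix, updating the layer tag.
set_layer <- function(expr, values, layer) {
  expression_matrix(values, expr$samples, layer)
}

#' Subset an expression matrix by gene and/or sample
#'
#' @param expr An [expression_matrix()].
#' @param genes Optional character vector of gene ids to keep.
#' @param samples Optional character vector of sample ids to keep.
#' @export
subset_expression <- function(expr, genes = NULL, samples = NULL) {
  v <- expr$values
  s <- expr$samples
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing)) abort(paste0("Unknown gene(s): ", paste(head(missing, 5), collapse = ", ")))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    s <- s[match(samples, s$sample), ]
  }
  expression_matrix(v, s, expr$layer)
}

# sample ids of the mpRIL columns, named by line
mpril_samples <- function(expr) {
  s <- expr$samples[expr$samples$role == "mpRIL", ]
  setNames(as.character(s$sample), s$line)
}

parent_samples <- function(expr) {
  expr$samples[expr$samples$role == "parent", ]
}
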