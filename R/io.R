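#' Read and write the tab-delimited exchange formats
#'
#' All stages exchange plain tab-delimited text. Expression tables have a
#' first column of gene ids and one column per sample; genotype tables
#' carry `marker`, `chromosome`, `position`, `sdp` and one column per
#' line; sample metadata, gene annotation and GO associations are plain
#' key tables. Values round-trip at full double precision.
#'
#' @param path File path.
#' @param expr,genos Objects to write.
#' @param samples Sample metadata tibble (see [expression_matrix()]); for
#'   `read_expression()`, either a tibble or a path to one written by
#'   [write_samples()].
#' @param layer Layer tag for the values being read.
#' @name mpeqtl_io
NULL

#' @rdname mpeqtl_io
#' @export
read_expression <- function(path, samples, layer = "raw_fpkm") {
  # base parser: correctly rounded doubles, so the text round trip is exact
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  values <- vapply(tab[, -1, drop = FALSE], as.numeric, numeric(nrow(tab)))
  rownames(values) <- tab[[1]]
  if (is.character(samples) && length(samples) == 1L) samples <- read_samples(samples)
  expression_matrix(values, samples, layer)
}

#' @rdname mpeqtl_io
#' @export
write_expression <- function(expr, path) {
  tab <- tibble::as_tibble(expr$values, rownames = "gene")
  # 17 significant digits so doubles survive the text round trip exactly
  tab <- dplyr::mutate(tab, dplyr::across(-"gene", ~ sprintf("%.17g", .x)))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname mpeqtl_io
#' @export
read_samples <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(), role = readr::col_character(),
    line = readr::col_character(), replicate = readr::col_integer()))
}

#' @rdname mpeqtl_io
#' @export
write_samples <- function(samples, path) {
  readr::write_tsv(samples, path)
  invisible(path)
}

#' @rdname mpeqtl_io
#' @export
read_genotypes <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    marker = readr::col_character(), chromosome = readr::col_character(),
    position = readr::col_double(), sdp = readr::col_character(),
    .default = readr::col_double()))
  meta <- tab[, c("marker", "chromosome", "position", "sdp")]
  alleles <- as.matrix(tab[, setdiff(names(tab), names(meta))])
  rownames(alleles) <- tab$marker
  genotype_matrix(alleles, meta)
}

#' @rdname mpeqtl_io
#' @export
write_genotypes <- function(genos, path) {
  tab <- dplyr::bind_cols(genos$markers,
                          tibble::as_tibble(genos$alleles))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname mpeqtl_io
#' @export
read_annotation <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), chromosome = readr::col_character(),
    start = readr::col_double()))
}

#' @rdname mpeqtl_io
#' @param annotation Gene annotation tibble (`gene`, `chromosome`, `start`).
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation, path)
  invisible(path)
}

#' @rdname mpeqtl_io
#' @return `read_go_map()`: a tibble with columns `gene`, `term`
#'   (WormBase-style two-column gene-to-GO associations).
#' @export
read_go_map <- function(path) {
  readr::read_tsv(path, col_names = c("gene", "term"),
                  col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname mpeqtl_io
#' @param go_map Two-column tibble `gene`, `term`.
#' @export
write_go_map <- function(go_map, path) {
  readr::write_tsv(go_map[, c("gene", "term")], path, col_names = FALSE)
  invisible(path)
}
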