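#' The four founder isolates and chromosome set
#'
#' The population modelled here descends from four wild *C. elegans*
#' isolates; markers live on the six nuclear chromosomes.
#'
#' @export
mp_founders <- function() c("JU1511", "JU1926", "JU1931", "JU1941")

#' @rdname mp_founders
#' @export
mp_chromosomes <- function() c("I", "II", "III", "IV", "V", "X")

#' SNP distribution pattern (SDP) labels
#'
#' An SDP partitions the four founders into carriers and non-carriers of a
#' SNP allele. A subset and its complement describe the same biallelic
#' split, so the 14 proper subsets collapse to 7 informative classes. The
#' canonical display label is the two-founder label containing JU1511
#' (`"12"`, `"13"`, `"14"`, where the digit indexes JU1511's partner in
#' founder order), or the singleton founder name for 1-vs-3 splits.
#'
#' @param carriers Character vector of founder names carrying the allele
#'   (any proper, non-empty subset of [mp_founders()]).
#' @return `sdp_label()`: a single display label among
#'   `c("12","13","14","JU1511","JU1926","JU1931","JU1941")`.
#' @examples
#' sdp_label(c("JU1926", "JU1931"))  # complement of {JU1511, JU1941} -> "14"
#' sdp_label("JU1931")
#' @export
sdp_label <- function(carriers) {
  founders <- mp_founders()
  carriers <- unique(as.character(carriers))
  if (!all(carriers %in% founders)) {
    abort(paste0("Unknown founder(s): ",
                 paste(setdiff(carriers, founders), collapse = ", ")))
  }
  k <- length(carriers)
  if (k == 0L || k == 4L) {
    abort("SDP carriers must be a non-empty, proper subset of the founders")
  }
  if (k >= 3L) carriers <- setdiff(founders, carriers)  # use complement
  if (length(carriers) == 1L) return(carriers)
  if (!"JU1511" %in% carriers) carriers <- setdiff(founders, carriers)
  partner <- setdiff(carriers, "JU1511")
  c(JU1926 = "12", JU1931 = "13", JU1941 = "14")[[partner]]
}

#' @rdname sdp_label
#' @param label An SDP display label.
#' @return `sdp_carriers()`: the canonical carrier set for a label (the
#'   pair containing JU1511, or the singleton).
#' @export
sdp_carriers <- function(label) {
  lv <- sdp_levels()
  if (!label %in% lv) abort(paste0("Unknown SDP label: ", label))
  switch(label,
    "12" = c("JU1511", "JU1926"),
    "13" = c("JU1511", "JU1931"),
    "14" = c("JU1511", "JU1941"),
    label
  )
}

#' @rdname sdp_label
#' @return `sdp_levels()`: the 7 labels in Table-order.
#' @export
sdp_levels <- function() c("12", "13", "14", "JU1511", "JU1926", "JU1931", "JU1941")

# founder x sdp carrier indicator matrix (4 x 7)
sdp_carrier_matrix <- function() {
  m <- vapply(sdp_levels(),
              function(l) mp_founders() %in% sdp_carriers(l),
              logical(4))
  rownames(m) <- mp_founders()
  m
}
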