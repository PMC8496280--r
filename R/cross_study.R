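#' Call eQTLs from an external study's significance profiles
#'
#' Given a gene x marker `-log10(p)` profile matrix from another eQTL
#' experiment, takes each gene's most significant marker as the peak,
#' calls an eQTL when the peak strictly exceeds `threshold`, and types
#' it cis/trans by the 1-Mbp gene-start rule against that study's own
#' marker map and annotation.
#'
#' @param profiles Matrix genes x markers of `-log10(p)` values.
#' @param markers Tibble `marker`, `chromosome`, `position` describing
#'   the profile columns.
#' @param annotation Tibble `gene`, `chromosome`, `start`.
#' @param threshold Peak cutoff, strict `>` (default 3.5).
#' @param window Cis window in bp (default 1e6).
#' @param study Study identifier stored on the calls.
#' @return Tibble of class `study_calls`: one row per called gene with
#'   `study`, `gene`, `marker`, `chromosome`, `position`, `neg_log10p`,
#'   `type`.
#' @export
call_external <- function(profiles, markers, annotation, threshold = 3.5,
                          window = 1e6, study = "external") {
  profiles <- as.matrix(profiles)
  markers <- tibble::as_tibble(markers)
  if (ncol(profiles) != nrow(markers)) {
    abort("`profiles` must have one column per row of `markers`")
  }
  if (!is.null(colnames(profiles)) &&
      !identical(colnames(profiles), as.character(markers$marker))) {
    missing <- setdiff(colnames(profiles), markers$marker)
    if (length(missing)) {
      abort(paste0("Profile markers missing from the marker map: ",
                   paste(head(missing, 10), collapse = ", ")))
    }
    markers <- markers[match(colnames(profiles), markers$marker), ]
  }
  ord <- order(match(markers$chromosome, mp_chromosomes()), markers$position)
  markers <- markers[ord, ]
  profiles <- profiles[, ord, drop = FALSE]
  idx <- apply(profiles, 1, which.max)
  calls <- tibble::tibble(
    study = study,
    gene = rownames(profiles) %||% as.character(seq_len(nrow(profiles))),
    marker = as.character(markers$marker[idx]),
    chromosome = markers$chromosome[idx],
    position = markers$position[idx],
    neg_log10p = profiles[cbind(seq_len(nrow(profiles)), idx)])
  calls <- calls[calls$neg_log10p > threshold, ]
  calls$significant <- TRUE
  calls <- classify_cis_trans(calls, annotation, window)
  calls$significant <- NULL
  structure(calls, class = c("study_calls", class(calls)))
}

#' Directional eQTL overlap percentage between two studies
#'
#' `100 * |genes of the given type called in both| / |genes of that type
#' in theirs|` — the denominator is always the *other* study, so the
#' measure is directional and both directions are worth reporting.
#'
#' @param ours,theirs Call tibbles with `gene` and `type` columns (e.g.
#'   [call_external()] output or significant [eqtl_records()]).
#' @param type `"cis"` or `"trans"`.
#' @return Percentage (scalar); `NA` with a warning when the other study
#'   has no calls of that type.
#' @export
overlap_percentage <- function(ours, theirs, type = c("cis", "trans")) {
  type <- match.arg(type)
  ours_g <- unique(ours$gene[!is.na(ours$type) & ours$type == type])
  theirs_g <- unique(theirs$gene[!is.na(theirs$type) & theirs$type == type])
  if (!length(theirs_g)) {
    warn(sprintf("No %s calls in the reference study; overlap undefined", type))
    return(NA_real_)
  }
  100 * length(intersect(ours_g, theirs_g)) / length(theirs_g)
}

#' Cross-study overlap table
#'
#' Table-3-style report: per external study, the number of cis and trans
#' calls and the percentage of each also found in our calls.
#'
#' @param ours Our significant, typed eQTL records.
#' @param external Named list of external call tibbles.
#' @return Tibble `study`, `n_cis`, `cis_overlap_pct`, `n_trans`,
#'   `trans_overlap_pct`.
#' @export
cross_study_table <- function(ours, external) {
  purrr::imap_dfr(external, function(calls, name) {
    tibble::tibble(
      study = name,
      n_cis = sum(calls$type == "cis", na.rm = TRUE),
      cis_overlap_pct = overlap_percentage(ours, calls, "cis"),
      n_trans = sum(calls$type == "trans", na.rm = TRUE),
      trans_overlap_pct = overlap_percentage(ours, calls, "trans"))
  })
}
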