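#' Band borders with clipping and the shared-midpoint rule
#'
#' Computes `[peak - window, peak + window]` borders for a set of
#' same-SDP band peaks on one chromosome, clipped at `[0, chrom_length]`.
#' When two consecutive bands would overlap, the shared boundary is the
#' midpoint between their peaks snapped to the 0.01-Mbp reporting grid:
#' the lower band's right border is `floor(mid / 1e4) * 1e4`, the upper
#' band's left border the next grid position above it.
#'
#' @param peaks Peak positions in bp (one chromosome, one SDP).
#' @param chrom_length Chromosome length in bp.
#' @param window Window in bp (default 1e6).
#' @param grid_bp Reporting grid for shared boundaries (default 1e4 bp =
#'   0.01 Mbp).
#' @return Tibble `peak`, `left`, `right` (bp), sorted by peak.
#' @export
band_borders <- function(peaks, chrom_length, window = 1e6, grid_bp = 1e4) {
  peaks <- sort(peaks)
  left <- pmax(0, peaks - window)
  right <- pmin(chrom_length, peaks + window)
  if (length(peaks) > 1) {
    for (i in seq_len(length(peaks) - 1)) {
      if (right[i] >= left[i + 1]) {
        mid <- (peaks[i] + peaks[i + 1]) / 2
        lower_right <- floor(mid / grid_bp) * grid_bp
        right[i] <- lower_right
        left[i + 1] <- lower_right + grid_bp
      }
    }
  }
  tibble::tibble(peak = peaks, left = left, right = right)
}

#' Detect trans-eQTL hotspots (trans-bands)
#'
#' Counts, separately per SDP, the trans-eQTL peaks of that SDP lying
#' within `window` bp of each same-SDP marker on the same chromosome.
#' Markers with strictly more than `min_count` such eQTLs are hotspot
#' candidates; runs of candidates lying within one window of each other
#' merge into one band whose peak is the max-count marker (ties broken
#' by lowest position). Borders
#' come from [band_borders()]; member genes are the trans-eQTLs of that
#' SDP whose peak falls inside the borders.
#'
#' @param records Significant eQTL records (tibble with `gene`,
#'   `chromosome`, `position`, `sdp`, `type`); only `type == "trans"`
#'   rows are used.
#' @param genos A [genotype_matrix()] supplying the candidate markers.
#' @param chrom_lengths Tibble `chromosome`, `length_bp` (default:
#'   [default_chromosomes()]).
#' @param min_count Minimum eQTLs in the window, strict `>` (default
#'   100).
#' @param window Window to both sides in bp (default 1e6).
#' @return Tibble of class `trans_bands`: `sdp`, `chromosome`,
#'   `peak_bp`, `left_bp`, `right_bp`, `peak_mbp`, `left_mbp`,
#'   `right_mbp`, `n_eqtls`, `genes` (list column).
#' @export
detect_trans_bands <- function(records, genos,
                               chrom_lengths = default_chromosomes(),
                               min_count = 100, window = 1e6) {
  trans <- records[!is.na(records$type) & records$type == "trans", ]
  empty <- tibble::tibble(sdp = character(), chromosome = character(),
                          peak_bp = double(), left_bp = double(),
                          right_bp = double(), peak_mbp = double(),
                          left_mbp = double(), right_mbp = double(),
                          n_eqtls = integer(), genes = list())
  if (!nrow(trans)) return(structure(empty, class = c("trans_bands", class(empty))))

  out <- list()
  for (s in unique(trans$sdp)) {
    for (ch in unique(trans$chromosome[trans$sdp == s])) {
      eq <- trans[trans$sdp == s & trans$chromosome == ch, ]
      cand_markers <- genos$markers[genos$markers$sdp == s &
                                    genos$markers$chromosome == ch, ]
      if (!nrow(cand_markers)) next
      counts <- vapply(cand_markers$position,
                       function(p) sum(abs(eq$position - p) <= window),
                       numeric(1))
      hot <- counts > min_count
      if (!any(hot)) next
      pos <- cand_markers$position[hot]
      cnt <- counts[hot]
      ord <- order(pos)
      pos <- pos[ord]; cnt <- cnt[ord]
      # split candidates into runs; consecutive candidates further apart
      # than one window belong to distinct hotspots (their windows may
      # still overlap, which the shared-midpoint border rule resolves)
      run <- cumsum(c(1, diff(pos) > window))
      peaks <- unname(vapply(split(seq_along(pos), run), function(idx) {
        best <- idx[cnt[idx] == max(cnt[idx])]
        pos[best[which.min(pos[best])]]
      }, numeric(1)))
      len <- chrom_lengths$length_bp[chrom_lengths$chromosome == ch]
      bb <- band_borders(peaks, len, window)
      bb$sdp <- s
      bb$chromosome <- ch
      bb$genes <- purrr::map2(bb$left, bb$right, function(l, r) {
        eq$gene[eq$position >= l & eq$position <= r]
      })
      out[[length(out) + 1]] <- bb
    }
  }
  if (!length(out)) return(structure(empty, class = c("trans_bands", class(empty))))
  bands <- dplyr::bind_rows(out) |>
    dplyr::transmute(sdp = .data$sdp, chromosome = .data$chromosome,
                     peak_bp = .data$peak, left_bp = .data$left,
                     right_bp = .data$right,
                     peak_mbp = round(.data$peak / 1e6, 2),
                     left_mbp = round(.data$left / 1e6, 2),
                     right_mbp = round(.data$right / 1e6, 2),
                     n_eqtls = lengths(.data$genes),
                     genes = .data$genes) |>
    dplyr::arrange(match(.data$chromosome, mp_chromosomes()), .data$peak_bp)
  structure(bands, class = c("trans_bands", class(bands)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.trans_bands <- function(x, ...) {
  d <- tibble::as_tibble(x)
  ggplot2::ggplot(d) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$left_mbp, xmax = .data$right_mbp,
                                    ymin = 0, ymax = .data$n_eqtls,
                                    fill = .data$sdp), alpha = 0.7) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chromosome),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mbp)", y = "trans-eQTLs in band", fill = "SDP") +
    ggplot2::theme_minimal()
}
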