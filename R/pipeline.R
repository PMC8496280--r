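#' Pipeline configuration
#'
#' All stage thresholds in one place, each defaulting to the study's
#' operating point. A YAML file with any subset of these keys can be
#' merged over the defaults with [read_pipeline_config()].
#'
#' @param expression_filter Mean log2 fpkm cutoff (default -5).
#' @param pseudocount Zero replacement before log2 (default `2^-10`).
#' @param tukey_p Parental DE significance (default 0.001).
#' @param deg_n_perm Permutations for the DEG FPR (default 100).
#' @param transgression_k_sd Envelope width in pooled SDs (default 2).
#' @param transgression_count Count threshold, strict `>` (default 50).
#' @param transgression_n_perm Permutations for the transgression FPR.
#' @param h2_n_perm Permutations per gene for the h2 threshold (default
#'   100).
#' @param h2_prob Quantile for the h2 threshold (default 0.95).
#' @param eqtl_min_class Minimum lines per genotype class (default 5).
#' @param eqtl_fp_tp_ratio FP/TP target (default 0.01).
#' @param eqtl_grid_step Threshold grid step (default 0.05).
#' @param eqtl_n_rounds Permutation rounds (default 1).
#' @param eqtl_threshold Fixed `-log10(p)` threshold overriding the
#'   permutation FP/TP procedure (e.g. 5.35 for comparison runs;
#'   default `NULL`).
#' @param cis_window Cis window in bp (default 1e6).
#' @param band_min_count Trans-band minimum eQTL count, strict `>`
#'   (default 100).
#' @param band_window Trans-band window in bp (default 1e6).
#' @param go_p GO enrichment cutoff (default 1e-5).
#' @param go_min_set Minimum background term size, strict `>` (default
#'   3).
#' @param cross_study_threshold External peak cutoff (default 3.5).
#' @param stages Character vector of stage toggles, any of
#'   `c("parental", "transgression", "heritability", "eqtl",
#'   "trans_bands", "enrichment")`.
#' @param seed Master seed; per-stage sub-seeds are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(expression_filter = -5,
                            pseudocount = 2^-10,
                            tukey_p = 0.001,
                            deg_n_perm = 100,
                            transgression_k_sd = 2,
                            transgression_count = 50,
                            transgression_n_perm = 100,
                            h2_n_perm = 100,
                            h2_prob = 0.95,
                            eqtl_min_class = 5,
                            eqtl_fp_tp_ratio = 0.01,
                            eqtl_grid_step = 0.05,
                            eqtl_n_rounds = 1,
                            eqtl_threshold = NULL,
                            cis_window = 1e6,
                            band_min_count = 100,
                            band_window = 1e6,
                            go_p = 1e-5,
                            go_min_set = 3,
                            cross_study_threshold = 3.5,
                            stages = c("parental", "transgression",
                                       "heritability", "eqtl",
                                       "trans_bands", "enrichment"),
                            seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with configuration keys.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(formals(pipeline_config)))
  if (length(unknown)) {
    abort(paste0("Unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, user)
}

# deterministic per-stage sub-seed
pipeline_seed <- function(seed, stage) {
  offset <- c(deg_fpr = 101L, transgression_fpr = 211L, h2 = 307L,
              eqtl_perm = 401L)[[stage]]
  as.integer((as.numeric(seed) %% 1000003) * 1013 + offset)
}

#' Run the full mpRIL expression-genetics pipeline
#'
#' Executes, on a simulated or user-supplied study: expression filtering
#' and normalization, parental differential expression with permutation
#' FPR, transgression with permutation FPR, kinship/REML heritability
#' with per-gene permutation thresholds, the genome-wide eQTL scan with
#' the permutation FP/TP threshold, cis/trans classification and SDP
#' tabulation, trans-band detection and per-band GO enrichment. Writes
#' every result table plus a run manifest when `out_dir` is given; with
#' a fixed seed reruns are byte-identical.
#'
#' @param data A list with `expr` (raw fpkm [expression_matrix()]),
#'   `genos`, `annotation`, optionally `go_map` — e.g. an `mp_sim` from
#'   [simulate_cross()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for the tab-delimited
#'   tables and the `manifest.yaml`.
#' @return List of class `mp_pipeline` with the per-stage results and a
#'   `manifest` of counts and settings.
#' @export
run_pipeline <- function(data, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  res <- list(config = config)

  prep <- prepare_expression(data$expr, config$expression_filter,
                             config$pseudocount)
  res$genes <- prep$genes
  manifest <- list(seed = seed, package_version = as.character(utils::packageVersion("mpeqtl")),
                   n_genes_input = nrow(data$expr$values),
                   n_genes_kept = length(prep$genes))

  if ("parental" %in% config$stages) {
    res$parental <- parental_de(prep$log2, config$tukey_p)
    res$deg_fpr <- deg_fpr(prep$log2, config$tukey_p, config$deg_n_perm,
                           seed = pipeline_seed(seed, "deg_fpr"))
    res$replicate_cor <- replicate_correlation(prep$log2)
    manifest$n_deg <- length(res$parental$deg_genes)
    manifest$deg_fpr <- res$deg_fpr$fpr
  }

  if ("transgression" %in% config$stages) {
    res$transgression <- transgression(prep$log2, config$transgression_k_sd,
                                       config$transgression_count)
    res$transgression_fpr <- transgression_fpr(
      prep$log2, config$transgression_k_sd, config$transgression_count,
      config$transgression_n_perm,
      seed = pipeline_seed(seed, "transgression_fpr"))
    manifest$n_transgressive <- sum(res$transgression$transgressive)
    manifest$transgression_fpr <- res$transgression_fpr$fpr
  }

  mp <- mpril_samples(prep$ratio)
  Y <- prep$ratio$values[, mp, drop = FALSE]
  colnames(Y) <- names(mp)
  mpril_lines <- intersect(names(mp), genotype_lines(data$genos))

  if ("heritability" %in% config$stages) {
    K <- kinship(data$genos, lines = mpril_lines)
    res$kinship <- K
    res$h2 <- h2_scan(Y[, mpril_lines, drop = FALSE], K,
                      n_perm = config$h2_n_perm, prob = config$h2_prob,
                      seed = pipeline_seed(seed, "h2"))
    manifest$n_h2_significant <- if (config$h2_n_perm > 0) sum(res$h2$significant) else NA
  }

  if ("eqtl" %in% config$stages) {
    scan <- scan_eqtl(Y, data$genos, min_class = config$eqtl_min_class)
    res$scan <- scan
    if (is.null(config$eqtl_threshold)) {
      thr <- eqtl_threshold(scan, Y, data$genos,
                            fp_tp_ratio = config$eqtl_fp_tp_ratio,
                            grid_step = config$eqtl_grid_step,
                            n_rounds = config$eqtl_n_rounds,
                            seed = pipeline_seed(seed, "eqtl_perm"))
      res$threshold <- thr
      thr_value <- thr$threshold
    } else {
      thr_value <- config$eqtl_threshold
    }
    res$records <- eqtl_records(scan, thr_value, data$annotation,
                                window = config$cis_window)
    res$sdp_table <- tabulate_sdp(res$records)
    manifest$eqtl_threshold <- thr_value
    manifest$n_eqtl <- nrow(res$records)
    manifest$n_cis <- sum(res$records$type == "cis")
    manifest$n_trans <- sum(res$records$type == "trans")
  }

  if ("trans_bands" %in% config$stages && !is.null(res$records)) {
    lens <- if (!is.null(data$chrom_lengths)) data$chrom_lengths else
      if (!is.null(data$config)) data$config$chromosomes else default_chromosomes()
    res$bands <- detect_trans_bands(res$records, data$genos,
                                    chrom_lengths = lens,
                                    min_count = config$band_min_count,
                                    window = config$band_window)
    manifest$n_trans_bands <- nrow(res$bands)
    manifest$n_trans_in_bands <- length(unique(unlist(res$bands$genes)))
  }

  if ("enrichment" %in% config$stages && !is.null(res$bands) &&
      !is.null(data$go_map) && nrow(res$bands)) {
    res$enrichment <- purrr::map_dfr(seq_len(nrow(res$bands)), function(i) {
      e <- go_enrichment(res$bands$genes[[i]], data$go_map, prep$genes,
                         p_threshold = config$go_p, min_set = config$go_min_set)
      if (nrow(e)) e$band <- i
      e
    })
    manifest$n_enriched_terms <- if (!is.null(res$enrichment)) nrow(res$enrichment) else 0L
  }

  res$manifest <- manifest
  res <- structure(res, class = "mp_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @export
print.mp_pipeline <- function(x, ...) {
  cat("<mp_pipeline>\n")
  m <- x$manifest
  for (k in names(m)) cat(sprintf("  %s: %s\n", k, paste(m[[k]], collapse = " ")))
  invisible(x)
}

# write all stage tables + manifest; deterministic output for a fixed seed
write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(tab, name) readr::write_tsv(tab, file.path(out_dir, name))
  if (!is.null(res$parental)) {
    w(res$parental$pairwise, "parental_pairwise.tsv")
    w(res$parental$pair_counts, "parental_pair_counts.tsv")
    w(res$parental$intersections, "parental_intersections.tsv")
    w(res$replicate_cor, "replicate_correlation.tsv")
  }
  if (!is.null(res$transgression)) w(tibble::as_tibble(res$transgression), "transgression.tsv")
  if (!is.null(res$h2)) w(res$h2, "heritability.tsv")
  if (!is.null(res$records)) {
    w(res$records, "eqtl_records.tsv")
    w(res$sdp_table, "eqtl_sdp_table.tsv")
  }
  if (!is.null(res$bands)) {
    bands <- tibble::as_tibble(res$bands)
    bands$genes <- vapply(bands$genes, paste, character(1), collapse = ",")
    w(bands, "trans_bands.tsv")
  }
  if (!is.null(res$enrichment) && nrow(res$enrichment)) {
    w(res$enrichment, "go_enrichment.tsv")
  }
  yaml::write_yaml(res$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
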