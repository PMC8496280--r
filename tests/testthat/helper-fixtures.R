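# Shared small fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# 40 mpRILs, 200 markers, 80 genes, no planted effects
small_sim <- function() {
  fixture("small_sim", function() {
    simulate_cross(sim_config(n_lines = 40, n_markers = 200, n_genes = 80,
                              noise_sd = 0.4, dev_covariate_sd = 0.3,
                              seed = 42))
  })
}

# hand-built expression matrix: 4 parents x 2 reps + n mpRILs
make_expr <- function(values, n_mpril, layer = "log2") {
  founders <- mp_founders()
  mp <- if (n_mpril > 0) {
    tibble::tibble(sample = paste0("L", seq_len(n_mpril)), role = "mpRIL",
                   line = paste0("L", seq_len(n_mpril)), replicate = 1L)
  }
  samples <- dplyr::bind_rows(
    mp,
    tibble::tibble(sample = paste0(rep(founders, each = 2), "_", 1:2),
                   role = "parent", line = rep(founders, each = 2),
                   replicate = rep(1:2, 4)))
  colnames(values) <- samples$sample
  expression_matrix(values, samples, layer)
}

# parental sample columns in make_expr() order
parent_cols <- function(n_mpril) n_mpril + 1:8

# independent REML oracle: dense lambda-grid profile restricted likelihood
# computed from the generic matrix formulae (no reuse of package internals)
reml_grid_oracle <- function(y, K, n_grid = 1e4) {
  n <- length(y)
  A <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1, drop = FALSE]
  q <- n - 1
  lambdas <- 10^seq(-5, 5, length.out = n_grid)
  ll <- vapply(lambdas, function(lam) {
    Sigma <- t(A) %*% (lam * K + diag(n)) %*% A
    eta <- drop(t(A) %*% y)
    s2 <- drop(crossprod(eta, solve(Sigma, eta))) / q
    -0.5 * (determinant(Sigma)$modulus[1] + q * log(s2) + q + q * log(2 * pi))
  }, numeric(1))
  lam <- lambdas[which.max(ll)]
  lam / (1 + lam)
}

# closed-form correlation/t-test oracle for the single-marker scan
scan_oracle_p <- function(y, x) {
  ok <- !is.na(x)
  x <- x[ok]; y <- y[ok]
  n <- length(y)
  r <- suppressWarnings(cor(x, y))
  if (is.na(r)) return(NA_real_)
  t <- r * sqrt((n - 2) / max(1 - r^2, 0))
  2 * pt(-abs(t), n - 2)
}

# brute-force hypergeometric upper tail by pmf enumeration
hyper_oracle <- function(k, m, n, N) {
  ks <- k:min(m, n)
  sum(choose(m, ks) * choose(N - m, n - ks)) / choose(N, n)
}

# naive double-loop allele-sharing kinship
kinship_oracle <- function(X) {
  nl <- ncol(X)
  K <- matrix(NA_real_, nl, nl, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(nl)) {
    for (j in seq_len(nl)) {
      ok <- !is.na(X[, i]) & !is.na(X[, j])
      K[i, j] <- mean(1 - abs(X[ok, i] - X[ok, j]))
    }
  }
  K
}

# small planted study reused across pipeline tests
pipeline_sim <- function() {
  fixture("pipeline_sim", function() {
    base_cfg <- function(effects = NULL) {
      sim_config(n_lines = 80, n_markers = 400, n_genes = 120,
                 noise_sd = 0.4, dev_covariate_sd = 0.2,
                 effects = effects, seed = 77)
    }
    # anchor the planted regulator on an actual JU1511 marker so its
    # target peaks co-locate (the genome realization is seed-identical)
    g <- simulate_genomes(base_cfg())
    m <- g$genos$markers
    cand <- m[m$chromosome == "I" & m$sdp == "JU1511", ]
    locus <- cand$position[which.min(abs(cand$position - 7e6))]
    effects <- dplyr::bind_rows(
      purrr::map_dfr(1:12, function(i) cis_effect("V", i * 1.5e6, 1.2, "14")),
      trans_band_effect("I", locus, 1.1, "JU1511", n_targets = 25))
    simulate_cross(base_cfg(effects))
  })
}

pipeline_cfg <- function(...) {
  pipeline_config(deg_n_perm = 10, transgression_n_perm = 10,
                  transgression_count = 20, h2_n_perm = 25,
                  eqtl_fp_tp_ratio = 0.05, band_min_count = 15,
                  seed = 7L, ...)
}


# parameter-recovery study: 40 planted cis effects each explaining ~25% of
# variance (beta = sqrt(1/3) on an SDP-14 background, noise SD 0.5) plus a
# major-effect (1.0 log2) JU1931 trans-band regulator with 150 target
# genes, at n = 200 lines and the study's 9000-marker density
recovery_run <- function() {
  cfg0 <- sim_config(n_lines = 200, n_markers = 9000, n_genes = 1000,
                     noise_sd = 0.5, dev_covariate_sd = 0, seed = 931)
  ann <- simulate_annotation(cfg0)
  g <- simulate_genomes(cfg0)

  set.seed(933)
  cis_genes <- sample(ann$gene, 40)
  cand <- g$genos$markers[g$genos$markers$chromosome == "V" &
                          g$genos$markers$sdp == "JU1931", ]
  locus <- cand$position[which.min(abs(cand$position - 10e6))]
  pool <- setdiff(ann$gene[ann$chromosome != "V"], cis_genes)
  trans_targets <- sample(pool, 150)

  beta <- sqrt(1 / 3)  # 25% of variance at allele frequency 1/2
  effects <- dplyr::bind_rows(
    purrr::map_dfr(cis_genes, function(gn) {
      a <- ann[ann$gene == gn, ]
      cis_effect(a$chromosome, a$start, beta, "14", gene = gn)
    }),
    trans_band_effect("V", locus, 1.0, "JU1931",
                      target_genes = trans_targets))
  cfg <- sim_config(n_lines = 200, n_markers = 9000, n_genes = 1000,
                    noise_sd = 0.5, dev_covariate_sd = 0,
                    effects = effects, seed = 931)
  sim <- simulate_cross(cfg)

  prep <- prepare_expression(sim$expr)
  sc <- scan_eqtl(prep$ratio, sim$genos)
  thr <- eqtl_threshold(sc, prep$ratio, sim$genos, fp_tp_ratio = 0.01,
                        seed = 935)
  recs <- eqtl_records(sc, thr, sim$annotation)

  detected <- recs[recs$gene %in% cis_genes, ]
  loc_ok <- vapply(seq_len(nrow(detected)), function(i) {
    a <- sim$annotation[sim$annotation$gene == detected$gene[i], ]
    detected$chromosome[i] == a$chromosome &&
      abs(detected$position[i] - a$start) <= 1e6
  }, logical(1))

  bands <- detect_trans_bands(recs, sim$genos,
                              chrom_lengths = cfg$chromosomes,
                              min_count = 100)
  gaps <- diff(cand$position)
  i <- which(cand$position == locus)
  spacing <- max(gaps[max(1, i - 1)], gaps[min(i, length(gaps))])

  lines <- sprintf("L%03d", 1:200)
  K <- kinship(sim$genos, lines = lines)
  mp <- mpril_samples(prep$ratio)
  Y <- prep$ratio$values[, mp, drop = FALSE]
  colnames(Y) <- names(mp)
  h <- h2_scan(Y[, lines], K, n_perm = 0)

  list(sim = sim, threshold = thr, records = recs,
       cis_power = nrow(detected) / length(cis_genes),
       cis_localized = if (nrow(detected)) mean(loc_ok) else 0,
       bands = bands, locus = locus, marker_spacing = spacing,
       h2_with_eqtl = mean(h$h2[h$gene %in% recs$gene]),
       h2_without_eqtl = mean(h$h2[!h$gene %in% recs$gene]))
}
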