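mpril_ids <- function(n) sprintf("L%03d", seq_len(n))

test_that("scan p-values match the closed-form correlation t-test oracle", {
  sim <- small_sim()
  lines <- mpril_ids(40)
  set.seed(401)
  Y <- matrix(rnorm(50 * 40), 50, 40, dimnames = list(paste0("g", 1:50), lines))
  # give some genes real signal from random markers
  for (i in 1:20) {
    m <- sample(nrow(sim$genos$alleles), 1)
    Y[i, ] <- Y[i, ] + 1.5 * sim$genos$alleles[m, lines]
  }
  X <- sim$genos$alleles[, lines]
  ones <- rowSums(X)
  for (g in sample(rownames(Y), 50)) {
    prof <- scan_gene(Y[g, ], sim$genos, min_class = 5)
    testable <- pmin(ones, 40 - ones) >= 5
    p_impl <- 10^(-prof$neg_log10p)
    p_oracle <- vapply(seq_len(nrow(X)),
                       function(m) scan_oracle_p(Y[g, ], X[m, ]), numeric(1))
    expect_lt(max(abs(p_impl[testable] - p_oracle[testable])), 1e-10)
    expect_true(all(prof$neg_log10p[!testable] == 0))
  }
})

test_that("a phenotype equal to a genotype row is a near-perfect fit", {
  g <- simulate_genomes(sim_config(n_lines = 200, n_markers = 300,
                                   n_genes = 5, seed = 71))
  lines <- mpril_ids(200)
  X <- g$genos$alleles[, lines]
  m <- which(pmin(rowSums(X), 200 - rowSums(X)) >= 20)[1]
  prof <- scan_gene(X[m, ], g$genos, min_class = 5)
  expect_gt(prof$neg_log10p[m], 15)
  expect_identical(prof$marker[which.max(prof$neg_log10p)], prof$marker[m])
})

test_that("degenerate markers yield a zero profile entry and a warning overall", {
  X <- rbind(mono = rep(1, 12), rare = c(1, rep(0, 11)),
             ok = rep(c(0, 1), 6))
  colnames(X) <- mpril_ids(12)
  markers <- tibble::tibble(marker = rownames(X), chromosome = "I",
                            position = c(1e5, 2e5, 3e5), sdp = "14")
  genos <- genotype_matrix(X, markers)
  set.seed(402)
  y <- setNames(rnorm(12), colnames(X))
  prof <- scan_gene(y, genos, min_class = 5)
  expect_equal(prof$neg_log10p[prof$marker == "mono"], 0)
  expect_equal(prof$neg_log10p[prof$marker == "rare"], 0)
  expect_gt(prof$neg_log10p[prof$marker == "ok"], 0)

  all_bad <- genotype_matrix(X[1:2, ], markers[1:2, ])
  expect_warning(p2 <- scan_gene(y, all_bad, min_class = 5), "degenerate")
  expect_true(all(p2$neg_log10p == 0))
})

test_that("scan p-values are invariant to affine phenotype transforms", {
  sim <- small_sim()
  lines <- mpril_ids(40)
  set.seed(403)
  y <- setNames(rnorm(40), lines)
  a <- scan_gene(y, sim$genos)
  b <- scan_gene(5 * y + 2, sim$genos)
  expect_equal(a$neg_log10p, b$neg_log10p, tolerance = 1e-9)
})

test_that("peak calling breaks ties by chromosome order then position", {
  prof <- tibble::tibble(
    marker = c("a", "b", "c"),
    chromosome = c("V", "II", "II"),
    position = c(1e6, 9e6, 3e6),
    sdp = "14",
    neg_log10p = c(7, 7, 5),
    slope = 1)
  pk <- call_peak(prof, threshold = 5.35)
  expect_identical(pk$marker, "b")
  expect_identical(pk$chromosome, "II")
  expect_true(pk$significant)
  # threshold is strict: a 5.30 peak fails a 5.35 cutoff
  prof2 <- dplyr::mutate(prof, neg_log10p = c(5.30, 5.30, 1))
  expect_false(call_peak(prof2, threshold = 5.35)$significant)
})

test_that("cis/trans classification applies the inclusive 1-Mbp same-chromosome rule", {
  ann <- tibble::tibble(gene = c("g1", "g2", "g3"),
                        chromosome = c("I", "II", "I"),
                        start = c(2e6, 5e6, 4e6))
  recs <- tibble::tibble(gene = c("g1", "g2", "g3"),
                         chromosome = c("I", "I", "I"),
                         position = c(2.5e6, 5e6, 3e6),
                         significant = TRUE)
  out <- classify_cis_trans(recs, ann, window = 1e6)
  expect_identical(out$type, c("cis", "trans", "cis"))
  # distance exactly 1 Mbp is cis (inclusive)
  rec_edge <- tibble::tibble(gene = "g1", chromosome = "I", position = 3e6,
                             significant = TRUE)
  expect_identical(classify_cis_trans(rec_edge, ann)$type, "cis")
  rec_out <- tibble::tibble(gene = "g1", chromosome = "I", position = 3e6 + 1,
                            significant = TRUE)
  expect_identical(classify_cis_trans(rec_out, ann)$type, "trans")
  expect_error(classify_cis_trans(
    tibble::tibble(gene = "nope", chromosome = "I", position = 1,
                   significant = TRUE), ann), "No annotation")
})

test_that("the permutation FP/TP threshold separates planted from permuted peaks", {
  cfg <- sim_config(n_lines = 100, n_markers = 300, n_genes = 80,
                    noise_sd = 0.4, dev_covariate_sd = 0, seed = 73,
                    effects = do.call(dplyr::bind_rows, lapply(1:30, function(i) {
                      trans_band_effect("II", 7e6, 2, "14", n_targets = 1)
                    })))
  sim <- simulate_cross(cfg)
  prep <- prepare_expression(sim$expr)
  sc <- scan_eqtl(prep$ratio, sim$genos)
  thr <- eqtl_threshold(sc, prep$ratio, sim$genos, fp_tp_ratio = 0.05, seed = 74)
  max_perm <- max(thr$permuted_peaks)
  expect_lte(thr$threshold, ceiling(max_perm / 0.05) * 0.05 + 0.05)
  expect_lt(thr$ratio, 0.05)
  expect_equal(round(thr$threshold / 0.05) * 0.05, thr$threshold,
               tolerance = 1e-9)
})

test_that("a pure-null scan reports the unattainable-ratio error", {
  g <- simulate_genomes(sim_config(n_lines = 60, n_markers = 150,
                                   n_genes = 5, seed = 75))
  set.seed(404)
  Y <- matrix(rnorm(40 * 60), 40, 60,
              dimnames = list(paste0("g", 1:40), mpril_ids(60)))
  sc <- scan_eqtl(Y, g$genos)
  expect_error(eqtl_threshold(sc, Y, g$genos, fp_tp_ratio = 0.01, seed = 76),
               "best achievable ratio")
})

test_that("SDP tabulation covers the full grid and conserves totals", {
  empty <- tabulate_sdp(tibble::tibble(gene = character(), sdp = character(),
                                       chromosome = character(),
                                       type = character()))
  expect_equal(nrow(empty), 7 * 6 * 2)
  expect_true(all(empty$n == 0))

  recs <- tibble::tibble(
    gene = paste0("g", 1:5),
    sdp = c("14", "14", "JU1931", "12", "14"),
    chromosome = c("I", "I", "V", "X", "II"),
    type = c("trans", "trans", "trans", "cis", "cis"))
  tab <- tabulate_sdp(recs)
  tot <- sdp_table_totals(tab)
  expect_equal(sum(tab$n), 5)
  expect_equal(tot$grand$n[tot$grand$type == "cis"], 2)
  expect_equal(tot$grand$n[tot$grand$type == "trans"], 3)
  expect_equal(tab$n[tab$sdp == "14" & tab$chromosome == "I" &
                     tab$type == "trans"], 2)
})
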