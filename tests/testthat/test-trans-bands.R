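# genotype map with controllable marker placement on one or two chromosomes
make_markers <- function(positions, chromosome = "I", sdp = "14") {
  n <- length(positions)
  X <- matrix(rep(c(0, 1), length.out = 8 * n), n, 8,
              dimnames = list(sprintf("m%03d", seq_len(n)), sprintf("L%03d", 1:8)))
  genotype_matrix(X, tibble::tibble(marker = rownames(X),
                                    chromosome = chromosome,
                                    position = positions, sdp = sdp))
}

trans_records <- function(n, position, sdp = "14", chromosome = "I",
                          prefix = "g") {
  tibble::tibble(gene = paste0(prefix, seq_len(n)), sdp = sdp,
                 chromosome = chromosome, position = position, type = "trans")
}

test_that("a single hotspot yields one band with window borders", {
  genos <- make_markers(c(1.03e6, 8e6))
  recs <- trans_records(150, 1.03e6)
  bands <- detect_trans_bands(recs, genos, min_count = 100, window = 1e6)
  expect_equal(nrow(bands), 1)
  expect_equal(bands$peak_mbp, 1.03)
  expect_equal(bands$left_mbp, 0.03)
  expect_equal(bands$right_mbp, 2.03)
  expect_equal(bands$n_eqtls, 150L)
  expect_setequal(bands$genes[[1]], recs$gene)
})

test_that("exactly min_count eQTLs in the window is not a band", {
  genos <- make_markers(c(1.03e6, 8e6))
  bands <- detect_trans_bands(trans_records(100, 1.03e6), genos,
                              min_count = 100, window = 1e6)
  expect_equal(nrow(bands), 0)
  bands101 <- detect_trans_bands(trans_records(101, 1.03e6), genos,
                                 min_count = 100, window = 1e6)
  expect_equal(nrow(bands101), 1)
})

test_that("borders clip at the chromosome ends", {
  genos <- make_markers(c(0.83e6, 8e6))
  bands <- detect_trans_bands(trans_records(120, 0.83e6), genos,
                              min_count = 100, window = 1e6)
  expect_equal(bands$left_mbp, 0)
  expect_equal(bands$right_mbp, 1.83)
})

test_that("overlapping same-SDP bands share a midpoint boundary on the 10-kb grid", {
  genos <- make_markers(c(14.69e6, 16.60e6), chromosome = "X", sdp = "JU1941")
  recs <- dplyr::bind_rows(
    trans_records(150, 14.69e6, sdp = "JU1941", chromosome = "X", prefix = "a"),
    trans_records(200, 16.60e6, sdp = "JU1941", chromosome = "X", prefix = "b"))
  bands <- detect_trans_bands(recs, genos, min_count = 100, window = 1e6)
  expect_equal(nrow(bands), 2)
  expect_equal(bands$left_mbp, c(13.69, 15.65))
  expect_equal(bands$right_mbp, c(15.64, 17.6))
  # membership is a partition: no gene in two same-SDP bands
  expect_length(intersect(bands$genes[[1]], bands$genes[[2]]), 0)
  expect_setequal(bands$genes[[1]], paste0("a", 1:150))
  expect_setequal(bands$genes[[2]], paste0("b", 1:200))
})

test_that("co-located hotspots of different SDPs give separate bands", {
  g1 <- make_markers(c(1.03e6, 8e6), sdp = "14")
  g2 <- make_markers(c(0.83e6, 9e6), sdp = "JU1511")
  genos <- genotype_matrix(rbind(g1$alleles, g2$alleles) |>
                             `rownames<-`(sprintf("m%03d", 1:4)),
                           dplyr::bind_rows(g1$markers, g2$markers) |>
                             dplyr::mutate(marker = sprintf("m%03d", 1:4)))
  recs <- dplyr::bind_rows(
    trans_records(120, 1.03e6, sdp = "14", prefix = "a"),
    trans_records(110, 0.83e6, sdp = "JU1511", prefix = "b"))
  bands <- detect_trans_bands(recs, genos, min_count = 100, window = 1e6)
  expect_equal(nrow(bands), 2)
  expect_setequal(bands$sdp, c("14", "JU1511"))
})

test_that("bands respond monotonically to min_count and window", {
  set.seed(501)
  genos <- make_markers(seq(1e6, 14e6, by = 0.5e6))
  recs <- trans_records(400, sample(seq(1e6, 14e6, by = 1e5), 400, replace = TRUE))
  for (mc in c(20, 50, 100)) {
    lo <- detect_trans_bands(recs, genos, min_count = mc)
    hi <- detect_trans_bands(recs, genos, min_count = mc + 30)
    # every higher-threshold band lies inside some lower-threshold band
    if (nrow(hi)) {
      for (i in seq_len(nrow(hi))) {
        expect_true(any(lo$left_bp <= hi$peak_bp[i] &
                        lo$right_bp >= hi$peak_bp[i]))
      }
    }
    expect_gte(nrow(lo), nrow(hi))
  }
  # raising the window never decreases any marker count
  count_at <- function(w) {
    vapply(genos$markers$position,
           function(p) sum(abs(recs$position - p) <= w), numeric(1))
  }
  expect_true(all(count_at(1.5e6) >= count_at(1e6)))
})

test_that("band_borders reproduces clipping and midpoint arithmetic directly", {
  bb <- band_borders(c(14.69e6, 16.60e6), chrom_length = 17.7e6, window = 1e6)
  expect_equal(bb$right, c(15.64e6, 17.6e6))
  expect_equal(bb$left, c(13.69e6, 15.65e6))
  bb2 <- band_borders(0.83e6, chrom_length = 15.1e6, window = 1e6)
  expect_equal(bb2$left, 0)
})

test_that("hypergeometric enrichment matches brute-force pmf enumeration", {
  # N = 20 annotated background genes, term of size 5, test set of 6, k = 4
  background <- paste0("g", 1:20)
  go_map <- tibble::tibble(
    gene = c(paste0("g", 1:5), background),
    term = c(rep("GO:A", 5), rep("GO:B", 20)))
  test_genes <- paste0("g", c(1:4, 10, 11))
  res <- go_enrichment(test_genes, go_map, background, keep_all = TRUE)
  a <- res[res$term == "GO:A", ]
  expect_equal(a$k, 4)
  expect_equal(a$m, 5)
  expect_equal(a$n, 6)
  expect_equal(a$N, 20)
  expect_equal(a$p, hyper_oracle(4, 5, 6, 20), tolerance = 1e-12)
  expect_equal(a$p, stats::phyper(3, 5, 15, 6, lower.tail = FALSE),
               tolerance = 1e-15)
})

test_that("enrichment reporting rules are strict", {
  background <- paste0("g", 1:50)
  go_map <- tibble::tibble(
    gene = c(paste0("g", 1:3), paste0("g", 4:8), paste0("g", 20:25)),
    term = c(rep("GO:small", 3), rep("GO:hit", 5), rep("GO:miss", 6)))
  test_genes <- paste0("g", 1:8)
  res <- go_enrichment(test_genes, go_map, background, p_threshold = 0.05,
                       min_set = 3, keep_all = TRUE)
  # size-3 term is never reported no matter how significant
  expect_false(res$significant[res$term == "GO:small"])
  # disjoint term: k = 0 and p = 1, never reported
  miss <- res[res$term == "GO:miss", ]
  expect_equal(miss$k, 0)
  expect_equal(miss$p, 1)
  expect_false(miss$significant)
  reported <- go_enrichment(test_genes, go_map, background,
                            p_threshold = 0.05, min_set = 3)
  expect_identical(reported$term, "GO:hit")
  expect_error(go_enrichment("g1", go_map, character(0)), "background")
  expect_error(go_enrichment("zzz", go_map, background), "subset")
})
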