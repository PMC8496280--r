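test_that("simulation is seed-deterministic", {
  cfg <- sim_config(n_lines = 10, n_markers = 60, n_genes = 20, seed = 5)
  a <- simulate_cross(cfg)
  b <- simulate_cross(cfg)
  expect_identical(a$genos$alleles, b$genos$alleles)
  expect_identical(a$expr$values, b$expr$values)
  c <- simulate_cross(sim_config(n_lines = 10, n_markers = 60, n_genes = 20,
                                 seed = 6))
  expect_false(identical(a$genos$alleles, c$genos$alleles))
})

test_that("zero breakpoints make each line a pure founder per chromosome", {
  cfg <- sim_config(n_lines = 15, n_markers = 90, n_genes = 10,
                    breakpoint_mean = 0, seed = 11)
  g <- simulate_genomes(cfg)
  founders <- mp_founders()
  for (ch in mp_chromosomes()) {
    mi <- g$genos$markers$chromosome == ch
    for (l in sprintf("L%03d", 1:15)) {
      seg <- g$truth$mosaics[g$truth$mosaics$line == l &
                             g$truth$mosaics$chromosome == ch, ]
      expect_identical(nrow(seg), 1L)
      expect_equal(g$genos$alleles[mi, l],
                   g$genos$alleles[mi, seg$founder])
    }
  }
})

test_that("founder mosaics tile each chromosome exactly", {
  sim <- small_sim()
  lens <- sim$config$chromosomes
  tiles <- split(sim$truth$mosaics,
                 paste(sim$truth$mosaics$line, sim$truth$mosaics$chromosome))
  for (tile in tiles) {
    tile <- tile[order(tile$start), ]
    expect_equal(tile$start[1], 1)
    expect_equal(tile$end[nrow(tile)],
                 lens$length_bp[lens$chromosome == tile$chromosome[1]])
    if (nrow(tile) > 1) {
      expect_equal(tile$start[-1], tile$end[-nrow(tile)] + 1)
    }
    expect_true(all(tile$founder %in% mp_founders()))
  }
})

test_that("marker SDP labels agree with the founder allele table", {
  sim <- small_sim()
  founders <- mp_founders()
  for (i in seq_len(nrow(sim$genos$markers))) {
    carriers <- founders[sim$genos$alleles[i, founders] == 1]
    expect_identical(sdp_label(carriers), sim$genos$markers$sdp[i])
  }
})

test_that("allele frequencies match the carriers/4 binomial expectation", {
  cfg <- sim_config(n_lines = 2000,
                    chromosomes = tibble::tibble(chromosome = "I",
                                                 length_bp = 15.1e6),
                    n_markers = 40, n_genes = 5, seed = 19)
  g <- simulate_genomes(cfg)
  lines <- sprintf("L%03d", 1:2000)
  freq <- rowMeans(g$genos$alleles[, lines])
  p <- vapply(g$genos$markers$sdp,
              function(s) length(sdp_carriers(s)) / 4, numeric(1))
  se <- sqrt(p * (1 - p) / 2000)
  expect_true(all(abs(freq - p) <= 3 * se))
})

test_that("a noise-free cis effect separates genotype classes by exactly d", {
  d <- 1.5
  cfg <- sim_config(n_lines = 30, n_markers = 60, n_genes = 20,
                    noise_sd = 0, dev_covariate_sd = 0,
                    effects = cis_effect("III", 7e6, d, "14"), seed = 23)
  sim <- simulate_cross(cfg)
  eff <- sim$truth$effects
  target <- eff$targets[[1]]
  carriers <- intersect(eff$carrier_lines[[1]], sprintf("L%03d", 1:30))
  others <- setdiff(sprintf("L%03d", 1:30), carriers)
  l2 <- log2(sim$expr$values[target, ])
  expect_equal(unname(unique(l2[carriers]) - unique(l2[others])), d)
  # and every non-target gene is flat across lines
  flat <- log2(sim$expr$values[setdiff(rownames(sim$expr$values), target),
                               sprintf("L%03d", 1:30)])
  expect_true(all(apply(flat, 1, function(r) diff(range(r))) < 1e-12))
})

test_that("a noise-free trans-band effect moves exactly its target genes", {
  cfg <- sim_config(n_lines = 30, n_markers = 60, n_genes = 40,
                    noise_sd = 0, dev_covariate_sd = 0,
                    effects = trans_band_effect("I", 5e6, 1, "JU1931",
                                                n_targets = 15), seed = 29)
  sim <- simulate_cross(cfg)
  eff <- sim$truth$effects
  targets <- eff$targets[[1]]
  expect_length(targets, 15)
  lines <- sprintf("L%03d", 1:30)
  carriers <- intersect(eff$carrier_lines[[1]], lines)
  others <- setdiff(lines, carriers)
  l2 <- log2(sim$expr$values)
  moved <- vapply(rownames(l2), function(g) {
    abs(mean(l2[g, carriers]) - mean(l2[g, others])) > 1e-9
  }, logical(1))
  expect_setequal(rownames(l2)[moved], targets)
})

test_that("unknown effect targets and chromosomes are rejected", {
  cfg <- sim_config(n_lines = 10, n_markers = 60, n_genes = 10,
                    effects = cis_effect("I", 1e6, 1, "14", gene = "nope"),
                    seed = 3)
  g <- simulate_genomes(cfg)
  expect_error(simulate_expression(g$genos, g$truth, cfg), "unknown gene")
})

test_that("the truth ledger records true h2 consistent with its components", {
  sim <- small_sim()
  expect_true(all(sim$truth$genes$true_h2 >= 0 & sim$truth$genes$true_h2 <= 1))
  # with no planted effects, every true h2 is 0
  expect_true(all(sim$truth$genes$additive_var == 0))
  expect_true(all(sim$truth$genes$true_h2 == 0))
})

test_that("write_simulation emits the exchange formats for the full study", {
  sim <- small_sim()
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  expect_true(all(file.exists(file.path(d, c(
    "genotypes.tsv", "expression_fpkm.tsv", "samples.tsv",
    "annotation.tsv", "truth_genes.tsv")))))
  g <- read_genotypes(file.path(d, "genotypes.tsv"))
  expect_identical(g$alleles, sim$genos$alleles)
})
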