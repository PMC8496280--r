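#' Simulation configuration for a four-founder mpRIL cross
#'
#' Describes the synthetic study: a population of recombinant inbred
#' lines whose chromosomes are mosaics of four founder haplotypes, a set
#' of SDP-structured SNP markers, and an expression layer with planted
#' cis effects, trans-band regulators, a scalar developmental covariate,
#' and residual noise. Defaults emulate the real study's conditions: 200
#' mpRILs plus the 4 founders with 2 replicates each, ~9000 markers over
#' the six *C. elegans* chromosomes, and ~12,000 expressed genes.
#'
#' Planted effect sizes are in log2-expression units: with `noise_sd = 0`
#' and a single cis effect of size `d`, the two genotype classes differ
#' by exactly `d` on the log2 scale.
#'
#' @param n_lines Number of mpRILs (default 200).
#' @param chromosomes Tibble `chromosome`, `length_bp`; defaults
#'   approximate the *C. elegans* karyotype (I 15.1, II 15.3, III 13.8,
#'   IV 17.5, V 20.9, X 17.7 Mbp).
#' @param n_markers Total SNP markers, allocated proportionally to
#'   chromosome length (default 9000).
#' @param n_genes Number of genes (default 12000).
#' @param breakpoint_mean Poisson mean number of founder-switch
#'   breakpoints per chromosome per line (default 5, reflecting the
#'   crossovers accumulated over the generations of an advanced
#'   intercross; single-meiosis counts leave identical-genotype blocks
#'   far wider than the marker spacing).
#' @param sdp_weights Named sampling weights over the 7 SDP classes;
#'   the default mirrors the empirical imbalance of the mapped eQTLs
#'   (many JU1511-, JU1941- and SDP-14-linked markers, few JU1926).
#' @param effects Planted-effect plan: tibble from [cis_effect()] /
#'   [trans_band_effect()] rows (default none).
#' @param dev_covariate_sd SD of the per-line scalar developmental
#'   covariate on the log2 scale (0 disables; default 0.5).
#' @param noise_sd Residual SD on the log2 scale (default 0.5).
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline
#'   log2 expression.
#' @param low_expr_frac Fraction of genes drawn from a lowly expressed
#'   baseline (around log2 fpkm -7) so the expression filter has work to
#'   do (default 0.02).
#' @param seed Master seed; all sub-steps derive named sub-seeds from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 200,
                       chromosomes = default_chromosomes(),
                       n_markers = 9000,
                       n_genes = 12000,
                       breakpoint_mean = 5,
                       sdp_weights = default_sdp_weights(),
                       effects = NULL,
                       dev_covariate_sd = 0.5,
                       noise_sd = 0.5,
                       baseline_mean = 3,
                       baseline_sd = 2,
                       low_expr_frac = 0.02,
                       seed = 1L) {
  stopifnot(n_lines > 0, n_markers > 0, n_genes > 0, breakpoint_mean >= 0,
            dev_covariate_sd >= 0, noise_sd >= 0, low_expr_frac >= 0)
  chromosomes <- tibble::as_tibble(chromosomes)
  stopifnot(all(c("chromosome", "length_bp") %in% names(chromosomes)))
  sdp_weights <- sdp_weights[sdp_levels()]
  if (anyNA(sdp_weights)) abort("`sdp_weights` must name all 7 SDP classes")
  structure(list(n_lines = n_lines, chromosomes = chromosomes,
                 n_markers = n_markers, n_genes = n_genes,
                 breakpoint_mean = breakpoint_mean,
                 sdp_weights = sdp_weights / sum(sdp_weights),
                 effects = effects,
                 dev_covariate_sd = dev_covariate_sd, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 low_expr_frac = low_expr_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_chromosomes <- function() {
  tibble::tibble(chromosome = mp_chromosomes(),
                 length_bp = c(15.1, 15.3, 13.8, 17.5, 20.9, 17.7) * 1e6)
}

#' @rdname sim_config
#' @export
default_sdp_weights <- function() {
  c("12" = 0.07, "13" = 0.08, "14" = 0.22, JU1511 = 0.22,
    JU1926 = 0.05, JU1931 = 0.14, JU1941 = 0.22)
}

#' Planted-effect plan rows
#'
#' `cis_effect()` plants a local effect at a locus on the gene nearest to
#' it (or an explicitly named gene); `trans_band_effect()` plants a
#' regulator at a locus driving many distant target genes, creating a
#' trans-band. The allelic contrast follows the locus SDP: lines whose
#' founder at the locus carries the allele get `effect_size` added on the
#' log2 scale.
#'
#' @param chromosome,position Locus.
#' @param effect_size Additive shift on the log2 scale for carrier lines.
#' @param sdp SDP label of the planted variant.
#' @param gene Optional explicit target gene id (cis).
#' @param n_targets Number of distant target genes (trans band), drawn
#'   from other chromosomes at realization time; or supply
#'   `target_genes`.
#' @param target_genes Optional explicit target gene ids.
#' @export
cis_effect <- function(chromosome, position, effect_size, sdp, gene = NULL) {
  tibble::tibble(kind = "cis", chromosome = chromosome, position = position,
                 effect_size = effect_size, sdp = sdp,
                 n_targets = 1L, targets = list(gene))
}

#' @rdname cis_effect
#' @export
trans_band_effect <- function(chromosome, position, effect_size, sdp,
                              n_targets = 150L, target_genes = NULL) {
  if (!is.null(target_genes)) n_targets <- length(target_genes)
  if (n_targets < 1) abort("A trans-band effect needs at least one target gene")
  tibble::tibble(kind = "trans_band", chromosome = chromosome,
                 position = position, effect_size = effect_size, sdp = sdp,
                 n_targets = as.integer(n_targets), targets = list(target_genes))
}

# deterministic per-stage sub-seed below 2^31
stage_seed <- function(seed, stage) {
  offset <- c(genomes = 11L, annotation = 23L, effects = 37L,
              expression = 53L, polygenic = 71L)[[stage]]
  as.integer((as.numeric(seed) %% 1000003) * 1009 + offset)
}

#' Simulate founder mosaics and SDP-structured genotypes
#'
#' Each line's chromosome is a mosaic of founder haplotypes: the number
#' of breakpoints is Poisson, breakpoint positions uniform, and the
#' founder of each segment drawn uniformly from the four founders. Each
#' marker is assigned an SDP class (its founder carrier subset); a line's
#' genotype at a marker is 1 iff its founder at that position is a
#' carrier. The four founders are appended as pure-genotype lines.
#'
#' @param config A [sim_config()].
#' @return List with `genos` (a [genotype_matrix()] over mpRILs plus the
#'   4 founders) and `truth` (class `sim_truth`: founder mosaics, marker
#'   table, seed).
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "genomes"))
  chroms <- config$chromosomes
  founders <- mp_founders()
  n_chr <- nrow(chroms)

  n_per_chr <- round(config$n_markers * chroms$length_bp / sum(chroms$length_bp))
  n_per_chr[n_chr] <- config$n_markers - sum(n_per_chr[-n_chr])
  if (any(n_per_chr < 1)) {
    abort(paste0("Zero markers allocated to chromosome ",
                 chroms$chromosome[which(n_per_chr < 1)[1]]))
  }

  markers <- purrr::map2_dfr(chroms$chromosome, seq_len(n_chr), function(ch, i) {
    pos <- sort(ceiling(runif(n_per_chr[i], 0, chroms$length_bp[i])))
    pos <- pmax(pos, 1)
    tibble::tibble(chromosome = ch, position = pos)
  })
  markers$marker <- sprintf("m%05d", seq_len(nrow(markers)))
  markers$sdp <- sample(sdp_levels(), nrow(markers), replace = TRUE,
                        prob = config$sdp_weights)
  markers <- markers[, c("marker", "chromosome", "position", "sdp")]

  line_ids <- sprintf("L%03d", seq_len(config$n_lines))
  mosaics <- purrr::map_dfr(line_ids, function(l) {
    purrr::map2_dfr(chroms$chromosome, chroms$length_bp, function(ch, len) {
      nb <- rpois(1, config$breakpoint_mean)
      brk <- sort(ceiling(runif(nb, 1, len - 1)))
      brk <- unique(brk)
      starts <- c(1, brk + 1)
      ends <- c(brk, len)
      tibble::tibble(line = l, chromosome = ch, start = starts, end = ends,
                     founder = sample(founders, length(starts), replace = TRUE))
    })
  })

  carrier <- sdp_carrier_matrix()            # founder x sdp
  # founder allele row per marker: 4 x n_markers indicator
  founder_alleles <- carrier[, markers$sdp, drop = FALSE]

  alleles <- matrix(NA_real_, nrow(markers), config$n_lines + 4L,
                    dimnames = list(markers$marker, c(line_ids, founders)))
  for (ch in chroms$chromosome) {
    mi <- which(markers$chromosome == ch)
    mpos <- markers$position[mi]
    seg <- mosaics[mosaics$chromosome == ch, ]
    for (l in line_ids) {
      s <- seg[seg$line == l, ]
      idx <- findInterval(mpos, s$start)
      f <- s$founder[idx]
      alleles[mi, l] <- founder_alleles[cbind(match(f, founders), mi)]
    }
  }
  for (f in founders) alleles[, f] <- founder_alleles[match(f, founders), ]

  genos <- genotype_matrix(alleles, markers)
  truth <- structure(list(mosaics = mosaics, markers = genos$markers,
                          founder_alleles = founder_alleles,
                          seed = config$seed),
                     class = "sim_truth")
  list(genos = genos, truth = truth)
}

# founder identity of each line at a locus; founders are their own founder
founder_at <- function(truth, lines, chromosome, position) {
  founders <- mp_founders()
  vapply(lines, function(l) {
    if (l %in% founders) return(l)
    s <- truth$mosaics[truth$mosaics$line == l &
                       truth$mosaics$chromosome == chromosome, ]
    if (!nrow(s)) abort(paste0("No mosaic for line ", l, " on chromosome ", chromosome))
    s$founder[findInterval(position, s$start)]
  }, character(1))
}

#' Simulate a gene annotation for the synthetic genome
#'
#' Genes are placed uniformly over the chromosomes, in numbers
#' proportional to chromosome length.
#'
#' @param config A [sim_config()].
#' @return Tibble `gene`, `chromosome`, `start`.
#' @export
simulate_annotation <- function(config) {
  set.seed(stage_seed(config$seed, "annotation"))
  chroms <- config$chromosomes
  n_chr <- nrow(chroms)
  n_per_chr <- round(config$n_genes * chroms$length_bp / sum(chroms$length_bp))
  n_per_chr[n_chr] <- config$n_genes - sum(n_per_chr[-n_chr])
  ann <- purrr::map2_dfr(chroms$chromosome, seq_len(n_chr), function(ch, i) {
    tibble::tibble(chromosome = ch,
                   start = sort(pmax(1, ceiling(runif(n_per_chr[i], 0, chroms$length_bp[i])))))
  })
  ann$gene <- sprintf("g%05d", seq_len(nrow(ann)))
  ann[, c("gene", "chromosome", "start")]
}

# Resolve the effect plan against a concrete annotation: pick cis target
# genes (nearest gene on the locus chromosome) and draw trans targets
# from other chromosomes.
resolve_effects <- function(config, annotation) {
  effects <- config$effects
  if (is.null(effects) || !nrow(effects)) {
    return(tibble::tibble(kind = character(), chromosome = character(),
                          position = double(), effect_size = double(),
                          sdp = character(), targets = list()))
  }
  set.seed(stage_seed(config$seed, "effects"))
  effects$targets <- purrr::pmap(effects, function(kind, chromosome, position,
                                                   effect_size, sdp, n_targets,
                                                   targets, ...) {
    if (!is.null(targets)) {
      missing <- setdiff(targets, annotation$gene)
      if (length(missing)) {
        abort(paste0("Planted effect references unknown gene(s): ",
                     paste(missing, collapse = ", ")))
      }
      return(targets)
    }
    if (kind == "cis") {
      local <- annotation[annotation$chromosome == chromosome, ]
      if (!nrow(local)) abort(paste0("No genes on chromosome ", chromosome))
      local$gene[which.min(abs(local$start - position))]
    } else {
      distant <- annotation[annotation$chromosome != chromosome, ]
      sample(distant$gene, min(n_targets, nrow(distant)))
    }
  })
  if (!all(effects$chromosome %in% config$chromosomes$chromosome)) {
    abort("Planted effect references an unknown chromosome")
  }
  effects
}

#' Simulate expression with planted effects
#'
#' On the log2 scale, gene *g* in line *l* is
#' `baseline_g + sum(planted effects carried by l) + loading_g *
#' dev_l + N(0, noise_sd)`; fpkm is `2^log2`. Parental replicates share
#' the line's genetic and developmental terms and differ only by noise.
#' The truth ledger records each gene's realized additive variance over
#' the mpRILs and its true narrow-sense heritability
#' `va / (va + dev + noise)`.
#'
#' @param genos A [genotype_matrix()] from [simulate_genomes()].
#' @param truth The matching `sim_truth`.
#' @param config A [sim_config()].
#' @param annotation Gene annotation (default: [simulate_annotation()]).
#' @return List with `expr` (an [expression_matrix()], layer raw_fpkm),
#'   `annotation`, and the augmented `truth` (adds `genes` tibble and the
#'   realized `effects` table).
#' @export
simulate_expression <- function(genos, truth, config,
                                annotation = simulate_annotation(config)) {
  stopifnot(inherits(genos, "genotype_matrix"), inherits(truth, "sim_truth"))
  effects <- resolve_effects(config, annotation)
  set.seed(stage_seed(config$seed, "expression"))

  founders <- mp_founders()
  line_ids <- setdiff(genotype_lines(genos), founders)
  all_lines <- c(line_ids, founders)
  n_genes <- nrow(annotation)
  genes <- annotation$gene

  base <- rnorm(n_genes, config$baseline_mean, config$baseline_sd)
  low <- runif(n_genes) < config$low_expr_frac
  base[low] <- rnorm(sum(low), -7, 1)
  loading <- rnorm(n_genes)
  dev <- setNames(rnorm(length(all_lines), 0, config$dev_covariate_sd), all_lines)

  # genetic component per gene per line from the planted effects
  genetic <- matrix(0, n_genes, length(all_lines),
                    dimnames = list(genes, all_lines))
  if (nrow(effects)) {
    effects$carrier_lines <- vector("list", nrow(effects))
    for (i in seq_len(nrow(effects))) {
      e <- effects[i, ]
      f <- founder_at(truth, all_lines, e$chromosome, e$position)
      x <- as.numeric(f %in% sdp_carriers(e$sdp))
      tg <- e$targets[[1]]
      genetic[tg, ] <- genetic[tg, , drop = FALSE] +
        e$effect_size * matrix(x, length(tg), length(all_lines), byrow = TRUE)
      effects$carrier_lines[[i]] <- all_lines[x == 1]
    }
  }

  samples <- dplyr::bind_rows(
    tibble::tibble(sample = line_ids, role = "mpRIL", line = line_ids,
                   replicate = 1L),
    purrr::map_dfr(founders, function(f) {
      tibble::tibble(sample = paste0(f, "_", 1:2), role = "parent", line = f,
                     replicate = 1:2)
    }))

  sline <- samples$line
  log2v <- matrix(base, n_genes, nrow(samples)) +
    genetic[, sline, drop = FALSE] +
    outer(loading, dev[sline]) +
    matrix(rnorm(n_genes * nrow(samples), 0, config$noise_sd),
           n_genes, nrow(samples))
  dimnames(log2v) <- list(genes, samples$sample)
  expr <- expression_matrix(2^log2v, samples, layer = "raw_fpkm")

  va <- apply(genetic[, line_ids, drop = FALSE], 1, var)
  vd <- loading^2 * var(dev[line_ids])
  tot <- va + vd + config$noise_sd^2
  true_h2 <- ifelse(tot > 0, va / tot, 0)

  truth$genes <- tibble::tibble(gene = genes, baseline = base,
                                loading = loading, additive_var = va,
                                true_h2 = true_h2)
  truth$effects <- effects
  truth$annotation <- annotation
  list(expr = expr, annotation = annotation, truth = truth)
}

#' Simulate a complete mpRIL study
#'
#' Convenience wrapper chaining [simulate_genomes()],
#' [simulate_annotation()] and [simulate_expression()].
#'
#' @param config A [sim_config()].
#' @return List of class `mp_sim` with `genos`, `expr`, `annotation`,
#'   `truth`, `config`.
#' @export
simulate_cross <- function(config) {
  g <- simulate_genomes(config)
  e <- simulate_expression(g$genos, g$truth, config)
  structure(list(genos = g$genos, expr = e$expr, annotation = e$annotation,
                 truth = e$truth, config = config),
            class = "mp_sim")
}

#' Simulate polygenic phenotypes with a target heritability
#'
#' Draws phenotypes `y = sqrt(h2) * g + sqrt(1 - h2) * e` with
#' `g ~ N(0, K)` and `e ~ N(0, I)`, the standard construction for
#' heritability parameter-recovery runs.
#'
#' @param K Kinship matrix (positive semidefinite, unit diagonal).
#' @param h2 True narrow-sense heritability in `[0, 1]`.
#' @param n_genes Number of phenotype vectors to draw.
#' @param seed Seed.
#' @return Matrix `n_genes x n_lines`.
#' @export
simulate_polygenic <- function(K, h2, n_genes, seed = 1L) {
  stopifnot(h2 >= 0, h2 <= 1)
  set.seed(stage_seed(seed, "polygenic"))
  n <- nrow(K)
  e <- eigen(K, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  g <- matrix(rnorm(n_genes * n), n_genes, n) %*% t(L)
  eps <- matrix(rnorm(n_genes * n), n_genes, n)
  y <- sqrt(h2) * g + sqrt(1 - h2) * eps
  colnames(y) <- colnames(K)
  rownames(y) <- sprintf("g%05d", seq_len(n_genes))
  y
}

#' Write a simulated study to a directory
#'
#' Writes the genotype, expression, sample, annotation and truth tables
#' in the package's tab-delimited exchange formats.
#'
#' @param sim An `mp_sim` from [simulate_cross()].
#' @param dir Output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "mp_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes(sim$genos, file.path(dir, "genotypes.tsv"))
  write_expression(sim$expr, file.path(dir, "expression_fpkm.tsv"))
  write_samples(sim$expr$samples, file.path(dir, "samples.tsv"))
  write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  readr::write_tsv(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  if (nrow(sim$truth$effects)) {
    eff <- sim$truth$effects
    eff$targets <- vapply(eff$targets, paste, character(1), collapse = ",")
    eff$carrier_lines <- vapply(eff$carrier_lines, paste, character(1), collapse = ",")
    readr::write_tsv(eff, file.path(dir, "truth_effects.tsv"))
  }
  invisible(dir)
}
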