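---
title: "Expression genetics in a four-founder mpRIL population: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression genetics in a four-founder mpRIL population: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpeqtl)
```

`mpeqtl` implements the expression-genetics analysis of a multiparental
recombinant inbred line (mpRIL) population: 200 *C. elegans* lines
descended from an advanced intercross of four wild isolates (JU1511,
JU1926, JU1931, JU1941), with RNA-seq expression for every line (one
replicate) and every founder (two replicates), and ~9000 SNP markers
called from the same reads. This vignette describes the statistical
models, the tunable parameters and their defaults, the synthetic-data
generator used for testing, and the numerical and design choices made
where the procedures left room.

## Data model

Expression enters as a gene-by-sample fpkm table. Genotypes are binary
marker-by-line calls (1 = non-reference allele present), each marker
annotated with chromosome, base-pair position, and an *SNP distribution
pattern* (SDP): the partition of the four founders into carriers and
non-carriers. A carrier subset and its complement describe the same
biallelic contrast, so the 14 proper subsets collapse to 7 informative
classes; `mpeqtl` canonicalizes to the two-founder label containing
JU1511 (`"12"`, `"13"`, `"14"`) or the singleton founder name.

## Normalization and filtering

Genes are first filtered to the consistently detected set: mean log2
fpkm strictly above −5 across all samples (`filter_expressed_genes()`,
threshold configurable). The surviving genes are then depth-normalized
per sample to fpkm-per-million (`normalize_expression()`), and all
downstream work uses log2 values and the per-gene log2 ratio with the
gene's mean (`log2_and_ratio()`). This order — filter on raw log2 fpkm,
normalize the survivors — is fixed in `prepare_expression()` because
the per-million rescaling is defined over the retained transcripts.

The raw data contain no stated rule for zero fpkm under the log
transform; `mpeqtl` replaces exact zeros with a configurable
pseudocount (default $2^{-10}$) and leaves non-zero values untouched.
The filtered gene set rarely contains zeros, so the choice is
inconsequential in practice, but it is exposed in the configuration
rather than hidden.

## Parental contrasts and transgression

Differential expression among the four founders uses a one-way ANOVA
per gene over the eight parental samples, with Tukey–Kramer
studentized-range p-values for the six founder pairs
(`tukey_pairwise()`, significance at adjusted *p* < 0.001). A gene is a
DEG when any pair is significant; an UpSet-style intersection table
summarises sharing across pairs. The false-positive rate is estimated
by permuting the founder labels over the eight parental samples and
dividing the mean permuted DEG count by the observed count
(`deg_fpr()`). Inside the permutation loop significance is decided by
comparing the range statistic with a single `qtukey` critical value —
algebraically identical to thresholding the p-value, and orders of
magnitude faster than evaluating `ptukey` per gene.

Transgression asks how many mpRILs express a gene beyond the extreme
founders. The envelope is the highest (lowest) founder line *mean*
plus (minus) 2 pooled within-line standard deviations; the pooled SD is
computed from the replicate deviations with 4 degrees of freedom
(8 parental samples − 4 line means). Line means rather than individual
replicates define the extremes because with two replicates a single
noisy sample would otherwise inflate the envelope asymmetrically; a
per-line-SD alternative is available through `k_sd` and the worker
arguments. Counting is strict (`>` the bound), and a gene is called
transgressive when strictly more than 50 mpRILs (a quarter of the
population) lie outside. The FPR again comes from permutations, here
relabelling eight randomly chosen samples as the 4 × 2 parental
structure (`transgression_fpr()`).

## Kinship and narrow-sense heritability

The kinship matrix is allele-sharing: $K_{ij}$ is the proportion of
markers (pairwise-complete under missingness) at which lines $i$ and
$j$ carry the same allele. Numerically negative eigenvalues are clipped
at zero so $K$ is a valid covariance structure.

Per-gene narrow-sense heritability fits the mixed model
$y = \mu + g + e$, $g \sim N(0, \sigma_g^2 K)$,
$e \sim N(0, \sigma_e^2 I)$ by restricted maximum likelihood. Working
in the contrast space orthogonal to the intercept, one eigendecomposition
of the centered kinship (`kinship_eigen()`) is shared across all genes
and permutations; each fit then reduces to a one-dimensional profile
likelihood in $\lambda = \sigma_g^2/\sigma_e^2$, maximized on a 41-point
log grid over $[10^{-5}, 10^5]$ and refined by bounded scalar
optimization. $h^2 = \lambda/(1+\lambda)$. The search range covers
$h^2 \in (10^{-5}, 1-10^{-5})$; a constant phenotype returns $h^2 = 0$
with a warning.

Significance is per gene: the phenotype is permuted across lines 100
times, and the threshold is the 5th largest permuted $h^2$ — the 95th
percentile, matching a 0.05 per-gene false-discovery level. The
alternative literal reading of "95th highest of 100" (a 5th-percentile
threshold) would flag almost everything and is rejected. On null data
the flag rate calibrates to ≈ 5/101, which the acceptance suite checks
against a binomial 99% band at 400 genes.

## eQTL mapping

Each gene's log2 ratio is regressed on each marker separately
(`scan_eqtl()`): ordinary least squares with an $F(1, n-2)$ test,
vectorized across markers and genes. Markers with fewer than 5 lines
in either genotype class (including monomorphic markers) are assigned
$-\log_{10}(p) = 0$; this `min_class` guard is configurable. The
per-gene peak is the most significant marker — one eQTL per gene —
with ties broken by chromosome order (I < II < III < IV < V < X) then
lowest position.

The significance threshold comes from one round of permutations: every
gene's phenotype is independently shuffled across lines, the scan is
repeated, and for candidate thresholds $T$ on a 0.05-step grid the
ratio FP(T)/TP(T) is formed from the permuted and observed peak counts.
The reported threshold is the smallest grid value with FP/TP < 0.01.
Two numerical choices matter here. First, the ratio is only considered
attainable where TP ≥ 1/ratio (100 at the default): with fewer
positives, FP = 0 satisfies any target vacuously, and on null data a
single lucky observed peak above the permuted maximum would
manufacture a threshold. Second, one permutation round is noisy;
`n_rounds` allows averaging FP over several rounds. On planted-effect
data at the study's scale the procedure lands near $-\log_{10}(p)
\approx 5.5{-}6$, the same regime as the published operating point
(5.35), though the exact value depends on the realized data.

A significant eQTL is *cis* when its peak lies on the gene's chromosome
within 1 Mbp of the gene start (inclusive), *trans* otherwise. The
same-chromosome requirement is implied by the distance rule and made
explicit. Counts are tabulated over the full 7 SDP × 6 chromosome ×
{cis, trans} grid (`tabulate_sdp()`); re-aggregating the published
count table through this function reproduces its marginal totals
exactly, which the acceptance suite asserts.

## Trans-bands

Hotspots are detected per SDP (`detect_trans_bands()`): for every
marker of that SDP, the trans-eQTL peaks of the same SDP within 1 Mbp
on the same chromosome are counted; markers with strictly more than
100 are candidates; runs of candidates within one window of each other
merge into one band whose peak is the max-count marker (ties → lowest
position). SDP stratification is forced by the published band table,
which lists two co-located chromosome-I bands under different SDPs —
only producible if counting is stratified.

Borders are peak ± window clipped at the chromosome ends. When two
same-SDP bands on one chromosome would overlap, the shared boundary is
the midpoint between their peaks snapped to the 0.01-Mbp reporting
grid: the lower band's right border is the midpoint floored to 10 kb,
the upper band's left border the next grid position. This rule
reproduces the published overlapping-band borders (15.64 / 15.65 Mbp
from peaks at 14.69 and 16.60) exactly. Candidate runs split when
consecutive candidate markers are more than one window apart, so two
hotspots 1–2 Mbp apart remain distinct bands and the midpoint rule can
engage.

Per-band GO enrichment (`go_enrichment()`) is an upper-tail
hypergeometric test with the expression-filtered gene set as
background. The annotated universe is the intersection of the
background with the genes present in the GO map; unannotated genes are
excluded from both the population size and the draw count, keeping
$k \le \min(m, n)$ coherent. Terms are reported at *p* < 10⁻⁵ with
background term size strictly greater than 3.

## Cross-study comparison

External eQTL experiments enter as gene × marker significance profiles
with their own marker maps and annotation. Peaks are called above
$-\log_{10}(p) = 3.5$ (strict), typed by the same 1-Mbp rule, and
compared by gene identity only: the overlap percentage divides the
shared genes of a type by the *other* study's count, so the measure is
directional and both directions are reported. Positional concordance
of peaks is deliberately out of scope.

## The synthetic-data generator

`simulate_cross()` generates the study conditions: 200 mpRILs plus the
four founders (two replicates each), ~9000 SDP-structured markers and
~12,000 genes by default, on chromosome lengths approximating the
*C. elegans* karyotype. Each line's chromosome is a mosaic of founder
haplotypes with a Poisson number of breakpoints at uniform positions;
a marker's genotype is 1 when the line's founder at that position
carries the allele, so marker SDPs, founder genotypes and line
genotypes are mutually consistent by construction. SDP class weights
default to the asymmetry seen in the mapped eQTLs (many JU1511-,
JU1941- and 14-linked markers, few JU1926) and are configurable.

The breakpoint mean defaults to 5 per chromosome per line. A
single-meiosis value (~1–1.5 crossovers per chromosome) would be
appropriate for an F2, but these lines went through repeated
intercrossing and selfing, which accumulates crossovers; more
importantly, at ~1.5 the 200-line population carries identical-genotype
marker blocks spanning hundreds of kilobases at 9000-marker density, so
peak positions degenerate to tie-breaking and no mapping-resolution
property can be exercised. Five breakpoints restore block sizes
commensurate with the marker spacing. The simulator makes no attempt at
pedigree realism (no funnel structure, no interference, no segregation
distortion); it targets the statistical structure the mapping methods
consume.

Expression is built on the log2 scale: per-gene baseline
($N(3, 2^2)$, with a 2% lowly expressed fraction around −7 to give the
filter work), planted cis and trans-band effects added to carrier
lines, an optional per-line scalar developmental covariate with
per-gene loadings (mimicking the dominant principal component of real
populations, default SD 0.5), and $N(0, 0.5^2)$ residual noise; fpkm is
$2^{\text{log2}}$. Effect sizes are absolute log2 shifts. The truth
ledger records mosaics, realized effects with their carrier lines, and
per-gene true $h^2$ as realized additive variance over additive +
covariate + noise variance. `simulate_polygenic()` draws phenotypes
with an exact target heritability directly from a kinship matrix for
parameter-recovery runs.

What passing tests on this generator do *not* show: robustness to
alignment and quantification artifacts, count overdispersion, batch
structure, segregation distortion, or reference-genome bias from
divergent wild-isolate regions — none of which the generator emulates.

## Problem sizes and runtimes

The test and acceptance runs use deliberately scaled studies chosen as
the smallest sizes at which each property is informative: the
null-calibration run uses 200 lines × 1000 markers × 400 genes with
100 permutations per gene; the planted-effect recovery run uses 200
lines at the study's full 9000-marker density with a 1000-gene
transcriptome, 40 cis effects each explaining 25% of variance
($\beta = \sqrt{1/3}$ on an SDP-14 background at residual SD 0.5) and
one major trans regulator (1.0 log2 units, 150 targets); transgression
calibration uses 200 lines × 300 genes. Unit tests use smaller
fixtures. The whole suite runs on one CPU in a few minutes; the
acceptance script in under a minute.

## Known limitations

- Single-marker, biallelic, additive model only: no founder-haplotype
  probabilities, no multi-QTL or epistasis models, matching the
  original analysis' deliberate scope.
- One eQTL per gene; secondary peaks are not called.
- The permutation FP/TP threshold from one round is noisy; prefer
  `n_rounds > 1` when runtime allows.
- GO associations are used as given, with no ontology-graph
  propagation.
- The heritability model has no replicate structure within mpRILs, so
  broad-sense heritability is not estimable and is not offered.
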