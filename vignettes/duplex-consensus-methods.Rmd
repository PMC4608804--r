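---
title: "Duplex-barcode consensus calling for cfDNA: models and methods"
author: "cfduplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplex-barcode consensus calling for cfDNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfduplex)
library(data.table)
```

## The problem

Circulating cell-free DNA (cfDNA) is a mixture of short (~166 bp)
double-stranded fragments, mostly leukocyte-derived, in which
tumor-derived fragments (ctDNA) may be present at mutant allele
fractions (MAF) of 0.1–1% — one or two mutant molecules among a
thousand wild-type molecules overlapping the same base. At those
concentrations an ordinary sequencing workflow cannot distinguish
signal from its own error floor: a per-base error rate of 10^-3 on a
78,000-bp targeted panel produces hundreds of spurious non-reference
positions in exactly the MAF range where somatic variants live, so a
wide panel is unusable without a specificity in the region of one error
per million sequenced bases.

`cfduplex` implements the digital strategy that makes wide panels
workable at low MAF, together with a synthetic-data generator that
reproduces the statistical structure the strategy relies on, so every
stage can be validated in silico:

1. **Digitization.** Each strand of every input duplex molecule carries
   a non-unique 7-mer barcode; molecule identity is the composite key
   (barcode pair, fragment start, fragment end). Reads are grouped into
   strand families on that key, each family is collapsed to a
   supermajority consensus, and the two strand consensi of each
   molecule are compared base by base. PCR duplicates collapse into
   their family; errors arising on a single strand (sequencing error,
   PCR jackpot error, DNA damage) fail duplex comparison and are
   discarded.
2. **Per-base noise modelling.** The duplex-confirmed minor-base
   fraction of every (panel position, alternate base) pair, observed
   across a cohort of germline-only normal samples, gives each targeted
   base its own background distribution; a call must rise above its own
   site's baseline, not a global threshold.
3. **SNV calling and quantification.** MAF is a molecule count ratio:
   mutant unique molecules over total unique molecules at the position.
   Germline variants are recognized by their fraction (≈50% or ≈100%)
   or by annotation; quantification uncertainty is reported per MAF
   stratum.
4. **Copy-number calling.** Absolute plasma copy number per gene comes
   from unique-fragment counts: normalize for capture/GC bias, scale so
   the modal gene equals two copies, and z-score against a normal
   cohort; `z > 2.5758` (the 99.5% normal quantile) with plasma CN ≥
   2.2 is reported as amplified. Because plasma is a
   (1−f)·germline + f·tumor mixture, a tumor at copy number 10 with 5%
   tumor-derived cfDNA appears at only 2.4 plasma copies — sub-copy
   resolution is the entire game.

## The simulator: what it emulates, and what it does not

`sim_params()` fixes the study conditions; defaults are the assay-scale
conditions the method targets.

| parameter | default | units | rationale |
|---|---|---|---|
| `molecules_per_position` | 3000 | unique molecules / base | ~10 ng input (3.3 pg per haploid copy) |
| `fragment_mean`, `fragment_sd` | 166, 10 | bp | apoptotic cfDNA mono-nucleosome peak |
| `conversion_efficiency` | 0.8 | fraction | ligation-based duplex conversion >80% |
| `strand_dropout` | 0 | fraction | both strands of a converted molecule recovered; raise to exercise single-strand molecules |
| `pcr_dup_mean` | 2 | reads / strand | family size 1 + Poisson(mean − 1); the paper's family-size law is undisclosed, this is a knob not a claim |
| `per_base_error_rate` | 1e-3 | / base | typical Q30-scale platform error; reproduces a realistic naive-calling noise floor |
| `pcr_lineage_rate` | 1e-3 | / strand family | explicit jackpot errors shared by a read subset of one strand, so duplex comparison has real single-strand-consistent artifacts to reject |
| `lowq_frac` | 0.002 | fraction of bases | sub-Q20 tail after base calling |
| `gdna_ratio` | 0 | mass ratio | long (>500 bp) genomic-DNA contamination carrying germline alleles only |

Molecules are placed uniformly over each region's overlap window, so a
somatic variant at true MAF *m* is carried by Binomial(n, m) of the n
overlapping molecules, heterozygous germline alleles split
Binomial(n, 0.5), and an amplified gene draws molecules in proportion
to its plasma copy number. Reads are represented sparsely — one row per
read plus a table of deviations from the panel reference — which is
what lets the full pipeline run at 3,000 molecules per position in
plain R; FASTQ and aligned-TSV materializations exist at the I/O
boundary (`write_reads_fastq()`, `write_reads_tsv()`).

The generator does **not** model capture/GC bias beyond a per-region
efficiency multiplier, trinucleotide damage signatures (e.g. oxo-G),
indels, fusions, paired-end read structure, or alignment artifacts.
Passing tests therefore demonstrate the statistical machinery — error
suppression, baselines, quantification, copy-number inference — under
the method's own assumptions, not robustness to every failure mode of
real libraries. Alignment and trimming are explicitly upstream of this
package: the simulator emits aligned coordinates.

## Numerical and design choices

- **Coordinates** are 0-based half-open everywhere internally; 1-based
  only in VCF output. MAFs are fractions in [0, 1] internally, percent
  in reports.
- **Supermajority q = 0.75.** No published voting rule exists for this
  assay; q = 0.75 is chosen so a single errored read can never flip a
  family of two or more (⌈0.75·n⌉ > n/2), while singleton families pass
  through (flagged low-confidence) and are still subject to duplex
  comparison. Masked (sub-Q20) members keep their place in the family
  denominator, so a half-masked family cannot fake unanimity.
- **Molecule identity** is (barcode pair, start, end): barcodes are
  deliberately non-unique (4^7 = 16,384), so collisions merge molecules;
  `barcode_collision_rate()` measures the loss (≲1% at test scale).
  Barcode matching is exact — no edit-distance clustering.
- **Noise threshold mean + k·sd, k = 10.** The thresholding statistic
  is not published; k = 10 with duplex confirmation is calibrated
  in-package to yield ~0 false positives per 1.56 Mb on simulated
  normals. The absolute support floor — two unique molecules, at least
  one duplex-confirmed — is carried by `min_support` in the caller;
  `threshold_for()` reports the combined site threshold
  max(mean + k·sd, 2/depth). Relaxing `min_support` to 1 deliberately
  enables single-molecule detection (0.06% MAF at 1,667 molecules).
- **Uncertainty bins** follow the worked examples for boundary
  membership: a 10% MAF gets the 4% relative bin (±0.4 points), a 1%
  MAF the 20% bin (±0.2 points); below the 0.25% reporting floor the
  bin is undefined and calls are flagged extrapolated (and
  `below_lod`), not suppressed.
- **Germline windows** [0.35, 0.65] and ≥0.85 are wide by design and
  overridable by a known-germline/known-somatic annotation table (the
  stand-in for database lookups).
- **CNV normalization** divides fragment density by the per-region
  capture-efficiency proxy and removes residual GC trend with a robust
  loess (`family = "symmetric"`, degree 1), so an amplified outlier does
  not drag the fit. The diploid baseline is the kernel-density mode
  (Silverman bandwidth) of the normalized values; ties break to the
  lower mode because amplification inflates and rarely deflates, and a
  majority of genes sitting far above the mode triggers a warning
  (diploid-majority assumption violated). z-scores are computed on
  normalized fragment values against the normal set, not on copy
  numbers; a reported amplification requires both z > 2.5758 and plasma
  CN ≥ 2.2.
- **Degenerate inputs**: zero-depth sites are uncalled and logged;
  degenerate covariates collapse normalization to the identity;
  contingency metrics with empty denominators report NA; the
  copy-number mixture inverse refuses f = 0.

## Validation harness and study sizes

All validation experiments run the full simulate → digitize → noise →
call pipeline; the sizes below are the package's chosen study sizes.

- **SNV limit of detection** (`run_dilution_series`): 29 SNVs × 3
  replicates per level over {1, 0.5, 0.3, 0.25, 0.1}% MAF at 3,000
  molecules/position and conversion 0.8. With detection requiring ≥2
  supporting unique molecules, the expected converted mutant count at
  0.1% is 2.4, giving P(detect) ≈ 0.69 < 0.80, while 0.25% gives ≈ 0.98
  — the >80% rule lands at 0.25% MAF. `scripts/acceptance.R` pools the
  detection curve over five independent series before applying the
  rule; the test suite pools two.
- **Spike-in accuracy** (`run_specificity_study`): 20 host samples on
  the full 54-gene, 78-kbp panel (1.56 Mb cumulative), each spiked with
  one donor's germline SNP set at 5% of molecules (so het SNPs appear
  near 2.5% MAF), run at 800 molecules/position with PCR duplicate mean
  1 — a problem size that leaves the 100%-sensitivity margin essentially
  unchanged (≈16 expected mutant molecules per spiked het SNP) while
  keeping the cohort tractable.
- **Split-sample robustness** (`run_split_sample_study`): 24 SNVs with
  true MAFs log-spaced over 0.1–30%, two independent aliquots at 3,000
  molecules/position; binomial counting noise is small against the MAF
  spread, so paired-MAF R² rounds to 1.0 and concordance is 100% above
  0.3% MAF.
- **CNV pools**: plasma copy numbers {2.1, 2.2, 2.6, 3, 4} on a
  24-gene panel, in duplicate at three input levels {1500, 3000, 4500}
  molecules/position; duplicate-mean recovery is within ±0.1 copies.
  The per-gene detection limit is z_threshold × sd_cn extra plasma
  copies (`cnv_lod_surface`), ≈0.2 extra copies for a gene whose
  counting noise is 0.07 copies.
- **Properties held throughout**: unique-molecule counts are invariant
  to the PCR duplicate factor; single-strand-consistent errors are
  never duplex-confirmed; simulated healthy normals produce zero
  somatic calls and zero reported amplifications; on instances of ≤50
  reads the sparse consensus caller is identical to an exhaustive
  brute-force reconstruction.

## Known limitations

- The synthetic panel matches the footprint (54 genes, ~78 kbp, 18
  complete-exon genes) but not the real exon list of any commercial
  assay; sequences are random with per-gene GC in [0.35, 0.65].
- Whether single-strand-only molecules may support calls is exposed as
  a switch (`count_single_strand`, plus `require_duplex`); the default
  requires duplex confirmation for somatic support.
- Strand-bias filtering beyond the duplex-discordance veto is not
  implemented (it is named but unspecified in the source method); the
  strand-half imbalance statistic is computed as a QC covariate only.
- No deletions, no segmentation: copy-number calling is gene-level
  focal amplification for a configurable reportable-gene set
  (default EGFR, ERBB2, MET).

## A worked desk-scale run

```{r example, eval = FALSE}
set.seed(7)
panel <- synthetic_panel(n_genes = 6, total_bp = 1200)
par <- sim_params(molecules_per_position = 1000)

# normal cohort -> per-base noise baseline
normals <- make_validation_cohort(panel, par, n_normal = 4,
                                  snps_mean = 3, snps_range = c(1L, 5L))
piles <- lapply(normals, function(s)
  pileup(consensus_molecules(s, panel), panel))
baseline <- train_baseline(piles, panel)

# case sample: one somatic variant at 0.5% MAF
pp <- panel_positions(panel)
site <- pp[600]
alt <- setdiff(c("A", "C", "G", "T"), site$ref)[1]
v <- truth_variants(site$chrom, site$pos, site$ref, alt, "somatic", 0.005)
rs <- simulate_sample(panel, v, NULL, par, "case")
calls <- call_snvs(pileup(consensus_molecules(rs, panel), panel), baseline)
calls[, .(chrom, pos, alt, mutant_molecules, total_molecules,
          maf, classification)]
```
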