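#' Classify a call as somatic or germline by allele fraction
#'
#' In cfDNA with low circulating tumor fraction, germline variants sit
#' near 50% (heterozygous) or 100% (homozygous) MAF while somatic
#' variants sit far lower, so fraction windows separate the classes: het
#' if MAF in `het_window`, hom if MAF >= `hom_min`, somatic otherwise.
#' An annotation (a stand-in for known-germline / known-somatic database
#' lookups) overrides the fraction rule.
#'
#' @param maf mutant allele fraction(s) in [0, 1]
#' @param annotation optional character vector: `known_germline`,
#'   `known_somatic` or `none`/NA
#' @param het_window heterozygous window (default [0.35, 0.65])
#' @param hom_min homozygous minimum (default 0.85)
#' @return character vector: `somatic`, `germline_het`, `germline_hom`
#' @export
classify_germline <- function(maf, annotation = NULL,
                              het_window = c(0.35, 0.65), hom_min = 0.85) {
  cls <- ifelse(maf >= hom_min, "germline_hom",
         ifelse(maf >= het_window[1] & maf <= het_window[2],
                "germline_het", "somatic"))
  if (!is.null(annotation)) {
    ann <- as.character(annotation)
    cls[!is.na(ann) & ann == "known_somatic"] <- "somatic"
    known_g <- !is.na(ann) & ann == "known_germline"
    cls[known_g] <- ifelse(maf[known_g] >= hom_min,
                           "germline_hom", "germline_het")
  }
  cls
}

#' MAF quantification uncertainty bin
#'
#' Relative quantification uncertainty by MAF stratum on the percent
#' scale: \[10, 100\] -> 4%, (3, 10) -> 6%, (1, 3\] -> 14%,
#' (0.5, 1\] -> 20%, \[0.25, 0.5\] -> 30% (boundary membership follows
#' the worked examples: 10% gets 4%, 1% gets 20%).  The absolute
#' error is `relative x MAF` in percentage points (a 10% MAF call is
#' +/- 0.4 points; a 1% call +/- 0.2 points).  Below the 0.25% reporting
#' floor the bin is undefined and the call is flagged extrapolated.
#'
#' @param maf mutant allele fraction(s) in [0, 1]
#' @return data.table with `rel` (relative uncertainty, fraction), `abs`
#'   (absolute error, MAF percentage points) and `extrapolated`
#' @export
uncertainty_bin <- function(maf) {
  pct <- maf * 100
  # boundary conventions follow the worked text examples: 10% belongs to
  # the 4% bin, 1% to the 20% bin
  rel <- fifelse(pct >= 10, 0.04,
         fifelse(pct > 3, 0.06,
         fifelse(pct > 1, 0.14,
         fifelse(pct > 0.5, 0.20,
         fifelse(pct >= 0.25, 0.30, NA_real_)))))
  # the floor bin is closed at 0.25 (the validated reporting floor)
  data.table(rel = rel, abs = rel * pct, extrapolated = is.na(rel))
}

#' Call SNVs from a pileup against a trained noise baseline
#'
#' A site/alternate pair is called iff (a) it is supported by at least
#' `min_support` mutant unique molecules, with at least one
#' duplex-confirmed when `require_duplex` is set, and (b) its mutant
#' fraction strictly exceeds the site's trained noise component
#' `mean + k*sd`.  The reported per-call `threshold` is the full
#' site-specific detection threshold
#' `max(mean + k*sd, floor_molecules/depth)`.  MAF = mutant unique
#' molecules / total unique molecules at the position.  Calls below the
#' `maf_floor` reporting floor are retained with `below_lod = TRUE`.
#'
#' @param pile a `pileup_set` (single sample or batched; calls are per
#'   sample)
#' @param baseline a `noise_baseline` trained on the same panel
#' @param min_support minimum mutant unique molecules (default 2)
#' @param require_duplex require >= 1 duplex-confirmed mutant molecule?
#' @param count_single_strand count single-strand-only molecules as
#'   support (default TRUE; duplex requirement still applies)
#' @param annotation optional data.table (`chrom`, `pos`, `alt`,
#'   `annotation`) of known-germline / known-somatic sites
#' @param het_window,hom_min germline classification windows
#' @param maf_floor reporting floor as a fraction (default 0.0025)
#' @return data.table of SNV calls
#' @export
call_snvs <- function(pile, baseline, min_support = 2L,
                      require_duplex = TRUE, count_single_strand = TRUE,
                      annotation = NULL,
                      het_window = c(0.35, 0.65), hom_min = 0.85,
                      maf_floor = 0.0025) {
  a <- copy(pile$alts)
  empty <- data.table(
    sample_id = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), mutant_molecules = integer(0),
    duplex_mutant = integer(0), total_molecules = integer(0),
    maf = numeric(0), threshold = numeric(0), classification = character(0),
    uncertainty_rel = numeric(0), uncertainty_abs = numeric(0),
    below_lod = logical(0))
  if (nrow(a) == 0L) return(empty)
  a <- a[depth > 0]
  if (nrow(a) == 0L) return(empty)
  a[, mutant_molecules := if (count_single_strand) n_duplex + n_single
                          else n_duplex]
  a[, maf := mutant_molecules / depth]
  a[, threshold := threshold_for(baseline, chrom, pos, alt, depth)]
  # the molecule-support requirement acts in molecule units (>=
  # min_support); the trained noise component acts on the fraction
  # (strictly above).  The baseline's absolute floor is what min_support
  # = 2 encodes; relaxing min_support deliberately relaxes it.
  thr_rel <- threshold_for(baseline, a$chrom, a$pos, a$alt)
  keep <- a$mutant_molecules >= min_support & a$maf > thr_rel
  if (require_duplex) keep <- keep & a$n_duplex >= 1L
  calls <- a[keep]
  if (nrow(calls) == 0L) return(empty)
  ann <- NULL
  if (!is.null(annotation)) {
    annotation <- as.data.table(annotation)
    ann <- annotation[calls, on = c("chrom", "pos", "alt"),
                      x.annotation]
  }
  calls[, classification := classify_germline(maf, ann, het_window, hom_min)]
  ub <- uncertainty_bin(calls$maf)
  calls[, `:=`(uncertainty_rel = ub$rel, uncertainty_abs = ub$abs)]
  calls[, below_lod := maf < maf_floor]
  setnames(calls, "n_duplex", "duplex_mutant")
  calls[, `:=`(n_single = NULL)]
  setnames(calls, "depth", "total_molecules")
  setcolorder(calls, c("sample_id", "chrom", "pos", "ref", "alt",
                       "mutant_molecules", "duplex_mutant",
                       "total_molecules", "maf", "threshold",
                       "classification", "uncertainty_rel",
                       "uncertainty_abs", "below_lod"))
  setorderv(calls, c("sample_id", "chrom", "pos", "alt"))
  calls[]
}

#' Kernel-density summary of MAFs across calls
#'
#' Gaussian kernel density over log10(MAF percent), split by
#' classification, with quartiles per class — the summary behind the
#' familiar three-peak cfDNA MAF picture (a low somatic mass, a
#' heterozygous peak near 50% and a homozygous peak near 100%).
#'
#' @param calls data.table of SNV calls (possibly pooled across samples)
#' @return list with `quantiles` (per class: quartiles, mean, n) and
#'   `densities` (per class: `stats::density` object on log10 percent,
#'   `NULL` for degenerate single-call classes)
#' @export
maf_density_summary <- function(calls) {
  calls <- as.data.table(calls)
  if (nrow(calls) == 0L) stop("no calls to summarize")
  qs <- calls[, .(
    n = .N,
    q1 = quantile(maf, 0.25, names = FALSE),
    median = quantile(maf, 0.5, names = FALSE),
    q3 = quantile(maf, 0.75, names = FALSE),
    mean = mean(maf)), by = classification]
  dens <- lapply(split(calls$maf, calls$classification), function(x) {
    lx <- log10(x * 100)
    if (length(unique(lx)) < 2L) NULL else density(lx, kernel = "gaussian")
  })
  list(quantiles = qs[], densities = dens)
}
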