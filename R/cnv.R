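#' Count unique fragments per gene
#'
#' Counts the reconstructed unique molecules overlapping each gene's
#' targeted regions (a molecule spanning two genes' regions is counted
#' once per gene overlapped).  Both strand halves of the original parent
#' molecules are tracked: `n_watson_half` / `n_crick_half` count
#' molecules whose watson / crick strand family was recovered, and the
#' half-imbalance statistic `|W - C| / (W + C)` is retained as a QC
#' covariate for uneven representation of the two halves.
#'
#' @param cons a `consensus_set`
#' @param panel the `ref_panel`; genes with zero covered bases are
#'   rejected at panel load, not here
#' @return data.table per (sample, gene): `n_fragments`, strand-half
#'   counts, `half_imbalance`, `covered_bp`, `gc`, `capture_eff`
#' @export
count_gene_fragments <- function(cons, panel) {
  mols <- as.data.table(cons$molecules)
  reg <- copy(panel$regions)
  if (any(reg[, sum(end - start), by = gene]$V1 <= 0))
    stop("gene with zero covered bases in panel")
  regk <- reg[, .(chrom, start, end, gene)]
  setkey(regk, chrom, start, end)
  mq <- mols[, .(cons_id, sample_id, chrom, start, end, w_size, c_size)]
  ov <- foverlaps(mq, regk, by.x = c("chrom", "start", "end"),
                  nomatch = NULL)
  # half-open intervals: foverlaps treats ends as closed, drop abutting hits
  ov <- ov[i.start < end & i.end > start]
  ov <- unique(ov[, .(sample_id, gene, cons_id, w_size, c_size)])
  cnt <- ov[, .(n_fragments = .N,
                n_watson_half = sum(w_size > 0L),
                n_crick_half = sum(c_size > 0L)),
            by = .(sample_id, gene)]
  cnt[, half_imbalance := abs(n_watson_half - n_crick_half) /
        pmax(n_watson_half + n_crick_half, 1L)]
  cov <- .gene_covariates(panel)
  cnt <- cov[cnt, on = "gene"]
  setcolorder(cnt, c("sample_id", "gene", "n_fragments", "n_watson_half",
                     "n_crick_half", "half_imbalance", "covered_bp",
                     "gc", "capture_eff"))
  setorderv(cnt, c("sample_id", "gene"))
  cnt[]
}

# per-gene covariates: covered length, length-weighted GC, mean capture
# efficiency proxy
.gene_covariates <- function(panel) {
  r <- panel$regions
  gcs <- vapply(seq_len(nrow(r)), function(i) {
    cs <- panel$chrom_seq[[r$chrom[i]]]
    s <- substring(cs$seq, r$start[i] - cs$base + 1L, r$end[i] - cs$base)
    f <- Biostrings::letterFrequency(Biostrings::DNAString(s), "GC",
                                     as.prob = TRUE)
    as.numeric(f)
  }, numeric(1))
  dt <- data.table(gene = r$gene, w = r$end - r$start, gc = gcs,
                   capture_eff = r$capture_eff)
  dt[, .(covered_bp = sum(w), gc = sum(gc * w) / sum(w),
         capture_eff = sum(capture_eff * w) / sum(w)), by = gene]
}

#' Normalize per-gene fragment counts for preparation/sequencing bias
#'
#' Fragment-count density (fragments per covered base) is divided by the
#' per-gene capture-efficiency proxy, then residual GC-dependent bias is
#' removed by a robust locally-weighted (loess) regression of log density
#' on GC content; the normalized value is observed / fitted.  The robust
#' family keeps amplified outlier genes from dragging the fit.  With
#' degenerate covariates (all equal) the fit collapses to an identity
#' normalization (observed density / mean density).
#'
#' @param counts output of [count_gene_fragments()] for one sample
#' @param span loess span (default 0.75)
#' @return the table with `density` and `normalized` columns added
#' @export
normalize_counts <- function(counts, span = 0.75) {
  counts <- copy(as.data.table(counts))
  if (length(unique(counts$sample_id)) > 1L)
    stop("normalize_counts expects a single sample")
  counts[, density := n_fragments / covered_bp / capture_eff]
  gcs <- counts$gc
  if (length(unique(round(gcs, 6))) < 4L) {
    counts[, normalized := density / mean(density)]
    message("degenerate covariates; identity normalization applied")
    return(counts[])
  }
  fit <- loess(log(density) ~ gc, data = counts, span = span,
               degree = 1, family = "symmetric",
               control = loess.control(surface = "direct"))
  counts[, normalized := density / exp(predict(fit, counts))]
  counts[]
}

#' Diploid baseline from the mode of normalized fragment values
#'
#' The mode of the per-gene normalized fragment values estimates the
#' value corresponding to two copies: most panel genes are diploid, so
#' the mode is robust to a minority of amplified genes.  The mode is
#' located on a Gaussian kernel density with Silverman's bandwidth; a
#' multimodal tie breaks to the lower mode (amplification inflates,
#' rarely deflates).  If most genes sit well above the mode the panel is
#' unlikely to contain a diploid majority and a warning is emitted.
#'
#' @param normalized numeric vector of per-gene normalized values (>= 3)
#' @return the baseline value (normalized units corresponding to CN 2)
#' @export
diploid_baseline <- function(normalized) {
  if (length(normalized) < 3L)
    stop("need >= 3 genes to estimate a diploid baseline")
  d <- density(normalized, bw = "nrd0", kernel = "gaussian")
  ymax <- max(d$y)
  peaks <- which(d$y >= ymax * (1 - 1e-8))
  if (length(peaks) > 1L)
    warning("multimodal baseline; lower mode chosen")
  baseline <- d$x[min(peaks)]
  if (mean(normalized > baseline * 1.15) > 0.5)
    warning("majority of genes above the modal baseline; ",
            "diploid-majority assumption is suspect")
  baseline
}

#' Absolute plasma copy number per gene
#'
#' Scales normalized fragment values so the modal (diploid) gene equals
#' 2.0 copies.
#'
#' @param normalized per-gene normalized values
#' @param baseline output of [diploid_baseline()] (computed if NULL)
#' @return numeric vector of plasma copy numbers
#' @export
plasma_copy_number <- function(normalized, baseline = NULL) {
  if (is.null(baseline)) baseline <- diploid_baseline(normalized)
  2 * normalized / baseline
}

#' Normal-set copy-number statistics
#'
#' Per-gene mean and standard deviation of the normalized fragment value
#' across a cohort of healthy-donor samples, used for z-scoring.
#'
#' @param normalized_list list of per-sample normalized count tables
#'   (outputs of [normalize_counts()])
#' @return list of class `normal_cn_stats` with per-gene `mean`, `sd`, `n`
#' @export
normal_cn_stats <- function(normalized_list) {
  if (length(normalized_list) < 2L) stop("need >= 2 normal samples")
  all <- rbindlist(lapply(normalized_list, function(x)
    as.data.table(x)[, .(sample_id, gene, normalized)]))
  st <- all[, .(mean = mean(normalized), sd = sd(normalized), n = .N),
            by = gene]
  if (any(st$sd <= 0)) stop("zero dispersion in normal set; cannot z-score")
  structure(list(genes = st[], n_samples = length(normalized_list)),
            class = "normal_cn_stats")
}

#' The z threshold for calling amplification
#'
#' Inverse standard-normal CDF at the given confidence level; the
#' default 99.5% gives 2.5758.
#'
#' @param confidence one-sided confidence level (default 0.995)
#' @return numeric threshold in standard units
#' @export
amplification_z_threshold <- function(confidence = 0.995) {
  qnorm(confidence)
}

#' Call gene amplifications by z-score against the normal set
#'
#' z = (normalized - normal mean) / normal sd, computed on normalized
#' fragment values (not on copy number).  A gene is `amplified` when
#' z exceeds the threshold (default 2.5758, the 99.5% normal quantile)
#' and `reportable` when its plasma copy number is at least
#' `reportable_cn` (default 2.2, the clinically significant plasma
#' elevation); a reported amplification call requires both.
#'
#' @param norm_counts normalized count table for one sample
#'   ([normalize_counts()])
#' @param stats a `normal_cn_stats`
#' @param z_threshold default [amplification_z_threshold()]
#' @param reportable_cn plasma-CN reporting threshold (default 2.2)
#' @param cnv_genes optional character vector restricting which genes are
#'   eligible for amplification calls (e.g. the assay's CNV-reportable
#'   genes); all genes are still z-scored
#' @return data.table per gene: unique fragments, normalized value,
#'   plasma CN, z-score, `amplified`, `reportable`, `called`
#' @export
call_amplification <- function(norm_counts, stats,
                               z_threshold = amplification_z_threshold(),
                               reportable_cn = 2.2, cnv_genes = NULL) {
  x <- copy(as.data.table(norm_counts))
  miss <- setdiff(x$gene, stats$genes$gene)
  if (length(miss))
    stop("gene absent from normal-set stats: ", paste(miss, collapse = ", "))
  x[stats$genes, on = "gene", `:=`(norm_mean = i.mean, norm_sd = i.sd)]
  x[, z_score := (normalized - norm_mean) / norm_sd]
  x[, plasma_cn := plasma_copy_number(normalized)]
  x[, amplified := z_score > z_threshold]
  x[, reportable := plasma_cn >= reportable_cn]
  x[, called := amplified & reportable]
  if (!is.null(cnv_genes)) x[!gene %in% cnv_genes, called := FALSE]
  out <- x[, .(sample_id, gene, n_fragments, normalized, plasma_cn,
               z_score, amplified, reportable, called)]
  setorderv(out, c("sample_id", "gene"))
  out[]
}

#' Germline/tumor copy-number mixture
#'
#' Plasma copy number is the tumor-fraction-weighted blend of germline
#' and tumor copy numbers: `(1 - f) * germline_cn + f * tumor_cn`.  A
#' tumor copy number of 10 at 5% tumor fraction yields 2.4 plasma
#' copies.
#'
#' @param tumor_cn gene copy number in the tumor
#' @param tumor_fraction fraction f of the gene's cfDNA that is
#'   tumor-derived, in [0, 1]
#' @param germline_cn germline copy number (default 2)
#' @return plasma copy number
#' @export
plasma_cn_mixture <- function(tumor_cn, tumor_fraction, germline_cn = 2) {
  if (any(tumor_fraction < 0 | tumor_fraction > 1))
    stop("tumor_fraction must lie in [0, 1]")
  (1 - tumor_fraction) * germline_cn + tumor_fraction * tumor_cn
}

#' @rdname plasma_cn_mixture
#' @param plasma_cn observed plasma copy number (for the inverse)
#' @return `tumor_cn_from_plasma`: the tumor copy number implied by an
#'   observed plasma copy number at tumor fraction f (undefined at f = 0)
#' @export
tumor_cn_from_plasma <- function(plasma_cn, tumor_fraction, germline_cn = 2) {
  if (any(tumor_fraction <= 0))
    stop("inverse undefined at tumor_fraction = 0")
  germline_cn + (plasma_cn - germline_cn) / tumor_fraction
}

#' CNV limit-of-detection surface
#'
#' Grid evaluation of amplification detectability over tumor copy number
#' and tumor fraction.  The per-gene counting noise (normal-set sd,
#' expressed in copy-number units as `2 * sd / mean`) sets the minimal
#' detectable plasma excess: at the z threshold the 50%-power limit of
#' detection is `z_threshold * sd_cn` extra plasma copies.
#'
#' @param stats a `normal_cn_stats`
#' @param gene gene symbol to evaluate
#' @param tumor_cn_grid,tumor_fraction_grid grids to evaluate
#' @param z_threshold default [amplification_z_threshold()]
#' @return list with `lod_extra_copies` (minimal detectable plasma
#'   excess, copies) and `surface` (data.table: tumor_cn, f, plasma
#'   excess, detection probability, detectable at >= 50% power)
#' @export
cnv_lod_surface <- function(stats, gene,
                            tumor_cn_grid = seq(3, 20, by = 1),
                            tumor_fraction_grid = c(0.005, 0.01, 0.02,
                                                    0.05, 0.1, 0.2),
                            z_threshold = amplification_z_threshold()) {
  g <- stats$genes[stats$genes$gene == gene]
  if (nrow(g) == 0L) stop("gene absent from normal-set stats: ", gene)
  sd_cn <- 2 * g$sd / g$mean
  lod <- z_threshold * sd_cn
  surf <- CJ(tumor_cn = tumor_cn_grid, tumor_fraction = tumor_fraction_grid)
  surf[, plasma_excess := plasma_cn_mixture(tumor_cn, tumor_fraction) - 2]
  surf[, detect_prob := 1 - pnorm(z_threshold - plasma_excess / sd_cn)]
  surf[, detectable := detect_prob >= 0.5]
  list(gene = gene, sd_cn = sd_cn, lod_extra_copies = lod,
       z_threshold = z_threshold, surface = surf[])
}
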