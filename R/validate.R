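#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Exact tail-inversion interval via the beta quantile identity; at the
#' boundaries the one-sided forms apply (for x = n the lower bound is
#' `(alpha/2)^(1/n)` and the upper bound is 1).
#'
#' @param x successes
#' @param n trials
#' @param level confidence level (default 0.95)
#' @return numeric vector `c(lower, upper)` as fractions
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  if (n <= 0) stop("n must be positive")
  if (x < 0 || x > n) stop("x must lie in [0, n]")
  alpha <- 1 - level
  lower <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Diagnostic accuracy metrics with exact confidence intervals
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP) and accuracy
#' (TP+TN)/total, each as a percentage with an exact binomial CI.
#' Metrics with a zero denominator are reported as `NA` (undefined).
#'
#' @param tp,fp,fn,tn contingency counts (all >= 0)
#' @param ci_level confidence level (default 0.95)
#' @return data.table: metric, estimate, lower, upper (percent)
#' @export
diagnostic_metrics <- function(tp, fp, fn, tn, ci_level = 0.95) {
  if (any(c(tp, fp, fn, tn) < 0)) stop("contingency counts must be >= 0")
  one <- function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    ci <- clopper_pearson(x, n, ci_level)
    c(100 * x / n, 100 * ci[["lower"]], 100 * ci[["upper"]])
  }
  m <- rbind(sensitivity = one(tp, tp + fn),
             specificity = one(tn, tn + fp),
             accuracy = one(tp + tn, tp + fp + fn + tn))
  data.table(metric = rownames(m), estimate = m[, 1],
             lower = m[, 2], upper = m[, 3])
}

#' Theoretical conversion efficiency of amplicon-based cfDNA methods
#'
#' With ~166-bp cfDNA fragments, an amplicon of length x can only
#' capture molecules whose random fragmentation spared the full
#' amplicon footprint, giving `(1 - x/166) * 100` percent efficiency
#' (floored at 0).  Integer-percent rendering truncates: x = 100 bp
#' gives 39.76%, rendered 39%.
#'
#' @param amplicon_length_bp amplicon length x in bp (> 0)
#' @param rendered return the truncated integer percent?
#' @return efficiency in percent
#' @export
amplicon_conversion_efficiency <- function(amplicon_length_bp,
                                           rendered = FALSE) {
  if (any(amplicon_length_bp <= 0)) stop("amplicon length must be positive")
  pct <- pmax(0, (1 - amplicon_length_bp / 166) * 100)
  if (rendered) floor(pct) else pct
}

#' Expected false positives over a targeted region
#'
#' A per-base false-positive rate times the targeted length: a 1% rate
#' on 78,000 bp yields 780 expected false positives, which is why
#' sub-ppm specificity is required for wide panels.
#'
#' @param fp_rate per-base false-positive rate in [0, 1]
#' @param target_bp targeted region size in bases
#' @return expected count
#' @export
expected_false_positives <- function(fp_rate, target_bp) {
  if (any(fp_rate < 0 | fp_rate > 1)) stop("fp_rate must lie in [0, 1]")
  fp_rate * target_bp
}

# one-region mini panel used by the per-variant simulation harnesses
.mini_panel <- function(region_bp = 80L) {
  synthetic_panel(n_genes = 1L, total_bp = region_bp, n_complete = 1L)
}

# simulate, digitize and call one batch of single-variant samples that
# share a mini panel and a trained baseline; returns the calls table
.call_batch <- function(panel, samples, params, baseline, min_support,
                        require_duplex) {
  sets <- lapply(seq_len(nrow(samples)), function(j) {
    v <- truth_variants(samples$chrom[j], samples$pos[j], samples$ref[j],
                        samples$alt[j], "somatic", samples$true_maf[j])
    simulate_sample(panel, v, NULL, params, sample_id = samples$sample_id[j])
  })
  rs <- bind_read_sets(sets)
  cons <- consensus_molecules(rs, panel)
  pile <- pileup(cons, panel)
  call_snvs(pile, baseline, min_support = min_support,
            require_duplex = require_duplex)
}

#' Serial-dilution limit-of-detection study for the SNV caller
#'
#' Runs the full simulate -> digitize -> noise -> call pipeline for
#' `n_variants` SNVs in `n_replicates` replicates at each dilution
#' level, on a small single-region panel per sample.  Detection means
#' the truth variant appears in the calls (at least `min_support` unique
#' molecules, at least one duplex-confirmed, above the site's noise
#' threshold).  The limit of detection is the lowest level at which more
#' than 80% of variant x replicate trials are detected.
#'
#' @param levels dilution levels as MAF fractions (the 0.25% level is
#'   included by default so the >80% rule can land on it)
#' @param n_variants,n_replicates study size (defaults 29 x 3)
#' @param params a `sim_params` (defaults: 3,000 molecules/position,
#'   conversion 0.8)
#' @param region_bp size of the per-variant targeted region
#' @param n_normal normal samples used to train the noise baseline
#' @param min_support,require_duplex detection rule (defaults 2, TRUE)
#' @return list of class `dilution_series`: `levels`, `detection`
#'   (fraction per level), `lod`, `detail` (per-trial outcomes)
#' @export
run_dilution_series <- function(levels = c(0.01, 0.005, 0.003, 0.0025, 0.001),
                                n_variants = 29L, n_replicates = 3L,
                                params = sim_params(), region_bp = 80L,
                                n_normal = 4L, min_support = 2L,
                                require_duplex = TRUE) {
  panel <- .mini_panel(region_bp)
  pp <- panel_positions(panel)
  site <- pp[which.min(abs(pos - (min(pos) + max(pos)) / 2))]
  normals <- make_validation_cohort(panel, params, n_normal, snps_mean = 0,
                                    snps_range = c(0L, 0L))
  npiles <- lapply(normals, function(s)
    pileup(consensus_molecules(s, panel), panel))
  baseline <- train_baseline(npiles, panel)
  alt <- sample(setdiff(c("A", "C", "G", "T"), site$ref),
                n_variants, replace = TRUE)
  detail <- list()
  for (lv in sort(levels, decreasing = TRUE)) {
    samples <- CJ(variant = seq_len(n_variants),
                  replicate = seq_len(n_replicates))
    samples[, `:=`(chrom = site$chrom, pos = site$pos, ref = site$ref,
                   alt = alt[variant], true_maf = lv,
                   sample_id = sprintf("L%g_v%02d_r%d", lv * 100,
                                       variant, replicate))]
    calls <- .call_batch(panel, samples, params, baseline, min_support,
                         require_duplex)
    hit <- calls[samples, on = c("sample_id", "chrom", "pos", "alt"),
                 nomatch = NULL, .(sample_id)]
    samples[, detected := sample_id %in% hit$sample_id]
    samples[, level := lv]
    detail[[length(detail) + 1L]] <-
      samples[, .(level, variant, replicate, sample_id, detected)]
  }
  detail <- rbindlist(detail)
  det <- detail[, .(detection = mean(detected), n = .N), by = level]
  setorder(det, level)
  structure(list(levels = det$level, detection = det$detection,
                 lod = dilution_lod(det$level, det$detection),
                 detail = detail),
            class = "dilution_series")
}

#' Limit of detection from a detection curve
#'
#' @param levels dilution levels (fractions)
#' @param detection detection fraction per level
#' @param rule detection must exceed this fraction (default 0.80)
#' @return the lowest level with detection above the rule (NA if none)
#' @export
dilution_lod <- function(levels, detection, rule = 0.80) {
  ok <- detection > rule
  if (!any(ok)) return(NA_real_)
  min(levels[ok])
}

#' Spike-in accuracy study: sensitivity and specificity over a cohort
#'
#' Emulates a matched spike-in accuracy experiment: for each of
#' `n_samples` host samples, one donor's germline SNP set is spiked at
#' `spike_frac` of molecules (so heterozygous donor SNPs appear at
#' ~spike_frac/2 MAF, homozygous at ~spike_frac), on top of the host's
#' own germline SNPs.  Calls are tallied against truth over all panel
#' bases: spiked sites called are true positives, somatic calls at any
#' other site are false positives, and the remaining site denominator
#' (n_samples x panel bases) counts as true negatives.
#'
#' @param panel a `ref_panel`
#' @param n_samples number of spiked host samples (default 20)
#' @param params a `sim_params`
#' @param spike_frac molecule fraction of the spiked donor (default 0.05)
#' @param n_normal baseline-training cohort size
#' @param snps_mean,snps_range germline SNP count law per donor/host
#' @return list of class `specificity_study`: `table` (tp/fp/fn/tn),
#'   `metrics` (diagnostic metrics with exact CIs), `per_sample`
#' @export
run_specificity_study <- function(panel, n_samples = 20L,
                                  params = sim_params(),
                                  spike_frac = 0.05, n_normal = 5L,
                                  snps_mean = 18, snps_range = c(12L, 27L)) {
  normals <- make_validation_cohort(panel, params, n_normal,
                                    snps_mean, snps_range)
  npiles <- lapply(normals, function(s)
    pileup(consensus_molecules(s, panel), panel))
  baseline <- train_baseline(npiles, panel)
  rm(normals, npiles)
  tp <- 0L; fp <- 0L; fn <- 0L
  per_sample <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    sid <- sprintf("acc%02d", i)
    n_host <- min(max(rpois(1L, snps_mean), snps_range[1]), snps_range[2])
    n_donor <- min(max(rpois(1L, snps_mean), snps_range[1]), snps_range[2])
    host <- random_germline_variants(panel, n_host)
    donor <- random_germline_variants(panel, n_donor)
    # drop donor sites colliding with host SNPs (ambiguous truth)
    donor <- donor[!host, on = c("chrom", "pos")]
    spiked <- truth_variants(donor$chrom, donor$pos, donor$ref, donor$alt,
                             "somatic",
                             spike_frac * ifelse(donor$kind == "germline_hom",
                                                 1, 0.5))
    rs <- simulate_sample(panel, rbind(host, spiked), NULL, params, sid)
    pile <- pileup(consensus_molecules(rs, panel), panel)
    calls <- call_snvs(pile, baseline)
    som <- calls[classification == "somatic"]
    hit <- som[spiked, on = c("chrom", "pos", "alt"), nomatch = NULL]
    tp_i <- nrow(hit)
    fn_i <- nrow(spiked) - tp_i
    fp_i <- nrow(som[!spiked, on = c("chrom", "pos", "alt")][
      !host, on = c("chrom", "pos")])
    tp <- tp + tp_i; fn <- fn + fn_i; fp <- fp + fp_i
    per_sample[[i]] <- data.table(sample_id = sid, n_spiked = nrow(spiked),
                                  tp = tp_i, fn = fn_i, fp = fp_i)
  }
  total_bases <- as.numeric(n_samples) * panel_total_length(panel)
  tn <- total_bases - tp - fp - fn
  structure(list(
    table = list(tp = tp, fp = fp, fn = fn, tn = tn),
    metrics = diagnostic_metrics(tp, fp, fn, tn),
    per_sample = rbindlist(per_sample)),
    class = "specificity_study")
}

#' Paired-call-set concordance (split samples, stressed vs control, ...)
#'
#' R-squared of paired MAFs over variants detected in both call sets
#' (keyed by sample, site and alternate base), plus the both-detected
#' concordance fraction within MAF strata.
#'
#' @param calls_a,calls_b SNV call tables for the paired aliquots
#' @param strata lower MAF bounds (fractions) for concordance strata
#' @return list: `r_squared`, `n_pairs`, `concordance` (per stratum)
#' @export
split_sample_concordance <- function(calls_a, calls_b,
                                     strata = c(0.003, 0.001)) {
  key <- c("sample_id", "chrom", "pos", "alt")
  a <- as.data.table(calls_a)[, c(key, "maf"), with = FALSE]
  b <- as.data.table(calls_b)[, c(key, "maf"), with = FALSE]
  setnames(a, "maf", "maf_a"); setnames(b, "maf", "maf_b")
  pairs <- merge(a, b, by = key, all = TRUE)
  both <- pairs[!is.na(maf_a) & !is.na(maf_b)]
  r2 <- if (nrow(both) >= 2L) cor(both$maf_a, both$maf_b)^2 else NA_real_
  pairs[, maf := pmax(maf_a, maf_b, na.rm = TRUE)]
  conc <- rbindlist(lapply(strata, function(s) {
    sub <- pairs[maf > s]
    data.table(stratum = sprintf("> %g%%", s * 100),
               n = nrow(sub),
               concordance = if (nrow(sub)) mean(!is.na(sub$maf_a) &
                                                   !is.na(sub$maf_b))
                             else NA_real_)
  }))
  list(r_squared = r2, n_pairs = nrow(both), concordance = conc)
}

#' Simulated split-sample robustness study
#'
#' Draws `n_variants` SNVs with true MAFs log-spaced over `maf_range`,
#' simulates two independent aliquots of each through the full pipeline,
#' and reports the paired-MAF concordance (R-squared rounds to 1.0 at
#' assay-scale molecule counts because binomial sampling noise is small
#' relative to the MAF spread).
#'
#' @param n_variants number of SNVs (default 24)
#' @param maf_range range of true MAFs (default 0.1% to 30%)
#' @param params a `sim_params`
#' @param region_bp per-variant region size
#' @param n_normal baseline-training cohort size
#' @return list: `concordance` ([split_sample_concordance()] output),
#'   `calls_a`, `calls_b`, `truth`
#' @export
run_split_sample_study <- function(n_variants = 24L,
                                   maf_range = c(0.001, 0.30),
                                   params = sim_params(), region_bp = 80L,
                                   n_normal = 4L) {
  panel <- .mini_panel(region_bp)
  pp <- panel_positions(panel)
  site <- pp[which.min(abs(pos - (min(pos) + max(pos)) / 2))]
  normals <- make_validation_cohort(panel, params, n_normal, snps_mean = 0,
                                    snps_range = c(0L, 0L))
  npiles <- lapply(normals, function(s)
    pileup(consensus_molecules(s, panel), panel))
  baseline <- train_baseline(npiles, panel)
  mafs <- pmin(exp(seq(log(maf_range[1]), log(maf_range[2]),
                       length.out = n_variants)), 0.5)
  alt <- sample(setdiff(c("A", "C", "G", "T"), site$ref),
                n_variants, replace = TRUE)
  truth <- data.table(variant = seq_len(n_variants), chrom = site$chrom,
                      pos = site$pos, ref = site$ref, alt = alt,
                      true_maf = mafs)
  one_aliquot <- function(tag) {
    samples <- copy(truth)
    samples[, sample_id := sprintf("v%02d", variant)]
    .call_batch(panel, samples, params, baseline,
                min_support = 2L, require_duplex = TRUE)
  }
  calls_a <- one_aliquot("a")
  calls_b <- one_aliquot("b")
  list(concordance = split_sample_concordance(calls_a, calls_b),
       calls_a = calls_a, calls_b = calls_b, truth = truth)
}

#' Genomic-DNA interference report
#'
#' Per-sample mass ratio of long genomic-DNA fragments (> 500 bp) to
#' short cfDNA fragments (< 500 bp), with cohort box-plot summary
#' statistics (median, quartiles).
#'
#' @param fragment_lengths named list of per-sample fragment-length
#'   vectors (bp); see [fragment_lengths()]
#' @return list: `per_sample` (data.table sample_id, gdna_ratio),
#'   `summary` (median and quartiles of the ratios)
#' @export
gdna_interference_report <- function(fragment_lengths) {
  per <- rbindlist(lapply(seq_along(fragment_lengths), function(i) {
    len <- fragment_lengths[[i]]
    nm <- names(fragment_lengths)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- sprintf("sample%02d", i)
    long <- sum(as.numeric(len[len > 500]))
    short <- sum(as.numeric(len[len < 500]))
    data.table(sample_id = nm,
               gdna_ratio = if (short > 0) long / short else Inf)
  }))
  qs <- quantile(per$gdna_ratio, c(0.25, 0.5, 0.75), names = FALSE)
  list(per_sample = per,
       summary = list(q1 = qs[1], median = qs[2], q3 = qs[3]))
}
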