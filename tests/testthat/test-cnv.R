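# synthetic per-gene count table with a known GC bias and capture
# efficiencies; n genes, density ~ base_density * eff * exp(slope * gc)
synthetic_counts <- function(n = 54L, base_density = 5,
                             covered_bp = 1500L, slope = 1.2,
                             eff = rep(1, n), cn = rep(2, n), seed = 1L) {
  set.seed(seed)
  gc <- runif(n, 0.35, 0.65)
  lambda <- base_density * covered_bp * eff * exp(slope * (gc - 0.5)) * cn / 2
  data.table(sample_id = "s1", gene = sprintf("G%02d", seq_len(n)),
             n_fragments = rpois(n, lambda),
             n_watson_half = NA_integer_, n_crick_half = NA_integer_,
             half_imbalance = 0, covered_bp = covered_bp, gc = gc,
             capture_eff = eff)
}

test_that("gene fragment counting handles containment and spanning", {
  # two genes adjacent on one contig so a molecule can span both
  p <- ref_panel(
    data.table(chrom = "ctg", start = c(0L, 100L), end = c(100L, 200L),
               gene = c("G1", "G2"), exon = "e1", class = "complete_exon"),
    list(ctg = list(base = 0L, seq = strrep("ACGT", 50))))
  mols <- data.table(
    cons_id = 1:3, sample_id = "s1", chrom = "ctg",
    start = c(10L, 95L, 120L), end = c(60L, 150L, 180L),
    w_size = c(2L, 1L, 0L), c_size = c(1L, 1L, 2L))
  cons <- structure(list(molecules = mols, calls = data.table()),
                    class = "consensus_set")
  cnt <- count_gene_fragments(cons, p)
  expect_equal(cnt[gene == "G1", n_fragments], 2L)   # mol 1 + spanning mol 2
  expect_equal(cnt[gene == "G2", n_fragments], 2L)   # spanning mol 2 + mol 3
  expect_equal(cnt[gene == "G1", n_watson_half], 2L)
  expect_equal(cnt[gene == "G2", n_crick_half], 2L)
})

test_that("strand-half imbalance vanishes with depth", {
  set.seed(900)
  p <- tiny_panel()
  rs <- simulate_sample(p, NULL, NULL, quick_params(molecules_per_position = 600L))
  cnt <- count_gene_fragments(consensus_molecules(rs, p), p)
  expect_true(all(cnt$half_imbalance < 0.05))
})

test_that("normalization removes an injected capture-efficiency bias", {
  eff <- rep(1, 54); eff[7] <- 2    # one diploid gene captured 2x
  cnt <- synthetic_counts(eff = eff, seed = 2L)
  nc <- normalize_counts(cnt)
  med <- median(nc$normalized)
  expect_lt(abs(nc$normalized[7] / med - 1), 0.05)
  # bias-free table normalizes to near-equal values
  nc0 <- normalize_counts(synthetic_counts(seed = 3L))
  expect_lt(sd(nc0$normalized) / mean(nc0$normalized), 0.05)
})

test_that("robust normalization does not shrink an amplified gene", {
  cn <- rep(2, 54); cn[11] <- 3.2
  nc <- normalize_counts(synthetic_counts(cn = cn, seed = 4L))
  base <- diploid_baseline(nc$normalized)
  pcn <- plasma_copy_number(nc$normalized, base)
  expect_lt(abs(pcn[11] - 3.2), 0.25)
  expect_lt(abs(median(pcn[-11]) - 2), 0.1)
})

test_that("degenerate covariates fall back to identity normalization", {
  cnt <- synthetic_counts(n = 6L, slope = 0, seed = 5L)
  cnt[, gc := 0.5]
  expect_message(nc <- normalize_counts(cnt), "identity")
  expect_equal(nc$normalized, nc$density / mean(nc$density))
})

test_that("the modal baseline is robust to a minority of amplified genes", {
  set.seed(6)
  vals <- rnorm(54, 1, 0.02)
  expect_lt(abs(diploid_baseline(vals) - 1), 0.02)
  vals_amp <- vals; vals_amp[1] <- 2.0   # 1 of 54 amplified
  expect_lt(abs(diploid_baseline(vals_amp) - diploid_baseline(vals)), 0.02)
  expect_true(all(abs(plasma_copy_number(vals) - 2) < 0.15))
  # a majority-amplified panel violates the diploid assumption loudly:
  # the sharp low cluster wins the mode but most genes sit far above it
  expect_warning(diploid_baseline(c(rnorm(10, 1, 0.005), runif(12, 1.3, 3))),
                 "majority")
  expect_error(diploid_baseline(c(1, 2)), ">= 3")
})

test_that("z-scores and flags follow the normal-set arithmetic", {
  # normal set: mean 2.00, sd 0.05 in normalized units
  stats <- structure(list(
    genes = data.table(gene = c("EGFR", sprintf("G%02d", 1:9)),
                       mean = 2, sd = 0.05, n = 10L),
    n_samples = 10L), class = "normal_cn_stats")
  norm_counts <- data.table(
    sample_id = "s1", gene = c("EGFR", sprintf("G%02d", 1:9)),
    n_fragments = 1000L, normalized = c(2.4, rep(2, 9)))
  res <- call_amplification(norm_counts, stats)
  egfr <- res[gene == "EGFR"]
  expect_equal(egfr$z_score, 8)
  expect_true(egfr$amplified)        # 8 > 2.5758
  expect_true(egfr$reportable)       # plasma CN ~2.4 >= 2.2
  expect_true(egfr$called)
  others <- res[gene != "EGFR"]
  expect_true(all(abs(others$z_score) < 1e-6))
  expect_false(any(others$amplified))
  # the 2.2-copy reporting boundary is inclusive (exact-baseline check)
  expect_true(plasma_copy_number(2.2, baseline = 2) >= 2.2)
  norm2 <- copy(norm_counts)[gene == "EGFR", normalized := 2.25]
  res2 <- call_amplification(norm2, stats)
  expect_true(res2[gene == "EGFR", reportable])
  expect_false(res2[gene == "G01", reportable])
  # unknown gene -> error
  expect_error(call_amplification(
    rbind(norm_counts, data.table(sample_id = "s1", gene = "NEW",
                                  n_fragments = 1L, normalized = 2)),
    stats), "absent")
})

test_that("mixture arithmetic and its inverse are exact", {
  expect_equal(plasma_cn_mixture(10, 0.05), 2.4)
  expect_equal(plasma_cn_mixture(10, 0), 2)
  expect_equal(plasma_cn_mixture(6, 0.02), 2.08)
  expect_equal(tumor_cn_from_plasma(2.4, 0.05), 10)
  for (f in c(0.01, 0.05, 0.5, 1)) {
    t <- 7.3
    expect_equal(tumor_cn_from_plasma(plasma_cn_mixture(t, f), f), t)
  }
  expect_error(tumor_cn_from_plasma(2.4, 0), "undefined")
  expect_error(plasma_cn_mixture(10, 1.5), "0, 1")
})

test_that("the CNV detection limit scales with counting noise", {
  mk_stats <- function(sd) structure(list(
    genes = data.table(gene = "EGFR", mean = 2, sd = sd, n = 25L),
    n_samples = 25L), class = "normal_cn_stats")
  lo <- cnv_lod_surface(mk_stats(0.07), "EGFR")
  expect_equal(lo$lod_extra_copies, qnorm(0.995) * 0.07)
  expect_lt(abs(lo$lod_extra_copies - 0.2), 0.025)
  hi <- cnv_lod_surface(mk_stats(0.07 * 2.5), "EGFR")
  expect_equal(hi$lod_extra_copies / lo$lod_extra_copies, 2.5)
  # tumor CN 6 at 2% tumor fraction is an 0.08-copy plasma excess
  row <- lo$surface[tumor_cn == 6 & tumor_fraction == 0.02]
  expect_equal(row$plasma_excess, 0.08)
  expect_identical(row$detectable, row$detect_prob >= 0.5)
})

test_that("no amplification calls arise in simulated normal samples", {
  set.seed(901)
  p <- synthetic_panel(n_genes = 12L, total_bp = 3000L)
  par <- sim_params(molecules_per_position = 500L, pcr_dup_mean = 1)
  norm_tbls <- lapply(sprintf("tr%02d", 1:8), function(sid)
    normalize_counts(count_gene_fragments(consensus_molecules(
      simulate_sample(p, NULL, NULL, par, sid), p), p)))
  stats <- normal_cn_stats(norm_tbls)
  n_called <- 0L
  for (i in 1:20) {
    nc <- normalize_counts(count_gene_fragments(consensus_molecules(
      simulate_sample(p, NULL, NULL, par, sprintf("ev%02d", i)), p), p))
    res <- call_amplification(nc, stats)
    n_called <- n_called + sum(res$called)
  }
  expect_equal(n_called, 0L)
})
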