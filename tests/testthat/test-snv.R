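clean_baseline <- function(panel, depth = 1000L) {
  train_baseline(lapply(c("n1", "n2"), function(s)
    fake_pileup(panel, s, depth)), panel)
}

test_that("two duplex molecules in a thousand are callable", {
  p <- tiny_panel()
  bl <- clean_baseline(p)
  pp <- panel_positions(p)
  site <- pp[60]
  alt <- setdiff(c("A", "C", "G", "T"), site$ref)[1]
  pile <- fake_pileup(p, "s1", 1000L,
                      data.table(chrom = site$chrom, pos = site$pos,
                                 alt = alt, n_duplex = 2L))
  calls <- call_snvs(pile, bl)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$maf, 0.002)
  expect_equal(calls$mutant_molecules, 2L)
  expect_identical(calls$classification, "somatic")
  # a single molecule fails default support but passes when relaxed
  pile1 <- fake_pileup(p, "s1", 1667L,
                       data.table(chrom = site$chrom, pos = site$pos,
                                  alt = alt, n_duplex = 1L))
  expect_equal(nrow(call_snvs(pile1, bl)), 0L)
  relaxed <- call_snvs(pile1, bl, min_support = 1L)
  expect_equal(nrow(relaxed), 1L)
  expect_equal(round(relaxed$maf * 100, 2), 0.06)
  expect_true(relaxed$below_lod)
})

test_that("the per-site baseline vetoes sub-threshold signal", {
  p <- tiny_panel()
  pp <- panel_positions(p)
  site <- pp[15]
  alt <- setdiff(c("A", "C", "G", "T"), site$ref)[1]
  # noisy site: threshold 0.5%
  piles <- lapply(c("n1", "n2", "n3"), function(s)
    fake_pileup(p, s, 1000L,
                data.table(chrom = site$chrom, pos = site$pos, alt = alt,
                           n_duplex = 4L)))
  bl <- train_baseline(piles, p, k = 10)
  thr <- threshold_for(bl, site$chrom, site$pos, alt)
  expect_gte(thr, 0.004)
  # observed 0.3% at that site: not called; same signal elsewhere: called
  other <- pp[90]
  alt2 <- setdiff(c("A", "C", "G", "T"), other$ref)[1]
  pile <- fake_pileup(p, "s1", 1000L, rbind(
    data.table(chrom = site$chrom, pos = site$pos, alt = alt, n_duplex = 3L),
    data.table(chrom = other$chrom, pos = other$pos, alt = alt2,
               n_duplex = 3L)))
  calls <- call_snvs(pile, bl)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, other$pos)
})

test_that("duplex confirmation is required for somatic support by default", {
  p <- tiny_panel()
  bl <- clean_baseline(p)
  pp <- panel_positions(p)
  site <- pp[70]
  alt <- setdiff(c("A", "C", "G", "T"), site$ref)[1]
  pile <- fake_pileup(p, "s1", 1000L,
                      data.table(chrom = site$chrom, pos = site$pos,
                                 alt = alt, n_duplex = 0L, n_single = 3L))
  expect_equal(nrow(call_snvs(pile, bl)), 0L)
  noduplex <- call_snvs(pile, bl, require_duplex = FALSE)
  expect_equal(nrow(noduplex), 1L)
  expect_equal(noduplex$mutant_molecules, 3L)
})

test_that("allele-fraction windows classify germline vs somatic", {
  expect_identical(classify_germline(0.50), "germline_het")
  expect_identical(classify_germline(1.00), "germline_hom")
  expect_identical(classify_germline(0.005), "somatic")
  expect_identical(classify_germline(c(0.35, 0.65, 0.85)),
                   c("germline_het", "germline_het", "germline_hom"))
  expect_identical(classify_germline(0.30), "somatic")
  # annotations override the fraction rule
  expect_identical(classify_germline(0.30, "known_germline"), "germline_het")
  expect_identical(classify_germline(0.40, "known_somatic"), "somatic")
})

test_that("uncertainty bins reproduce the quantification table", {
  b10 <- uncertainty_bin(0.10)
  expect_equal(b10$rel, 0.04)
  expect_equal(b10$abs, 0.4)        # +/- 0.4 percentage points at 10% MAF
  b1 <- uncertainty_bin(0.01)
  expect_equal(b1$rel, 0.20)        # 1% sits in the 20% bin per the text rule
  expect_equal(b1$abs, 0.2)
  b03 <- uncertainty_bin(0.003)
  expect_equal(b03$rel, 0.30)
  expect_equal(b03$abs, 0.09)
  expect_equal(uncertainty_bin(0.05)$rel, 0.06)
  expect_equal(uncertainty_bin(0.03)$rel, 0.14)
  # below the 0.25% reporting floor the bin is undefined
  b_low <- uncertainty_bin(0.002)
  expect_true(b_low$extrapolated)
  expect_true(is.na(b_low$rel))
})

test_that("MAF density summary recovers known quartiles", {
  # degenerate single call
  one <- data.table(maf = 0.01, classification = "somatic")
  s1 <- maf_density_summary(one)
  expect_equal(s1$quantiles$median, 0.01)
  expect_null(s1$densities$somatic)
  # lognormal somatic cohort centred on a 0.5% median with a heavy
  # upper tail; recovered quartiles must match the law's own quartiles
  # (the sampling oracle) within Monte-Carlo error
  set.seed(800)
  mu <- log(0.005)
  sigma <- (log(0.025) - log(0.002)) / (2 * qnorm(0.75))
  som <- exp(rnorm(2000, mu, sigma))
  q1_true <- exp(mu - qnorm(0.75) * sigma)
  q3_true <- exp(mu + qnorm(0.75) * sigma)
  germ <- c(rnorm(500, 0.5, 0.02), rnorm(200, 1, 0.005))
  calls <- rbind(
    data.table(maf = som, classification = "somatic"),
    data.table(maf = pmin(germ, 1), classification = rep(
      c("germline_het", "germline_hom"), c(500, 200))))
  s <- maf_density_summary(calls)
  qs <- s$quantiles[classification == "somatic"]
  expect_lt(abs(qs$median - 0.005) / 0.005, 0.10)
  expect_lt(abs(qs$q1 - q1_true) / q1_true, 0.12)
  expect_lt(abs(qs$q3 - q3_true) / q3_true, 0.12)
  # germline peaks sit near 50% and 100%, separated from the somatic mass
  het_peak <- with(s$densities$germline_het, x[which.max(y)])
  expect_lt(abs(10^het_peak - 50), 5)
  expect_lt(10^with(s$densities$somatic, x[which.max(y)]), 10)
})

test_that("estimated MAF recovers truth within the uncertainty band", {
  # full-depth simulations at the quantification-study fractions
  set.seed(801)
  par <- sim_params(molecules_per_position = 3000L)
  p <- cfduplex:::.mini_panel(60L)
  bl <- clean_baseline(p, depth = 2500L)
  pp <- panel_positions(p)
  site <- pp[which.min(abs(pp$pos - (min(pp$pos) + max(pp$pos)) / 2))]
  altb <- setdiff(c("A", "C", "G", "T"), site$ref)[1]
  reps <- 12L
  for (true_maf in c(0.01, 0.05, 0.10)) {
    samples <- data.table(
      variant = seq_len(reps), chrom = site$chrom, pos = site$pos,
      ref = site$ref, alt = altb, true_maf = true_maf,
      sample_id = sprintf("m%g_%02d", true_maf, seq_len(reps)))
    calls <- cfduplex:::.call_batch(p, samples, par, bl, 2L, TRUE)
    hit <- calls[pos == site$pos & alt == altb]
    expect_equal(nrow(hit), reps)
    band <- uncertainty_bin(true_maf)$abs / 100
    expect_lt(abs(mean(hit$maf) - true_maf), band)
  }
})
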