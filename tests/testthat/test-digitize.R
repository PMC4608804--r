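# a 30-bp two-gene reference shared by the surgical digitize tests
surgical_panel <- function() {
  ref_panel(
    data.table(chrom = "ctg", start = c(0L, 20L), end = c(10L, 30L),
               gene = c("G1", "G2"), exon = c("e1", "e1"),
               class = "complete_exon"),
    list(ctg = list(base = 0L, seq = strrep("A", 30))))
}

test_that("quality filtering masks bases and drops mostly-masked reads", {
  p <- surgical_panel()
  spec <- data.table(
    sample_id = "s", mol_id = c(1L, 1L, 2L), bc_w = 1L, bc_c = 2L,
    chrom = "ctg", start = 0L, end = 10L, strand = c("W", "W", "C"),
    dev = list(
      NULL,
      data.table(pos = 3L, base = "C", qual = 10L),        # one low-q base
      data.table(pos = 0:5, base = "G", qual = 5L)))       # 60% masked
  rs <- manual_read_set(spec)
  fr <- filter_reads(rs, min_base_quality = 20L, max_masked_frac = 0.5)
  expect_equal(nrow(fr$reads), 2L)              # 60%-masked read dropped
  expect_true(all(fr$bases[read_id == 2L, masked]))
  # fully high-quality input passes through unchanged
  spec2 <- data.table(
    sample_id = "s", mol_id = 1L, bc_w = 1L, bc_c = 2L, chrom = "ctg",
    start = 0L, end = 10L, strand = c("W", "C"),
    dev = list(NULL, data.table(pos = 3L, base = "C", qual = 30L)))
  fr2 <- filter_reads(manual_read_set(spec2))
  expect_equal(nrow(fr2$reads), 2L)
  expect_false(any(fr2$bases$masked))
})

test_that("family grouping partitions by the exact composite key", {
  spec <- data.table(
    sample_id = "s", mol_id = 1L, bc_w = 5L, bc_c = 9L, chrom = "ctg",
    start = c(0L, 0L, 0L, 2L, 2L), end = c(10L, 10L, 10L, 12L, 12L),
    strand = "W")
  g <- group_families(manual_read_set(spec)$reads)
  expect_equal(uniqueN(g$family_id), 2L)        # same barcodes, two starts
  expect_equal(sort(g[, .N, by = family_id]$N), c(2L, 3L))
})

test_that("supermajority voting follows the q = 0.75 arithmetic", {
  expect_identical(strand_consensus(c("A", "A", "A")), "A")
  expect_identical(strand_consensus(c("A", "A", "G")), NA_character_)
  expect_identical(strand_consensus(c("A", "A", "A", "G")), "A")
  expect_identical(strand_consensus("G"), "G")  # singleton passes through
  # masked members cannot vote but still count toward the family size
  expect_identical(
    strand_consensus(c("A", "A", "G"), quals = rbind(30L, 30L, 10L)),
    NA_character_)
  expect_identical(
    strand_consensus(c("A", "A", "A", "G"),
                     quals = rbind(30L, 30L, 30L, 10L)),
    "A")
})

test_that("duplex comparison vetoes discordant strands", {
  expect_identical(pair_duplex("A", "A")$status, "duplex_confirmed")
  d <- pair_duplex("A", "G")
  expect_identical(d$status, "discordant_no_call")
  expect_true(is.na(d$base))
  s <- pair_duplex("A", NA_character_)
  expect_identical(s$status, "single_strand_only")
  expect_identical(s$base, "A")
  only <- pair_duplex("A", NULL)
  expect_identical(only$status, "single_strand_only")
})

test_that("single-strand errors are never duplex-confirmed", {
  p <- surgical_panel()
  # molecule with 2 reads per strand; W strand carries a shared PCR-style
  # error at pos 4 on both W reads (wins the W consensus)
  spec <- data.table(
    sample_id = "s", mol_id = 1L, bc_w = 3L, bc_c = 4L, chrom = "ctg",
    start = 0L, end = 10L, strand = c("W", "W", "C", "C"),
    dev = list(data.table(pos = 4L, base = "T", qual = 30L),
               data.table(pos = 4L, base = "T", qual = 30L),
               NULL, NULL))
  cons <- consensus_molecules(manual_read_set(spec), p)
  call <- cons$calls[pos == 4L]
  expect_equal(nrow(call), 1L)
  expect_identical(call$status, "discordant_no_call")
  expect_equal(sum(cons$calls$status == "duplex_confirmed"), 0L)
})

test_that("true duplex variants survive with both strands agreeing", {
  p <- surgical_panel()
  spec <- data.table(
    sample_id = "s", mol_id = 1L, bc_w = 3L, bc_c = 4L, chrom = "ctg",
    start = 0L, end = 10L, strand = c("W", "W", "C"),
    dev = list(data.table(pos = 7L, base = "G", qual = 30L),
               data.table(pos = 7L, base = "G", qual = 30L),
               data.table(pos = 7L, base = "G", qual = 30L)))
  cons <- consensus_molecules(manual_read_set(spec), p)
  expect_equal(cons$calls[pos == 7L, status], "duplex_confirmed")
  expect_equal(cons$calls[pos == 7L, base], "G")
  expect_equal(cons$molecules$w_size, 2L)
  expect_equal(cons$molecules$c_size, 1L)
})

test_that("unique molecule counts are invariant to PCR duplication", {
  p <- tiny_panel()
  counts <- vapply(c(1, 2, 5, 10), function(d) {
    set.seed(500)  # identical molecules and conversion draws
    rs <- simulate_sample(p, NULL, NULL, quick_params(pcr_dup_mean = d))
    nrow(consensus_molecules(rs, p)$molecules)
  }, numeric(1))
  expect_true(all(counts == counts[1]))
  expect_gt(counts[1], 0)
})

test_that("unique-molecule depth never exceeds raw read depth", {
  set.seed(501)
  p <- tiny_panel()
  rs <- simulate_sample(p, NULL, NULL, quick_params(pcr_dup_mean = 3))
  cons <- consensus_molecules(rs, p)
  pile <- pileup(cons, p)
  # raw read depth at each position
  pp <- panel_positions(p)
  raw <- vapply(seq_len(nrow(pp)), function(i)
    rs$reads[chrom == pp$chrom[i] & start <= pp$pos[i] & end > pp$pos[i], .N],
    numeric(1))
  mrg <- pile$depth[data.table(chrom = pp$chrom, pos = pp$pos, raw = raw),
                    on = c("chrom", "pos")]
  expect_true(all(mrg$depth <= mrg$raw))
})

test_that("consensus recovery accounting matches conversion efficiency", {
  set.seed(502)
  p <- tiny_panel()
  par <- quick_params(conversion_efficiency = 0.8)
  rs <- simulate_sample(p, NULL, NULL, par)
  cons <- consensus_molecules(rs, p)
  frac <- nrow(cons$molecules) / nrow(rs$truth$molecules)
  n <- nrow(rs$truth$molecules)
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / n) + 0.01)
})

test_that("single-strand molecules are retained and flagged", {
  set.seed(503)
  p <- tiny_panel()
  par <- quick_params(strand_dropout = 0.3)
  rs <- simulate_sample(p, NULL, NULL, par)
  cons <- consensus_molecules(rs, p)
  expect_gt(sum(cons$molecules$single_strand), 0L)
  # dropout-adjusted recovery: converted x (1 - dropout^2)
  frac <- nrow(cons$molecules) / nrow(rs$truth$molecules)
  expect_lt(abs(frac - 0.8 * (1 - 0.3^2)), 0.03)
})

test_that("pileup tallies unique molecules by base", {
  p <- surgical_panel()
  # 3 molecules over G1; molecule 3 duplex-carries C at pos 5
  spec <- data.table(
    sample_id = "s", mol_id = rep(1:3, each = 2L),
    bc_w = rep(c(11L, 12L, 13L), each = 2L),
    bc_c = rep(c(21L, 22L, 23L), each = 2L),
    chrom = "ctg", start = 0L, end = 10L,
    strand = rep(c("W", "C"), 3L),
    dev = list(NULL, NULL, NULL, NULL,
               data.table(pos = 5L, base = "C", qual = 30L),
               data.table(pos = 5L, base = "C", qual = 30L)))
  cons <- consensus_molecules(manual_read_set(spec), p)
  pile <- pileup(cons, p)
  expect_equal(pile$depth[pos == 5L, depth], 3L)
  expect_equal(pile$alts[pos == 5L, .(alt, n_duplex, n_single)],
               data.table(alt = "C", n_duplex = 1L, n_single = 0L))
  # a position covered by zero molecules has zero depth, no alt rows
  expect_equal(pile$depth[pos == 25L, depth], 0L)
  expect_equal(nrow(pile$alts[pos == 25L]), 0L)
})

test_that("sparse consensus matches the brute-force oracle on small instances", {
  p <- tiny_panel(n_genes = 1L, total_bp = 60L)
  for (seed in 1:6) {
    set.seed(600 + seed)
    par <- sim_params(molecules_per_position = 4L,
                      per_base_error_rate = 0.02, lowq_frac = 0.05,
                      pcr_lineage_rate = 0.2, strand_dropout = 0.2,
                      pcr_dup_mean = 2.5)
    v <- if (seed %% 2 == 0) somatic_at_center(p, 0.4) else NULL
    rs <- simulate_sample(p, v, NULL, par)
    if (nrow(rs$reads) == 0L || nrow(rs$reads) > 50L) next
    got <- pipeline_calls_for_oracle(consensus_molecules(rs, p))
    want <- oracle_consensus(rs, p)
    expect_identical(got$molecules, want$molecules)
    expect_equal(as.data.frame(got$calls), as.data.frame(want$calls),
                 ignore_attr = TRUE)
  }
})
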