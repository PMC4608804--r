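library(data.table)

# small deterministic panel for unit tests
tiny_panel <- function(n_genes = 2L, total_bp = 400L, seed = 11L, ...) {
  set.seed(seed)
  synthetic_panel(n_genes = n_genes, total_bp = total_bp, ...)
}

# desk-scale simulation parameters
quick_params <- function(molecules_per_position = 300L, ...) {
  sim_params(molecules_per_position = molecules_per_position, ...)
}

# pick a mid-region site and build a somatic truth variant there
somatic_at_center <- function(panel, maf, alt = NULL) {
  pp <- panel_positions(panel)
  site <- pp[which.min(abs(pos - (min(pos) + max(pos)) / 2))]
  if (is.null(alt)) alt <- setdiff(c("A", "C", "G", "T"), site$ref)[1]
  truth_variants(site$chrom, site$pos, site$ref, alt, "somatic", maf)
}

# simulate -> digitize -> pileup in one step
mini_pipeline <- function(panel, variants = NULL, params = quick_params(),
                          sample_id = "s1", amps = NULL) {
  rs <- simulate_sample(panel, variants, amps, params, sample_id)
  cons <- consensus_molecules(rs, panel)
  list(rs = rs, cons = cons, pile = pileup(cons, panel))
}

# baseline trained on a clean normal cohort of the same panel
quick_baseline <- function(panel, params = quick_params(), n_normal = 3L,
                           snps_mean = 0) {
  normals <- make_validation_cohort(panel, params, n_normal,
                                    snps_mean = snps_mean,
                                    snps_range = c(0L, 30L))
  piles <- lapply(normals, function(s)
    pileup(consensus_molecules(s, panel), panel))
  train_baseline(piles, panel)
}

# hand-build a pileup_set with uniform depth and explicit alt rows
# (alt_rows: data.table with chrom, pos, alt, n_duplex [, n_single, depth])
fake_pileup <- function(panel, sample_id, depth_value, alt_rows = NULL) {
  pp <- panel_positions(panel)
  depth <- data.table(sample_id = sample_id, chrom = pp$chrom,
                      pos = pp$pos, depth = as.integer(depth_value))
  if (!is.null(alt_rows)) {
    a <- as.data.table(alt_rows)
    a[, sample_id := sample_id]
    a[, ref := ref_base_at(panel, chrom, pos)]
    if (!"n_single" %in% names(a)) a[, n_single := 0L]
    if (!"depth" %in% names(a)) a[, depth := as.integer(depth_value)]
    setcolorder(a, c("sample_id", "chrom", "pos", "ref", "alt",
                     "n_duplex", "n_single", "depth"))
  } else {
    a <- data.table(sample_id = character(0), chrom = character(0),
                    pos = integer(0), ref = character(0),
                    alt = character(0), n_duplex = integer(0),
                    n_single = integer(0), depth = integer(0))
  }
  structure(list(depth = depth, alts = a), class = "pileup_set")
}

# hand-build a read_set from explicit reads (for surgical digitize tests):
# `spec` is a data.table with sample_id, mol_id, bc_w, bc_c, chrom, start,
# end, strand, and an optional list-column `dev` of data.tables(pos, base,
# qual)
manual_read_set <- function(spec) {
  spec <- as.data.table(spec)
  spec[, read_id := .I]
  spec[, len := end - start]
  devs <- list()
  if ("dev" %in% names(spec)) {
    for (i in seq_len(nrow(spec))) {
      d <- spec$dev[[i]]
      if (!is.null(d) && nrow(d))
        devs[[length(devs) + 1L]] <- data.table(
          read_id = spec$read_id[i], pos = d$pos, base = d$base,
          qual = if ("qual" %in% names(d)) d$qual else 30L)
    }
    spec[, dev := NULL]
  }
  bases <- if (length(devs)) rbindlist(devs)
           else data.table(read_id = integer(0), pos = integer(0),
                           base = character(0), qual = integer(0))
  if (!"gene" %in% names(spec)) spec[, gene := chrom]
  structure(list(reads = spec[], bases = bases,
                 truth = list(molecules = spec[, .(mol_id)], alleles = bases[0])),
            class = "read_set")
}
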