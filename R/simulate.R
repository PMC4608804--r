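#' Simulation parameters for synthetic cfDNA samples
#'
#' Defaults encode the assay conditions the method targets: ~166-bp
#' double-stranded cfDNA fragments, >80% molecule conversion efficiency,
#' 3,000 unique molecules overlapping each targeted base (about a 10-ng
#' plasma input), and a per-base sequencing error rate of 1e-3 (typical
#' Q30-scale platform error).
#'
#' @param molecules_per_position expected haploid genome-equivalents
#'   (unique cfDNA molecules) overlapping each targeted base
#' @param tumor_fraction fraction of cfDNA molecules that are tumor-derived
#' @param fragment_mean,fragment_sd normal law for cfDNA fragment length (bp)
#' @param conversion_efficiency probability an input molecule is converted
#'   to a sequenceable duplex library molecule
#' @param strand_dropout probability each strand of a converted molecule
#'   is lost independently (0 = both strands always recovered)
#' @param pcr_dup_mean mean PCR family size per strand; sizes are drawn
#'   as 1 + Poisson(pcr_dup_mean - 1)
#' @param per_base_error_rate probability a sequenced base flips to a
#'   uniformly chosen other base
#' @param pcr_lineage_rate probability per strand family of a PCR-lineage
#'   ("jackpot") error shared by a subset of that strand's reads
#' @param lowq_frac fraction of sequenced bases falling below Q20
#' @param gdna_ratio mass ratio of long (>500 bp) genomic-DNA contaminant
#'   fragments to short cfDNA fragments
#' @param gdna_len_range uniform length range (bp) for gDNA fragments
#' @return list of class `sim_params`
#' @export
sim_params <- function(molecules_per_position = 3000L,
                       tumor_fraction = 0,
                       fragment_mean = 166, fragment_sd = 10,
                       conversion_efficiency = 0.8,
                       strand_dropout = 0,
                       pcr_dup_mean = 2,
                       per_base_error_rate = 1e-3,
                       pcr_lineage_rate = 1e-3,
                       lowq_frac = 0.002,
                       gdna_ratio = 0,
                       gdna_len_range = c(600L, 3000L)) {
  p <- as.list(environment())
  fr <- c("tumor_fraction", "conversion_efficiency", "strand_dropout",
          "per_base_error_rate", "pcr_lineage_rate", "lowq_frac")
  for (f in fr)
    if (p[[f]] < 0 || p[[f]] > 1)
      stop(f, " must lie in [0, 1]")
  if (p$molecules_per_position < 1) stop("molecules_per_position must be >= 1")
  if (p$gdna_ratio < 0) stop("gdna_ratio must be >= 0")
  structure(p, class = "sim_params")
}

#' Genome copies from cfDNA mass
#'
#' One haploid genome copy has a mass of 3.3 pg (0.0033 ng), so a 5-30 ng
#' input corresponds to 1,500-9,000 genome copies.
#'
#' @param mass_ng input cfDNA mass in nanograms (> 0)
#' @param round_to_hundred round to the nearest hundred for reporting?
#' @return number of haploid genome copies
#' @export
genome_copies_from_mass <- function(mass_ng, round_to_hundred = FALSE) {
  if (any(mass_ng <= 0)) stop("mass_ng must be positive")
  copies <- mass_ng / 0.0033
  if (round_to_hundred) round(copies / 100) * 100 else copies
}

#' Ground-truth variant table constructor
#'
#' @param chrom,pos variant site (0-based panel coordinates)
#' @param ref,alt reference and alternate bases
#' @param kind one of `somatic`, `germline_het`, `germline_hom`
#' @param true_maf true mutant-molecule fraction (somatic only; germline
#'   fractions are implied 0.5 / 1.0)
#' @return data.table of ground-truth variants
#' @export
truth_variants <- function(chrom, pos, ref, alt, kind, true_maf = NA_real_) {
  v <- data.table(chrom = chrom, pos = as.integer(pos), ref = ref,
                  alt = alt, kind = kind, true_maf = true_maf)
  if (any(v$ref == v$alt)) stop("ref and alt must differ")
  bad <- v$kind == "somatic" & (is.na(v$true_maf) | v$true_maf <= 0 | v$true_maf > 0.5)
  if (any(bad)) stop("somatic true_maf must lie in (0, 0.5]")
  v
}

#' Draw random germline SNPs on a panel
#'
#' @param panel a `ref_panel`
#' @param n number of SNPs
#' @param p_hom probability a SNP is homozygous (rest heterozygous)
#' @return a truth-variant data.table
#' @export
random_germline_variants <- function(panel, n, p_hom = 1 / 3) {
  pp <- panel_positions(panel)
  pp <- pp[ref != "N"]
  idx <- sample.int(nrow(pp), min(n, nrow(pp)))
  site <- pp[idx]
  other <- c("A", "C", "G", "T")
  altb <- vapply(site$ref, function(r) sample(setdiff(other, r), 1L), character(1))
  kind <- ifelse(runif(nrow(site)) < p_hom, "germline_hom", "germline_het")
  truth_variants(site$chrom, site$pos, site$ref, altb, kind)
}

#' Draw ground-truth duplex cfDNA molecules
#'
#' Fragments are placed uniformly over each region's overlap window with
#' lengths ~ Normal(`fragment_mean`, `fragment_sd`), so every targeted
#' base is overlapped by ~`molecules_per_position` molecules (Poisson
#' count).  Each molecule receives two independent heptamer strand
#' barcodes (encoded as integers in 1..4^7 = 16384).  For a somatic
#' variant with true MAF m, each overlapping cfDNA molecule carries the
#' alternate allele with probability m (so the mutant-molecule count is
#' Binomial(n, m)); heterozygous germline alleles split Binomial(n, 0.5).
#' Amplified genes draw extra tumor-origin molecules so the expected
#' plasma copy number is (1-f)*germline_cn + f*tumor_cn.  gDNA
#' contaminant fragments (> 500 bp) carry germline alleles only and are
#' dosed by mass ratio.
#'
#' @param panel a `ref_panel`
#' @param variants truth-variant data.table (or NULL)
#' @param amps data.table with `gene`, `tumor_cn` (and optional
#'   `germline_cn`, default 2) for focally amplified genes (or NULL)
#' @param params a `sim_params`
#' @param sample_id sample label carried through the pipeline
#' @return list of class `duplex_molecules` with `molecules` (one row per
#'   double-stranded fragment), `alleles` (sparse non-reference bases per
#'   molecule) and `sample_id`
#' @export
draw_molecules <- function(panel, variants = NULL, amps = NULL,
                           params = sim_params(), sample_id = "s1") {
  if (!is.null(variants) && nrow(variants)) {
    pp <- panel_positions(panel)
    ok <- mapply(function(cm, p) any(pp$chrom == cm & pp$pos == p),
                 variants$chrom, variants$pos)
    if (!all(ok))
      stop("variant position outside panel: ",
           paste(sprintf("%s:%d", variants$chrom[!ok], variants$pos[!ok]),
                 collapse = ", "))
  }
  f <- params$tumor_fraction
  r <- copy(panel$regions)
  r[, plasma_cn := 2]
  if (!is.null(amps) && nrow(amps)) {
    amps <- as.data.table(amps)
    if (!"germline_cn" %in% names(amps)) amps[, germline_cn := 2]
    for (j in seq_len(nrow(amps))) {
      pcn <- (1 - f) * amps$germline_cn[j] + f * amps$tumor_cn[j]
      r[gene == amps$gene[j], plasma_cn := pcn]
    }
  }
  lmean <- params$fragment_mean
  mol_list <- vector("list", nrow(r))
  for (i in seq_len(nrow(r))) {
    L <- r$end[i] - r$start[i]
    w <- L + lmean - 1
    n <- rpois(1L, params$molecules_per_position * (r$plasma_cn[i] / 2) * w / lmean)
    if (n == 0L) next
    len <- pmax(50L, as.integer(round(rnorm(n, lmean, params$fragment_sd))))
    st <- r$start[i] - len + 1L + as.integer(floor(runif(n) * (L + len - 1L)))
    mol_list[[i]] <- data.table(
      chrom = r$chrom[i], gene = r$gene[i], start = st, end = st + len,
      origin = "germline")
  }
  mols <- rbindlist(mol_list)
  if (nrow(mols) == 0L) stop("no molecules drawn; increase molecules_per_position")
  # tumor-origin labelling: fraction f overall; amplified genes carry the
  # extra (plasma_cn - germline_cn) molecules as tumor-derived
  mols[, origin := ifelse(runif(.N) < f, "tumor", "germline")]
  # gDNA contaminant fragments (> 500 bp), dosed by mass
  if (params$gdna_ratio > 0) {
    cf_mass <- sum(mols$end - mols$start)
    glen_mean <- mean(params$gdna_len_range)
    gd_list <- list()
    per_reg_mass <- cf_mass * (r$end - r$start) / sum(r$end - r$start)
    for (i in seq_len(nrow(r))) {
      n <- rpois(1L, params$gdna_ratio * per_reg_mass[i] / glen_mean)
      if (n == 0L) next
      len <- as.integer(round(runif(n, params$gdna_len_range[1],
                                    params$gdna_len_range[2])))
      L <- r$end[i] - r$start[i]
      st <- r$start[i] - len + 1L + as.integer(floor(runif(n) * (L + len - 1L)))
      gd_list[[length(gd_list) + 1L]] <- data.table(
        chrom = r$chrom[i], gene = r$gene[i], start = st, end = st + len,
        origin = "gdna")
    }
    if (length(gd_list)) mols <- rbind(mols, rbindlist(gd_list))
  }
  mols[, mol_id := seq_len(.N)]
  mols[, bc_w := sample.int(16384L, .N, replace = TRUE)]
  mols[, bc_c := sample.int(16384L, .N, replace = TRUE)]
  mols[, sample_id := sample_id]
  setcolorder(mols, c("sample_id", "mol_id", "chrom", "gene", "start",
                      "end", "origin", "bc_w", "bc_c"))

  allele_list <- list()
  if (!is.null(variants) && nrow(variants)) {
    for (j in seq_len(nrow(variants))) {
      v <- variants[j]
      ov <- mols[chrom == v$chrom & start <= v$pos & end > v$pos]
      if (nrow(ov) == 0L) next
      carry <- switch(v$kind,
        germline_hom = rep(TRUE, nrow(ov)),
        germline_het = runif(nrow(ov)) < 0.5,
        somatic = ov$origin != "gdna" & runif(nrow(ov)) < v$true_maf)
      if (v$kind == "somatic")
        mols[mol_id %in% ov$mol_id[carry], origin := "tumor"]
      if (any(carry))
        allele_list[[length(allele_list) + 1L]] <- data.table(
          mol_id = ov$mol_id[carry], chrom = v$chrom, pos = v$pos,
          base = v$alt)
    }
  }
  alleles <- if (length(allele_list)) rbindlist(allele_list)
             else data.table(mol_id = integer(0), chrom = character(0),
                             pos = integer(0), base = character(0))
  structure(list(molecules = mols, alleles = alleles,
                 sample_id = sample_id, truth = variants),
            class = "duplex_molecules")
}

.other_base <- function(cur) {
  # uniformly chosen base different from `cur`, vectorized
  bases <- c("A", "C", "G", "T")
  idx <- match(cur, bases)
  idx[is.na(idx)] <- 1L  # N treated as A slot; still returns a real base
  pick <- as.integer(floor(runif(length(cur)) * 3)) + 1L
  m <- matrix(c(2L, 3L, 4L, 1L, 3L, 4L, 1L, 2L, 4L, 1L, 2L, 3L),
              nrow = 4L, byrow = TRUE)
  bases[m[cbind(idx, pick)]]
}

#' Amplify molecules and emit error-bearing tagged reads
#'
#' Each molecule converts independently with probability
#' `conversion_efficiency`; each recovered strand emits a PCR family of
#' 1 + Poisson(mean - 1) full-length reads.  Sequencing errors flip each
#' base to a uniformly chosen other base with `per_base_error_rate`;
#' PCR-lineage ("jackpot") errors are injected per strand family at
#' `pcr_lineage_rate` and shared by a random subset of that strand's
#' reads, so duplex comparison has single-strand-consistent artifacts to
#' reject.  A fraction `lowq_frac` of bases is emitted below Q20.
#'
#' Reads are stored sparsely: `reads` holds one row per read (family key
#' = barcode pair + fragment coordinates + strand), and `bases` holds
#' only positions where a read differs from the panel reference or
#' carries low quality; every other base is the reference at Q30.
#'
#' @param mols a `duplex_molecules` object
#' @param panel the `ref_panel` the molecules were drawn on
#' @param params a `sim_params`
#' @return list of class `read_set` with `reads`, `bases`, `truth`
#' @export
amplify_and_sequence <- function(mols, panel, params = sim_params()) {
  m <- mols$molecules
  n <- nrow(m)
  converted <- rbinom(n, 1L, params$conversion_efficiency) == 1L
  keep_w <- converted & (rbinom(n, 1L, 1 - params$strand_dropout) == 1L)
  keep_c <- converted & (rbinom(n, 1L, 1 - params$strand_dropout) == 1L)
  strands <- rbind(
    m[keep_w][, strand := "W"],
    m[keep_c][, strand := "C"])
  if (nrow(strands) == 0L)
    return(structure(list(
      reads = data.table(), bases = data.table(), truth = mols),
      class = "read_set"))
  fam_size <- 1L + rpois(nrow(strands), max(params$pcr_dup_mean - 1, 0))
  reads <- strands[rep(seq_len(nrow(strands)), fam_size)]
  reads[, read_id := seq_len(.N)]
  reads[, len := end - start]
  n_reads <- nrow(reads)

  rows <- list()
  # inherited molecule alleles (priority 1)
  if (nrow(mols$alleles)) {
    inh <- mols$alleles[reads, on = "mol_id", allow.cartesian = TRUE,
                        nomatch = NULL,
                        .(read_id, pos = x.pos, base = x.base,
                          start = i.start, end = i.end)]
    inh <- inh[pos >= start & pos < end, .(read_id, pos, base)]
    if (nrow(inh)) rows$allele <- inh[, `:=`(prio = 1L, qual = 30L)]
  }
  # PCR-lineage errors (priority 2): one event per hit strand family,
  # shared (one erroneous base) by a random subset of that family's reads
  if (params$pcr_lineage_rate > 0) {
    fam_idx <- rep(seq_len(nrow(strands)), fam_size)
    hit <- which(runif(nrow(strands)) < params$pcr_lineage_rate)
    if (length(hit)) {
      ev <- data.table(
        fam = hit,
        pos = strands$start[hit] + as.integer(
          floor(runif(length(hit)) * (strands$end[hit] - strands$start[hit]))),
        mol_id = strands$mol_id[hit], chrom = strands$chrom[hit])
      cur <- ref_base_at(panel, ev$chrom, ev$pos)
      if (nrow(mols$alleles)) {
        key <- mols$alleles[ev, on = c("mol_id", "pos"), x.base]
        cur[!is.na(key)] <- key[!is.na(key)]
      }
      ev[, base := .other_base(cur)]
      lin <- rbindlist(lapply(seq_len(nrow(ev)), function(j) {
        members <- reads$read_id[fam_idx == ev$fam[j]]
        sel <- if (length(members) == 1L) members
               else sample(members, 1L + rbinom(1L, length(members) - 1L, 0.5))
        data.table(read_id = sel, pos = ev$pos[j], base = ev$base[j])
      }))
      rows$lineage <- lin[, `:=`(prio = 2L, qual = 30L)]
    }
  }
  # sequencing errors (priority 3)
  n_err <- rbinom(n_reads, reads$len, params$per_base_error_rate)
  if (sum(n_err)) {
    idx <- rep(seq_len(n_reads), n_err)
    err <- data.table(
      read_id = reads$read_id[idx],
      pos = reads$start[idx] + as.integer(floor(runif(length(idx)) * reads$len[idx])))
    err <- unique(err, by = c("read_id", "pos"))
    cur <- ref_base_at(panel, reads$chrom[match(err$read_id, reads$read_id)],
                       err$pos)
    if (nrow(mols$alleles)) {
      key <- mols$alleles[
        data.table(mol_id = reads$mol_id[match(err$read_id, reads$read_id)],
                   pos = err$pos),
        on = c("mol_id", "pos"), base]
      cur[!is.na(key)] <- key[!is.na(key)]
    }
    err[, base := .other_base(cur)]
    rows$error <- err[, `:=`(prio = 3L, qual = 30L)]
  }
  # low-quality bases (affect qual only; base resolved from other rows/ref)
  n_lowq <- rbinom(n_reads, reads$len, params$lowq_frac)
  if (sum(n_lowq)) {
    idx <- rep(seq_len(n_reads), n_lowq)
    lq <- data.table(
      read_id = reads$read_id[idx],
      pos = reads$start[idx] + as.integer(floor(runif(length(idx)) * reads$len[idx])),
      base = NA_character_, prio = 0L,
      qual = 2L + as.integer(floor(runif(length(idx)) * 18)))
    rows$lowq <- lq
  }
  bases <- rbindlist(rows, use.names = TRUE)
  if (nrow(bases)) {
    setorder(bases, read_id, pos, -prio)
    bases <- bases[, .(base = base[1L], qual = min(qual), prio = prio[1L]),
                   by = .(read_id, pos)]
    # pure low-quality rows carry the base the read actually has there
    na_i <- which(is.na(bases$base))
    if (length(na_i)) {
      cm <- reads$chrom[match(bases$read_id[na_i], reads$read_id)]
      cur <- ref_base_at(panel, cm, bases$pos[na_i])
      if (nrow(mols$alleles)) {
        key <- mols$alleles[
          data.table(mol_id = reads$mol_id[match(bases$read_id[na_i], reads$read_id)],
                     pos = bases$pos[na_i]),
          on = c("mol_id", "pos"), base]
        cur[!is.na(key)] <- key[!is.na(key)]
      }
      set(bases, na_i, "base", cur)
    }
    bases[, prio := NULL]
  } else {
    bases <- data.table(read_id = integer(0), pos = integer(0),
                        base = character(0), qual = integer(0))
  }
  reads <- reads[, .(sample_id, read_id, mol_id, bc_w, bc_c, chrom, gene,
                     start, end, strand, len)]
  structure(list(reads = reads, bases = bases, truth = mols),
            class = "read_set")
}

#' Simulate one sample end to end (molecules then reads)
#'
#' @inheritParams draw_molecules
#' @return a `read_set`
#' @export
simulate_sample <- function(panel, variants = NULL, amps = NULL,
                            params = sim_params(), sample_id = "s1") {
  mols <- draw_molecules(panel, variants, amps, params, sample_id)
  amplify_and_sequence(mols, panel, params)
}

#' Combine read sets from several samples into one table pair
#'
#' Re-offsets read and molecule identifiers so they stay unique across
#' samples; family keys already include the sample id.
#'
#' @param sets list of `read_set` objects
#' @return a `read_set` with combined tables (truth = list of inputs' truths)
#' @export
bind_read_sets <- function(sets) {
  off_r <- 0L; off_m <- 0L
  rs <- vector("list", length(sets)); bs <- vector("list", length(sets))
  ms <- vector("list", length(sets)); as_ <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    r <- copy(s$reads); b <- copy(s$bases); m <- copy(s$truth$molecules)
    a <- copy(s$truth$alleles)
    if (nrow(r)) { r[, read_id := read_id + off_r]; r[, mol_id := mol_id + off_m] }
    if (nrow(b)) b[, read_id := read_id + off_r]
    m[, mol_id := mol_id + off_m]
    if (nrow(a)) a[, mol_id := mol_id + off_m]
    off_r <- off_r + (if (nrow(r)) max(s$reads$read_id) else 0L)
    off_m <- off_m + max(s$truth$molecules$mol_id)
    rs[[i]] <- r; bs[[i]] <- b; ms[[i]] <- m; as_[[i]] <- a
  }
  structure(list(
    reads = rbindlist(rs), bases = rbindlist(bs),
    truth = list(molecules = rbindlist(ms), alleles = rbindlist(as_),
                 per_sample = lapply(sets, function(s) s$truth$truth))),
    class = "read_set")
}

#' Simulate a cohort of healthy-donor normal samples
#'
#' Each sample carries only germline SNPs (count drawn around
#' `snps_mean`, truncated to `snps_range`, matching a typical 12-27 SNPs
#' per sample on a 78-kbp panel), no somatic content, and diploid copy
#' number for every gene.  Used to train noise baselines and normal-set
#' copy-number statistics.
#'
#' @param panel a `ref_panel`
#' @param params a `sim_params`
#' @param n_normal number of samples (>= 2)
#' @param snps_mean,snps_range Poisson mean and truncation range for the
#'   per-sample germline SNP count
#' @return list of `read_set` objects named `normal01`, ...
#' @export
make_validation_cohort <- function(panel, params = sim_params(),
                                   n_normal = 10L, snps_mean = 18,
                                   snps_range = c(12L, 27L)) {
  if (n_normal < 2L) stop("n_normal must be >= 2")
  lapply(seq_len(n_normal), function(i) {
    n_snp <- min(max(rpois(1L, snps_mean), snps_range[1]), snps_range[2])
    v <- random_germline_variants(panel, n_snp)
    simulate_sample(panel, v, NULL, params,
                    sample_id = sprintf("normal%02d", i))
  })
}

#' Per-sample fragment-length vectors from ground truth
#'
#' @param sets list of `read_set` or `duplex_molecules` objects
#' @return named list of integer fragment lengths per sample
#' @export
fragment_lengths <- function(sets) {
  lapply(sets, function(s) {
    m <- if (inherits(s, "read_set")) s$truth$molecules else s$molecules
    m$end - m$start
  })
}

#' Barcode collision rate among drawn molecules
#'
#' Molecule identity downstream is the composite key (barcode pair,
#' start, end); distinct molecules sharing that key merge.  Returns the
#' fraction of molecules lost to such collisions.
#'
#' @param mols a `duplex_molecules` object
#' @return fraction in [0, 1]
#' @export
barcode_collision_rate <- function(mols) {
  m <- mols$molecules
  n_key <- nrow(unique(m[, .(chrom, start, end, bc_w, bc_c)]))
  1 - n_key / nrow(m)
}
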