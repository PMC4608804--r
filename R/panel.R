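#' Targeted panel representation
#'
#' A `ref_panel` bundles the targeted regions of a capture panel (BED-like,
#' 0-based half-open coordinates) with the reference sequence underlying
#' each region.  Regions carry a gene symbol, an exon label and a coverage
#' class (`complete_exon` for genes whose every exon is covered,
#' `critical_exon` otherwise), plus a per-region capture-efficiency proxy
#' used as a normalization covariate by the copy-number caller.
#'
#' @param regions data.table with columns `chrom`, `start`, `end`, `gene`,
#'   `exon`, `class` and optionally `capture_eff` (default 1).
#' @param chrom_seq named list, one entry per chromosome/contig, each a
#'   `list(base = <0-based coordinate of the first stored base>,
#'   seq = <character scalar>)`.  Positions outside the stored window
#'   read as `"N"`.
#' @return An object of class `ref_panel`.
#' @export
ref_panel <- function(regions, chrom_seq) {
  regions <- as.data.table(regions)
  req <- c("chrom", "start", "end", "gene", "exon", "class")
  miss <- setdiff(req, names(regions))
  if (length(miss))
    stop("panel regions lack column(s): ", paste(miss, collapse = ", "))
  if (!"capture_eff" %in% names(regions)) regions[, capture_eff := 1]
  regions[, start := as.integer(start)]
  regions[, end := as.integer(end)]
  if (any(regions$end <= regions$start))
    stop("panel regions must satisfy end > start (0-based half-open)")
  bad_class <- setdiff(unique(regions$class),
                       c("complete_exon", "critical_exon"))
  if (length(bad_class))
    stop("unknown coverage class: ", paste(bad_class, collapse = ", "))
  setorder(regions, chrom, start)
  # regions within one gene must not overlap
  ov <- regions[, {
    if (.N > 1L) {
      o <- order(start)
      any(start[o][-1L] < end[o][-.N])
    } else FALSE
  }, by = .(gene, chrom)]
  if (any(ov$V1))
    stop("overlapping regions within gene(s): ",
         paste(unique(ov$gene[ov$V1]), collapse = ", "))
  # sequence must exist for every region
  for (i in seq_len(nrow(regions))) {
    cs <- chrom_seq[[regions$chrom[i]]]
    if (is.null(cs))
      stop("no reference sequence for contig ", regions$chrom[i])
    if (regions$start[i] < cs$base ||
        regions$end[i] > cs$base + nchar(cs$seq))
      stop("reference sequence does not cover region ",
           regions$chrom[i], ":", regions$start[i], "-", regions$end[i])
  }
  structure(list(regions = regions, chrom_seq = chrom_seq),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf(
    "ref_panel: %d regions, %d genes, %s bp targeted\n",
    nrow(x$regions), length(unique(x$regions$gene)),
    format(panel_total_length(x), big.mark = ",")))
  invisible(x)
}

#' Total targeted length of a panel in base pairs
#' @param panel a `ref_panel`
#' @return integer, sum of region widths
#' @export
panel_total_length <- function(panel) {
  sum(panel$regions$end - panel$regions$start)
}

#' Reference base lookup (vectorized)
#'
#' @param panel a `ref_panel`
#' @param chrom,pos parallel vectors of contig names and 0-based positions
#' @return character vector of bases; `"N"` outside the stored sequence
#' @export
ref_base_at <- function(panel, chrom, pos) {
  chrom <- rep_len(chrom, length(pos))
  out <- rep("N", length(pos))
  for (cm in unique(chrom)) {
    cs <- panel$chrom_seq[[cm]]
    if (is.null(cs)) next
    i <- which(chrom == cm)
    off <- pos[i] - cs$base + 1L
    ok <- off >= 1L & off <= nchar(cs$seq)
    if (!any(ok)) next
    out[i[ok]] <- substring(cs$seq, off[ok], off[ok])
  }
  out
}

#' Per-position table of all targeted panel positions
#'
#' @param panel a `ref_panel`
#' @return data.table with `chrom`, `pos` (0-based), `gene`, `ref`
#' @export
panel_positions <- function(panel) {
  pp <- panel$regions[, .(pos = seq.int(start, end - 1L)),
                      by = .(chrom, start, end, gene)]
  pp[, c("start", "end") := NULL]
  pp[, ref := ref_base_at(panel, chrom, pos)]
  pp[]
}

#' Read a panel from a BED-like TSV and a region FASTA
#'
#' The TSV carries 6 or 7 columns: `chrom`, `start`, `end`, `gene`,
#' `exon`, `class`, and optionally `capture_eff`; a header line is
#' detected and allowed.  Coordinates are 0-based half-open.  The FASTA
#' supplies one record per region, named `"<chrom>:<start>-<end>"`, whose
#' length must equal the region width.  Gaps between regions on a contig
#' are padded with `N`.
#'
#' @param bed_path path to the region TSV
#' @param fasta_path path to the companion FASTA
#' @return a `ref_panel`
#' @examples
#' bed <- system.file("extdata", "synthetic_panel.bed", package = "cfduplex")
#' fa <- system.file("extdata", "synthetic_panel.fa", package = "cfduplex")
#' p <- read_panel(bed, fa)
#' panel_total_length(p)
#' @export
read_panel <- function(bed_path, fasta_path) {
  dt <- fread(bed_path, header = FALSE, sep = "\t",
              colClasses = list(character = 1))
  if (nrow(dt) == 0L) stop("panel file has no records")
  if (identical(tolower(as.character(dt[1, 2])), "start"))
    dt <- dt[-1L]
  if (ncol(dt) < 6L) stop("panel TSV needs >= 6 columns")
  nm <- c("chrom", "start", "end", "gene", "exon", "class", "capture_eff")
  setnames(dt, seq_len(min(ncol(dt), 7L)), nm[seq_len(min(ncol(dt), 7L))])
  dt[, start := as.integer(start)]
  dt[, end := as.integer(end)]
  if ("capture_eff" %in% names(dt)) dt[, capture_eff := as.numeric(capture_eff)]

  fa <- Biostrings::readDNAStringSet(fasta_path)
  want <- sprintf("%s:%d-%d", dt$chrom, dt$start, dt$end)
  miss <- setdiff(want, names(fa))
  if (length(miss))
    stop("FASTA lacks record(s): ", paste(head(miss, 3), collapse = ", "))
  w <- Biostrings::width(fa[want])
  if (any(w != dt$end - dt$start))
    stop("sequence/region length mismatch for ",
         paste(want[w != dt$end - dt$start], collapse = ", "))

  chrom_seq <- list()
  for (cm in unique(dt$chrom)) {
    sub <- dt[chrom == cm][order(start)]
    base <- min(sub$start)
    span <- max(sub$end) - base
    buf <- rep("N", span)
    for (j in seq_len(nrow(sub))) {
      s <- as.character(fa[[sprintf("%s:%d-%d", cm, sub$start[j], sub$end[j])]])
      buf[(sub$start[j] - base + 1L):(sub$end[j] - base)] <-
        strsplit(s, "")[[1]]
    }
    chrom_seq[[cm]] <- list(base = base, seq = paste(buf, collapse = ""))
  }
  ref_panel(dt, chrom_seq)
}

#' Write a panel to a BED-like TSV and a region FASTA
#'
#' Inverse of [read_panel()]: `read_panel(write_panel(p)) == p` on the
#' region table and the targeted sequence.
#'
#' @param panel a `ref_panel`
#' @param bed_path,fasta_path output paths
#' @return invisibly, the two paths
#' @export
write_panel <- function(panel, bed_path, fasta_path) {
  r <- panel$regions
  fwrite(r[, .(chrom, start, end, gene, exon, class, capture_eff)],
         bed_path, sep = "\t", col.names = FALSE)
  seqs <- vapply(seq_len(nrow(r)), function(i) {
    cs <- panel$chrom_seq[[r$chrom[i]]]
    substring(cs$seq, r$start[i] - cs$base + 1L, r$end[i] - cs$base)
  }, character(1))
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- sprintf("%s:%d-%d", r$chrom, r$start, r$end)
  Biostrings::writeXStringSet(ss, fasta_path)
  invisible(c(bed_path, fasta_path))
}

# 54 cancer-gene symbols for the synthetic panel (the three CNV-reportable
# genes first)
.panel_genes <- c(
  "EGFR", "ERBB2", "MET", "KRAS", "NRAS", "HRAS", "BRAF", "TP53",
  "PIK3CA", "PTEN", "APC", "ALK", "RET", "ROS1", "KIT", "PDGFRA",
  "SMAD4", "STK11", "AKT1", "ATM", "CCND1", "CCND2", "CCNE1", "CDH1",
  "CDK4", "CDK6", "CDKN2A", "CTNNB1", "ESR1", "EZH2", "FBXW7", "FGFR1",
  "FGFR2", "FGFR3", "GATA3", "GNA11", "GNAQ", "GNAS", "IDH1", "IDH2",
  "JAK2", "JAK3", "MAP2K1", "MAP2K2", "MLH1", "MPL", "MYC", "NF1",
  "NFE2L2", "NOTCH1", "NPM1", "RAF1", "RB1", "SMO")

#' Build a synthetic targeted panel
#'
#' Generates a random-sequence analog of a 54-gene, ~78-kbp pan-cancer
#' cfDNA panel: each gene lives on its own contig (named by the gene),
#' split into a few exon regions, with per-gene GC content drawn from
#' U(0.35, 0.65) so normalization covariates have realistic spread.  The
#' first `n_complete` genes are flagged `complete_exon`, the rest
#' `critical_exon`.  Scale it down (`n_genes`, `total_bp`) for desk tests.
#'
#' @param n_genes number of genes (<= 54 named genes, then `GENE<k>`)
#' @param total_bp total targeted length to distribute across genes
#' @param n_complete number of complete-exon genes
#' @param flank untargeted reference flank retained per contig (bp), so
#'   simulated fragments overlapping region edges still have sequence
#' @param capture_eff_sd lognormal sd of the per-region capture-efficiency
#'   proxy (0 = unbiased)
#' @param seed optional RNG seed
#' @return a `ref_panel`
#' @export
synthetic_panel <- function(n_genes = 54L, total_bp = 78000L,
                            n_complete = 18L, flank = 400L,
                            capture_eff_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- if (n_genes <= length(.panel_genes)) .panel_genes[seq_len(n_genes)]
           else c(.panel_genes, sprintf("GENE%02d", seq_len(n_genes - length(.panel_genes))))
  per_gene <- diff(round(seq(0, total_bp, length.out = n_genes + 1L)))
  reg_list <- vector("list", n_genes)
  chrom_seq <- list()
  for (i in seq_len(n_genes)) {
    g <- genes[i]
    n_ex <- max(1L, min(rpois(1L, 3L) + 1L, per_gene[i] %/% 120L))
    cut <- diff(round(seq(0, per_gene[i], length.out = n_ex + 1L)))
    cut <- cut[cut > 0]
    n_ex <- length(cut)
    intron <- if (n_ex > 1L) sample(200:1500, n_ex - 1L, replace = TRUE) else integer(0)
    starts <- flank + cumsum(c(0L, cut[-n_ex] + intron))
    ends <- starts + cut
    span <- ends[n_ex] + flank
    gcp <- runif(1, 0.35, 0.65)
    seqc <- paste(sample(c("A", "C", "G", "T"), span, replace = TRUE,
                         prob = c((1 - gcp) / 2, gcp / 2, gcp / 2, (1 - gcp) / 2)),
                  collapse = "")
    chrom_seq[[g]] <- list(base = 0L, seq = seqc)
    eff <- if (capture_eff_sd > 0) rlnorm(n_ex, 0, capture_eff_sd) else rep(1, n_ex)
    reg_list[[i]] <- data.table(
      chrom = g, start = as.integer(starts), end = as.integer(ends),
      gene = g, exon = sprintf("exon%d", seq_len(n_ex)),
      class = if (i <= n_complete) "complete_exon" else "critical_exon",
      capture_eff = eff)
  }
  ref_panel(rbindlist(reg_list), chrom_seq)
}

#' Write SNV calls as VCF v4.2
#'
#' Positions are emitted 1-based; MAF is written as the `AF` INFO field
#' (fraction), with mutant and total unique-molecule counts and the
#' germline/somatic classification.  Germline rows are excluded unless
#' `report_germline` is set.  Output is deterministically ordered by
#' (chrom, pos, alt) with fixed float formatting, so identical inputs give
#' byte-identical files.
#'
#' @param calls data.table of SNV calls (see [call_snvs()])
#' @param panel a `ref_panel`; calls outside the panel are rejected
#' @param path output path
#' @param report_germline include germline-classified calls?
#' @return invisibly, `path`
#' @export
write_vcf <- function(calls, panel, path, report_germline = FALSE) {
  calls <- as.data.table(calls)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=cfduplex",
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Mutant allele fraction (mutant unique molecules / total unique molecules)">',
    '##INFO=<ID=MM,Number=A,Type=Integer,Description="Mutant unique molecules">',
    '##INFO=<ID=DM,Number=A,Type=Integer,Description="Duplex-confirmed mutant unique molecules">',
    '##INFO=<ID=TM,Number=1,Type=Integer,Description="Total unique molecules at position">',
    '##INFO=<ID=CLASS,Number=A,Type=String,Description="somatic, germline_het or germline_hom">',
    '##INFO=<ID=UNC,Number=A,Type=Float,Description="Absolute MAF uncertainty, percentage points">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(calls)) {
    inside <- mapply(function(cm, p)
      any(panel$regions$chrom == cm & panel$regions$start <= p &
            panel$regions$end > p),
      calls$chrom, calls$pos)
    if (!all(inside))
      stop("call position outside panel: ",
           paste(sprintf("%s:%d", calls$chrom[!inside], calls$pos[!inside]),
                 collapse = ", "))
    if (!report_germline)
      calls <- calls[classification == "somatic"]
  }
  lines <- hdr
  if (nrow(calls)) {
    setorder(calls, chrom, pos, alt)
    unc <- ifelse(is.na(calls$uncertainty_abs), ".",
                  sprintf("%.4f", calls$uncertainty_abs))
    lines <- c(lines, sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.6f;MM=%d;DM=%d;TM=%d;CLASS=%s;UNC=%s",
      calls$chrom, calls$pos + 1L, calls$ref, calls$alt, calls$maf,
      calls$mutant_molecules, calls$duplex_mutant, calls$total_molecules,
      calls$classification, unc))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Sample-level quality control
#'
#' A sample fails QC if the cfDNA input mass is below the configured
#' minimum (assay-scale default 5 ng) or the mean raw base coverage is
#' below the configured minimum (assay-scale default 3,000x).  Thresholds
#' live in the run configuration so desk-scale tests can scale them.
#'
#' @param reads_summary list with `input_mass_ng` and `mean_raw_depth`
#' @param config a run configuration (see [default_config()])
#' @return list with `pass` (logical) and `reasons` (character)
#' @export
sample_qc <- function(reads_summary, config = default_config()) {
  reasons <- character(0)
  if (reads_summary$input_mass_ng < config$qc$min_input_ng)
    reasons <- c(reasons, sprintf(
      "insufficient input: %.2f ng < %.2f ng minimum",
      reads_summary$input_mass_ng, config$qc$min_input_ng))
  if (reads_summary$mean_raw_depth < config$qc$min_mean_depth)
    reasons <- c(reasons, sprintf(
      "insufficient coverage: mean raw depth %.0fx < %dx minimum",
      reads_summary$mean_raw_depth, config$qc$min_mean_depth))
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Default run configuration
#'
#' Assay-scale defaults: minimum 5 ng input (~1,500 genome copies at
#' 3.3 pg per haploid copy), minimum mean raw coverage 3,000x, minimum
#' base quality Q20; consensus supermajority 0.75; noise threshold
#' mean + 10 sd with a 2-molecule floor; SNV minimum support 2 unique
#' molecules with at least one duplex-confirmed; CNV z threshold
#' `qnorm(0.995)` = 2.5758 and reportable plasma copy number >= 2.2.
#'
#' @param seed integer seed recorded in the config
#' @return nested list of per-stage parameter blocks
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      molecules_per_position = 3000L, tumor_fraction = 0,
      fragment_mean = 166, fragment_sd = 10,
      conversion_efficiency = 0.8, strand_dropout = 0,
      pcr_dup_mean = 2, per_base_error_rate = 1e-3,
      pcr_lineage_rate = 1e-3, lowq_frac = 0.002, gdna_ratio = 0),
    consensus = list(min_base_quality = 20L, max_masked_frac = 0.5,
                     supermajority = 0.75),
    noise = list(k = 10, floor_molecules = 2L),
    snv = list(min_support = 2L, require_duplex = TRUE,
               het_window = c(0.35, 0.65), hom_min = 0.85,
               maf_floor = 0.0025),
    cnv = list(z_threshold = qnorm(0.995), reportable_cn = 2.2,
               cnv_genes = c("EGFR", "ERBB2", "MET")),
    qc = list(min_input_ng = 5, min_mean_depth = 3000L, min_qscore = 20L))
}

#' Read / write a run configuration (YAML)
#'
#' Configurations round-trip losslessly through the file.
#'
#' @param path YAML file path
#' @param config configuration list
#' @return `read_config`: the configuration list
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15L)
  invisible(path)
}
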