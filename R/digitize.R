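#' Mask low-quality bases and drop unusable reads
#'
#' Bases below `min_base_quality` are masked (excluded from consensus
#' voting, not altered); reads with more than `max_masked_frac` of their
#' bases masked are dropped entirely.
#'
#' @param rs a `read_set`
#' @param min_base_quality Phred threshold (default Q20)
#' @param max_masked_frac maximum tolerated masked fraction per read
#' @return a `read_set` whose `bases` carry a logical `masked` column
#' @export
filter_reads <- function(rs, min_base_quality = 20L, max_masked_frac = 0.5) {
  reads <- copy(rs$reads)
  bases <- copy(rs$bases)
  if (nrow(bases)) {
    bases[, masked := qual < min_base_quality]
    nm <- bases[masked == TRUE, .(n_masked = .N), by = read_id]
    if (nrow(nm)) {
      nm <- nm[reads, on = "read_id", nomatch = NULL]
      drop <- nm[n_masked / len > max_masked_frac, read_id]
      if (length(drop)) {
        reads <- reads[!read_id %in% drop]
        bases <- bases[!read_id %in% drop]
      }
    }
  } else {
    bases <- data.table(read_id = integer(0), pos = integer(0),
                        base = character(0), qual = integer(0),
                        masked = logical(0))
  }
  structure(list(reads = reads, bases = bases, truth = rs$truth),
            class = "read_set")
}

#' Group reads into strand families
#'
#' The family key is the exact composite (sample, watson barcode, crick
#' barcode, fragment start, fragment end, strand of origin).  No
#' error-tolerant barcode matching is attempted.
#'
#' @param reads the `reads` table of a `read_set`
#' @return the table with a `family_id` column and deterministic ordering
#' @export
group_families <- function(reads) {
  reads <- copy(reads)
  setorder(reads, sample_id, chrom, start, end, bc_w, bc_c, strand, read_id)
  reads[, family_id := .GRP,
        by = .(sample_id, bc_w, bc_c, chrom, start, end, strand)]
  reads[]
}

#' Per-strand consensus of aligned family sequences (reference rule)
#'
#' Definitional form of the voting rule used by the pipeline, for small
#' explicit families: at each position the base carried by at least
#' `max(1, ceiling(q * size))` unmasked members is called; otherwise the
#' position is masked (`NA`).  Singleton families pass their base through
#' (flagged low-confidence by the caller).
#'
#' @param seqs character vector of equal-length member sequences
#' @param quals optional integer matrix/list of per-base qualities; bases
#'   below `min_base_quality` do not vote
#' @param q supermajority fraction (default 0.75)
#' @param min_base_quality Phred threshold
#' @return character vector of consensus bases, `NA` where masked
#' @export
strand_consensus <- function(seqs, quals = NULL, q = 0.75,
                             min_base_quality = 20L) {
  if (!length(seqs)) stop("empty family")
  n <- length(seqs)
  L <- nchar(seqs[1])
  if (any(nchar(seqs) != L)) stop("family members must share length")
  needed <- max(1L, ceiling(q * n))
  mat <- do.call(rbind, strsplit(seqs, ""))
  if (!is.null(quals)) {
    qm <- if (is.list(quals)) do.call(rbind, quals) else quals
    mat[qm < min_base_quality] <- NA_character_
  }
  vapply(seq_len(L), function(j) {
    tb <- table(mat[, j], useNA = "no")
    if (!length(tb)) return(NA_character_)
    w <- which(tb >= needed)
    if (!length(w)) NA_character_ else names(tb)[w[which.max(tb[w])]]
  }, character(1))
}

#' Pair two strand consensi into duplex statuses (reference rule)
#'
#' @param watson,crick character vectors of per-position strand consensus
#'   calls (`NA` = masked); pass `NULL` for an unrecovered strand
#' @return data.table with `base` and `status` per position
#' @export
pair_duplex <- function(watson, crick) {
  if (is.null(watson) && is.null(crick)) stop("no strand recovered")
  if (is.null(watson) || is.null(crick)) {
    one <- if (is.null(watson)) crick else watson
    return(data.table(
      base = one,
      status = ifelse(is.na(one), "masked_no_call", "single_strand_only")))
  }
  if (length(watson) != length(crick))
    stop("strand consensi must share length")
  status <- rep("duplex_confirmed", length(watson))
  base <- watson
  both_na <- is.na(watson) & is.na(crick)
  one_na <- xor(is.na(watson), is.na(crick))
  disc <- !is.na(watson) & !is.na(crick) & watson != crick
  status[both_na] <- "masked_no_call"
  status[one_na] <- "single_strand_only"
  base[one_na] <- ifelse(is.na(watson[one_na]), crick[one_na], watson[one_na])
  status[disc] <- "discordant_no_call"
  base[disc] <- NA_character_
  base[both_na] <- NA_character_
  data.table(base = base, status = status)
}

#' Reconstruct unique consensus molecules from barcoded reads
#'
#' The digitization pipeline: quality filtering, family grouping by the
#' composite barcode/coordinate key, per-strand supermajority consensus,
#' and duplex comparison of the two strands of each molecule.  Positions
#' where a molecule's consensus equals the panel reference on both
#' strands are left implicit; the returned `calls` table materializes
#' only non-reference calls and no-call positions, with statuses
#' `duplex_confirmed`, `single_strand_only`, `discordant_no_call` or
#' `masked_no_call`.
#'
#' @param rs a `read_set`
#' @param panel the `ref_panel`
#' @param q supermajority fraction for strand consensus (default 0.75)
#' @param min_base_quality Phred threshold for voting (default Q20)
#' @param max_masked_frac per-read masked-fraction drop threshold
#' @return list of class `consensus_set` with `molecules` (one row per
#'   reconstructed unique molecule, with per-strand family sizes) and
#'   `calls` (sparse per-position non-reference/no-call table)
#' @export
consensus_molecules <- function(rs, panel, q = 0.75,
                                min_base_quality = 20L,
                                max_masked_frac = 0.5) {
  fr <- filter_reads(rs, min_base_quality, max_masked_frac)
  reads <- group_families(fr$reads)
  if (nrow(reads) == 0L)
    return(structure(list(
      molecules = data.table(), calls = data.table()),
      class = "consensus_set"))
  fams <- reads[, .(fam_size = .N), by = .(family_id, sample_id, bc_w, bc_c,
                                           chrom, gene, start, end, strand)]

  # --- per-strand sparse consensus -------------------------------------
  bj <- fr$bases[reads[, .(read_id, family_id)], on = "read_id",
                 nomatch = NULL]
  strand_calls <- if (nrow(bj)) {
    nrows <- bj[, .(n_rows = .N), by = .(family_id, pos)]
    cnt <- bj[masked == FALSE, .N, by = .(family_id, pos, base)]
    vt <- fams[, .(family_id, chrom, fam_size)][nrows, on = "family_id"]
    vt[, ref := ref_base_at(panel, chrom, pos)]
    vt[, needed := pmax(1L, as.integer(ceiling(q * fam_size)))]
    ref_cnt <- cnt[vt, on = c("family_id", "pos"),
                   nomatch = NULL][base == ref, .(family_id, pos, N)]
    vt[, ref_votes := fam_size - n_rows]
    vt[ref_cnt, on = c("family_id", "pos"), ref_votes := ref_votes + N]
    alt_best <- cnt[vt[, .(family_id, pos, ref)], on = c("family_id", "pos"),
                    nomatch = NULL][base != ref]
    alt_best <- alt_best[order(family_id, pos, -N, base)][
      , .SD[1L], by = .(family_id, pos)]
    vt[alt_best, on = c("family_id", "pos"),
       `:=`(alt_base = i.base, alt_votes = i.N)]
    vt[is.na(alt_votes), alt_votes := 0L]
    # winner: alt if it reaches the supermajority, else ref, else mask
    vt[, base := fifelse(alt_votes >= needed, alt_base,
                 fifelse(ref_votes >= needed, ref, NA_character_))]
    # materialize only non-ref calls and masks
    vt[is.na(base) | base != ref, .(family_id, pos, base)]
  } else data.table(family_id = integer(0), pos = integer(0),
                    base = character(0))

  # --- duplex pairing ---------------------------------------------------
  key <- c("sample_id", "bc_w", "bc_c", "chrom", "start", "end")
  mols <- dcast(fams, sample_id + bc_w + bc_c + chrom + gene + start + end ~
                  strand, value.var = "fam_size", fill = 0L)
  for (cn in c("W", "C")) if (!cn %in% names(mols)) mols[, (cn) := 0L]
  setnames(mols, c("W", "C"), c("w_size", "c_size"))
  setorderv(mols, c("sample_id", "chrom", "start", "end", "bc_w", "bc_c"))
  mols[, cons_id := .I]
  mols[, single_strand := w_size == 0L | c_size == 0L]

  sc <- strand_calls[fams[, .(family_id, sample_id, bc_w, bc_c, chrom,
                              start, end, strand)],
                     on = "family_id", nomatch = NULL]
  sc <- sc[mols[, c(key, "cons_id"), with = FALSE], on = key, nomatch = NULL]
  if (nrow(sc) == 0L) {
    calls <- data.table(cons_id = integer(0), sample_id = character(0),
                        pos = integer(0), base = character(0),
                        status = character(0))
    return(structure(list(molecules = mols[], calls = calls),
                     class = "consensus_set"))
  }
  wide <- dcast(sc, cons_id + pos ~ strand, value.var = "base",
                fun.aggregate = function(x) x[1L])
  for (cn in c("W", "C")) if (!cn %in% names(wide)) wide[, (cn) := NA_character_]
  # distinguish "strand called ref implicitly" from "strand masked":
  # a missing row on a present strand means that strand called reference
  wide <- wide[mols[, .(cons_id, w_size, c_size, chrom)], on = "cons_id",
               nomatch = NULL]
  wide[, ref := ref_base_at(panel, chrom, pos)]
  calls <- .pair_duplex_sparse(wide, sc)
  calls <- calls[mols[, .(cons_id, sample_id)], on = "cons_id", nomatch = NULL]
  setcolorder(calls, c("cons_id", "sample_id", "pos", "base", "status"))
  structure(list(molecules = mols[], calls = calls[]),
            class = "consensus_set")
}

# internal: duplex-pair the sparse strand calls.
# `wide` has one row per (cons_id, pos) with columns W, C (strand call:
# base, or NA meaning EITHER implicit reference OR mask) plus w_size,
# c_size, ref; `sc` still knows which (cons_id, pos, strand) rows were
# materialized (mask rows have base NA, non-ref rows have a base).
.pair_duplex_sparse <- function(wide, sc) {
  mk <- sc[is.na(base)]
  wide[, w_masked := FALSE]
  wide[, c_masked := FALSE]
  if (nrow(mk)) {
    wide[mk[strand == "W"], on = c("cons_id", "pos"), w_masked := TRUE]
    wide[mk[strand == "C"], on = c("cons_id", "pos"), c_masked := TRUE]
  }
  # effective per-strand call: base, "ref" (implicit), or NA (mask/absent)
  wide[, w_eff := fifelse(w_size == 0L | w_masked, NA_character_,
                  fifelse(is.na(W), ref, W))]
  wide[, c_eff := fifelse(c_size == 0L | c_masked, NA_character_,
                  fifelse(is.na(C), ref, C))]
  wide[, status := fifelse(
    !is.na(w_eff) & !is.na(c_eff) & w_eff == c_eff, "duplex_confirmed",
    fifelse(!is.na(w_eff) & !is.na(c_eff), "discordant_no_call",
    fifelse(is.na(w_eff) & is.na(c_eff), "masked_no_call",
            "single_strand_only")))]
  wide[, base := fifelse(status == "duplex_confirmed", w_eff,
                 fifelse(status == "single_strand_only",
                         fifelse(is.na(w_eff), c_eff, w_eff),
                         NA_character_))]
  # drop rows that resolved to a duplex-confirmed reference call (implicit)
  wide[!(status == "duplex_confirmed" & base == ref) &
         !(status == "single_strand_only" & base == ref),
       .(cons_id, pos, base, status)]
}

#' Per-position unique-molecule tallies
#'
#' Counts, for every targeted panel position, the unique molecules
#' covering it (denominator excludes molecules with a no-call at that
#' position) and the non-reference base calls by duplex status.
#'
#' @param cons a `consensus_set`
#' @param panel the `ref_panel`
#' @return list of class `pileup_set` with `depth` (per sample x panel
#'   position unique-molecule depth) and `alts` (per sample x site x alt
#'   base: duplex-confirmed and single-strand-only molecule counts)
#' @export
pileup <- function(cons, panel) {
  mols <- cons$molecules
  if (is.null(mols) || nrow(mols) == 0L)
    return(structure(list(depth = data.table(), alts = data.table()),
                     class = "pileup_set"))
  reg <- panel$regions
  depth_list <- list()
  for (i in seq_len(nrow(reg))) {
    L <- reg$end[i] - reg$start[i]
    ov <- mols[chrom == reg$chrom[i] & start < reg$end[i] & end > reg$start[i]]
    if (nrow(ov) == 0L) next
    ov[, `:=`(cs = pmax(start, reg$start[i]) - reg$start[i],
              ce = pmin(end, reg$end[i]) - reg$start[i])]
    dl <- ov[, {
      inc <- tabulate(cs + 1L, nbins = L)
      dec <- tabulate(ce + 1L, nbins = L + 1L)[seq_len(L)]
      .(pos = reg$start[i] + seq_len(L) - 1L, depth = cumsum(inc - dec))
    }, by = sample_id]
    dl[, chrom := reg$chrom[i]]
    depth_list[[length(depth_list) + 1L]] <- dl
  }
  depth <- rbindlist(depth_list)
  # positions covered by no molecule still appear, at depth 0
  pp <- panel_positions(panel)[, .(chrom, pos)]
  full <- CJ(sample_id = unique(mols$sample_id), k = seq_len(nrow(pp)))
  full <- cbind(full[, .(sample_id)], pp[full$k])
  depth <- depth[full, on = c("sample_id", "chrom", "pos")]
  depth[is.na(depth), depth := 0L]
  calls <- cons$calls
  if (nrow(calls)) {
    cj <- calls[mols[, .(cons_id, chrom)], on = "cons_id", nomatch = NULL]
    nocall <- cj[status %in% c("discordant_no_call", "masked_no_call"),
                 .(nocall = .N), by = .(sample_id, chrom, pos)]
    if (nrow(nocall)) {
      depth[nocall, on = c("sample_id", "chrom", "pos"),
            depth := depth - i.nocall]
    }
    alts <- cj[status %in% c("duplex_confirmed", "single_strand_only") &
                 !is.na(base),
               .(n_duplex = sum(status == "duplex_confirmed"),
                 n_single = sum(status == "single_strand_only")),
               by = .(sample_id, chrom, pos, base)]
    setnames(alts, "base", "alt")
    alts[, ref := ref_base_at(panel, chrom, pos)]
    alts <- alts[alt != ref]
    alts <- depth[alts, on = c("sample_id", "chrom", "pos"), nomatch = NULL]
    setcolorder(alts, c("sample_id", "chrom", "pos", "ref", "alt",
                        "n_duplex", "n_single", "depth"))
  } else {
    alts <- data.table(sample_id = character(0), chrom = character(0),
                       pos = integer(0), ref = character(0),
                       alt = character(0), n_duplex = integer(0),
                       n_single = integer(0), depth = integer(0))
  }
  setorderv(depth, c("sample_id", "chrom", "pos"))
  setorderv(alts, c("sample_id", "chrom", "pos", "alt"))
  structure(list(depth = depth[], alts = alts[]), class = "pileup_set")
}

#' Split a multi-sample pileup into per-sample pileups
#'
#' Batched simulation runs carry several samples through digitization at
#' once; baseline training and per-sample calling want one `pileup_set`
#' per sample.
#'
#' @param ps a `pileup_set`
#' @return named list of single-sample `pileup_set` objects
#' @export
split_pileup <- function(ps) {
  ids <- unique(ps$depth$sample_id)
  setNames(lapply(ids, function(s) {
    structure(list(depth = ps$depth[sample_id == s],
                   alts = ps$alts[sample_id == s]),
              class = "pileup_set")
  }), ids)
}
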