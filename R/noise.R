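#' Train per-base noise baselines from a normal cohort
#'
#' For every (panel position, alternate base) pair, the duplex-confirmed
#' minor-base fraction observed in each normal sample is accumulated into
#' a mean and standard deviation — a separate noise model for each
#' targeted base.  Germline SNP sites are excluded from the contributing
#' sample only: any site whose observed fraction in a sample falls in the
#' heterozygous window or above the homozygous minimum is treated as a
#' germline variant of that donor, not as noise.  The per-site relative
#' detection threshold is `mean + k * sd`; at call time it is floored at
#' `floor_molecules / depth` (an absolute minimum of supporting
#' molecules).
#'
#' @param pileups list of `pileup_set` objects, one per normal sample
#'   (>= 2 samples)
#' @param panel the `ref_panel`
#' @param k number of standard deviations above the mean (default 10)
#' @param floor_molecules absolute molecule floor applied at call time
#' @param het_window,hom_min germline-exclusion windows on the observed
#'   fraction
#' @return list of class `noise_baseline` with a full `sites` grid
#'   (position x 3 alternate bases: mean, sd, n, relative threshold)
#' @export
train_baseline <- function(pileups, panel, k = 10, floor_molecules = 2L,
                           het_window = c(0.35, 0.65), hom_min = 0.85) {
  if (length(pileups) < 2L)
    stop("need at least 2 normal samples to train a baseline")
  pp <- panel_positions(panel)
  bases <- c("A", "C", "G", "T")
  grid <- pp[, .(alt = setdiff(bases, ref)), by = .(chrom, pos, ref)]
  n_tot <- length(pileups)
  grid[, `:=`(s1 = 0, s2 = 0, n_excl = 0L)]
  for (ps in pileups) {
    a <- ps$alts
    if (nrow(a) == 0L) next
    a <- a[depth > 0]
    a[, frac := n_duplex / depth]
    germ <- a[(frac >= het_window[1] & frac <= het_window[2]) |
                frac >= hom_min]
    contrib <- a[!germ, on = c("sample_id", "chrom", "pos", "alt")]
    grid[contrib, on = c("chrom", "pos", "alt"),
         `:=`(s1 = s1 + i.frac, s2 = s2 + i.frac^2)]
    if (nrow(germ))
      grid[germ, on = c("chrom", "pos", "alt"), n_excl := n_excl + 1L]
  }
  grid[, n_samples := n_tot - n_excl]
  grid[, mean_frac := fifelse(n_samples > 0L, s1 / pmax(n_samples, 1L), 0)]
  grid[, sd_frac := fifelse(
    n_samples > 1L,
    sqrt(pmax(s2 - pmax(n_samples, 1L) * mean_frac^2, 0) /
           pmax(n_samples - 1L, 1L)),
    0)]
  grid[, thr_rel := mean_frac + k * sd_frac]
  grid[, c("s1", "s2", "n_excl") := NULL]
  structure(list(sites = grid[], k = k, floor_molecules = floor_molecules,
                 n_samples = n_tot),
            class = "noise_baseline")
}

#' Site- and alternate-base-specific detection threshold
#'
#' Returns `max(mean + k * sd, floor_molecules / depth)` for the site.
#' Without a `depth`, the relative component alone is returned.
#'
#' @param baseline a `noise_baseline`
#' @param chrom,pos,alt site and alternate base (vectorized)
#' @param depth optional local unique-molecule depth for the absolute
#'   molecule floor
#' @return numeric vector of fraction thresholds
#' @export
threshold_for <- function(baseline, chrom, pos, alt, depth = NULL) {
  q <- data.table(chrom = chrom, pos = as.integer(pos), alt = alt)
  hit <- baseline$sites[q, on = c("chrom", "pos", "alt")]
  if (anyNA(hit$thr_rel))
    stop("untrained site: ",
         paste(sprintf("%s:%d>%s", q$chrom[is.na(hit$thr_rel)],
                       q$pos[is.na(hit$thr_rel)],
                       q$alt[is.na(hit$thr_rel)]), collapse = ", "))
  thr <- hit$thr_rel
  if (!is.null(depth)) thr <- pmax(thr, baseline$floor_molecules / depth)
  thr
}

#' Persist / load a noise baseline as TSV
#'
#' @param baseline a `noise_baseline`
#' @param path TSV path
#' @return `read_baseline`: the `noise_baseline`
#' @export
write_baseline <- function(baseline, path) {
  hdr <- sprintf("# cfduplex noise_baseline k=%g floor_molecules=%d n_samples=%d",
                 baseline$k, baseline$floor_molecules, baseline$n_samples)
  writeLines(hdr, path)
  fwrite(baseline$sites[, .(chrom, pos, ref, alt, mean_frac, sd_frac,
                            n_samples, thr_rel)],
         path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[0-9.e+-]+", hdr))[[1]]
  kv <- setNames(as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  sites <- fread(path, skip = 1L, sep = "\t")
  structure(list(sites = sites, k = unname(kv["k"]),
                 floor_molecules = as.integer(kv["floor_molecules"]),
                 n_samples = as.integer(kv["n_samples"])),
            class = "noise_baseline")
}
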