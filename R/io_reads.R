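#' Heptamer barcode encoding
#'
#' Strand barcodes are non-unique 7-mers over {A,C,G,T} (4^7 = 16,384
#' possibilities), stored internally as integers 1..16384.
#'
#' @param code integer codes in 1..16384
#' @return `bc_to_heptamer`: character 7-mers; `heptamer_to_bc`: codes
#' @export
bc_to_heptamer <- function(code) {
  if (any(code < 1L | code > 16384L)) stop("barcode code out of range")
  x <- code - 1L
  bases <- c("A", "C", "G", "T")
  out <- character(length(x))
  for (i in 7:1) {
    out <- paste0(bases[x %% 4L + 1L], out)
    x <- x %/% 4L
  }
  out
}

#' @rdname bc_to_heptamer
#' @param heptamer character 7-mers
#' @export
heptamer_to_bc <- function(heptamer) {
  if (any(nchar(heptamer) != 7L)) stop("barcodes must be 7-mers")
  m <- match(do.call(rbind, strsplit(heptamer, "")), c("A", "C", "G", "T"))
  if (anyNA(m)) stop("barcodes must be over A/C/G/T")
  m <- matrix(m - 1L, ncol = 7L)
  as.integer(m %*% 4L^(6:0)) + 1L
}

#' Write / read an aligned-read table (TSV dialect)
#'
#' One row per read; the sparse non-reference / low-quality bases are
#' packed into a `bases` column as `pos:base:qual` triples joined by
#' `|` (`.` when the read matches the reference at full quality).
#' Round-trips losslessly.
#'
#' @param rs a `read_set`
#' @param path TSV path
#' @return `read_reads_tsv`: a `read_set` (without ground truth)
#' @export
write_reads_tsv <- function(rs, path) {
  r <- copy(rs$reads)
  if (nrow(rs$bases)) {
    packed <- rs$bases[, .(packed = paste(sprintf("%d:%s:%d", pos, base, qual),
                                          collapse = "|")), by = read_id]
    r[packed, on = "read_id", bases := i.packed]
  }
  if (!"bases" %in% names(r)) r[, bases := NA_character_]
  r[is.na(bases), bases := "."]
  r[, `:=`(bc_w = bc_to_heptamer(bc_w), bc_c = bc_to_heptamer(bc_c))]
  fwrite(r, path, sep = "\t")
  invisible(path)
}

#' @rdname write_reads_tsv
#' @export
read_reads_tsv <- function(path) {
  r <- fread(path, sep = "\t")
  r[, `:=`(bc_w = heptamer_to_bc(bc_w), bc_c = heptamer_to_bc(bc_c))]
  has <- r[bases != "."]
  bases <- if (nrow(has)) {
    b <- has[, {
      parts <- strsplit(unlist(strsplit(bases, "|", fixed = TRUE)), ":")
      .(pos = as.integer(vapply(parts, `[`, "", 1L)),
        base = vapply(parts, `[`, "", 2L),
        qual = as.integer(vapply(parts, `[`, "", 3L)))
    }, by = read_id]
    b
  } else data.table(read_id = integer(0), pos = integer(0),
                    base = character(0), qual = integer(0))
  r[, bases := NULL]
  structure(list(reads = r, bases = bases, truth = NULL),
            class = "read_set")
}

#' Materialize full read sequences and qualities
#'
#' Expands the sparse read representation against the panel reference:
#' each read's sequence is the reference over [start, end) with its
#' recorded deviations applied, qualities Q30 except recorded rows.
#'
#' @param rs a `read_set`
#' @param panel the `ref_panel`
#' @return data.table: read_id, seq, qual (Phred+33 string)
#' @export
materialize_read_seqs <- function(rs, panel) {
  r <- rs$reads
  out <- vector("list", nrow(r))
  bx <- if (nrow(rs$bases)) split(rs$bases, by = "read_id", keep.by = TRUE)
        else list()
  for (i in seq_len(nrow(r))) {
    L <- r$end[i] - r$start[i]
    pos <- r$start[i]:(r$end[i] - 1L)
    s <- ref_base_at(panel, rep(r$chrom[i], L), pos)
    q <- rep(30L, L)
    b <- bx[[as.character(r$read_id[i])]]
    if (!is.null(b)) {
      idx <- b$pos - r$start[i] + 1L
      ok <- idx >= 1L & idx <= L
      s[idx[ok]] <- b$base[ok]
      q[idx[ok]] <- b$qual[ok]
    }
    out[[i]] <- list(seq = paste(s, collapse = ""),
                     qual = intToUtf8(q + 33L))
  }
  data.table(read_id = r$read_id,
             seq = vapply(out, `[[`, "", "seq"),
             qual = vapply(out, `[[`, "", "qual"))
}

#' Write / read annotated FASTQ
#'
#' FASTQ dialect: the read name encodes the molecular annotations as
#' `sample|watson-barcode|crick-barcode|chrom|start|end|strand|readid`
#' (coordinates 0-based half-open).  `read_reads_fastq` recovers the
#' sparse representation by diffing each sequence against the panel
#' reference; positions whose reference is `N` are not recoverable and
#' are skipped.
#'
#' @param rs a `read_set`
#' @param panel the `ref_panel`
#' @param path FASTQ path
#' @return `read_reads_fastq`: a `read_set`
#' @export
write_reads_fastq <- function(rs, panel, path) {
  mat <- materialize_read_seqs(rs, panel)
  r <- rs$reads
  name <- sprintf("%s|%s|%s|%s|%d|%d|%s|%d", r$sample_id,
                  bc_to_heptamer(r$bc_w), bc_to_heptamer(r$bc_c),
                  r$chrom, r$start, r$end, r$strand, r$read_id)
  lines <- character(4L * nrow(r))
  lines[seq(1, length(lines), 4)] <- paste0("@", name)
  lines[seq(2, length(lines), 4)] <- mat$seq
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- mat$qual
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path, panel) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ")
  name <- sub("^@", "", lines[seq(1, length(lines), 4)])
  seqs <- lines[seq(2, length(lines), 4)]
  quals <- lines[seq(4, length(lines), 4)]
  f <- tstrsplit(name, "|", fixed = TRUE)
  reads <- data.table(
    sample_id = f[[1]], read_id = as.integer(f[[8]]),
    mol_id = NA_integer_,
    bc_w = heptamer_to_bc(f[[2]]), bc_c = heptamer_to_bc(f[[3]]),
    chrom = f[[4]], gene = NA_character_,
    start = as.integer(f[[5]]), end = as.integer(f[[6]]),
    strand = f[[7]])
  reads[, len := end - start]
  base_list <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    L <- reads$len[i]
    pos <- reads$start[i]:(reads$end[i] - 1L)
    refs <- ref_base_at(panel, rep(reads$chrom[i], L), pos)
    s <- strsplit(seqs[i], "")[[1]]
    q <- utf8ToInt(quals[i]) - 33L
    dev <- which((s != refs | q != 30L) & refs != "N")
    if (length(dev))
      base_list[[i]] <- data.table(read_id = reads$read_id[i],
                                   pos = pos[dev], base = s[dev],
                                   qual = q[dev])
  }
  bases <- rbindlist(base_list)
  if (nrow(bases) == 0L)
    bases <- data.table(read_id = integer(0), pos = integer(0),
                        base = character(0), qual = integer(0))
  structure(list(reads = reads, bases = bases, truth = NULL),
            class = "read_set")
}
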