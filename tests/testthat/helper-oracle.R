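# Independent brute-force implementations used as oracles.

# exhaustive consensus reconstruction: materializes every read, groups by
# definition, votes position by position with explicit loops, and pairs
# strands with explicit case analysis.  Returns sorted call rows in the
# same sparse convention as consensus_molecules() (non-reference and
# no-call positions only).
oracle_consensus <- function(rs, panel, q = 0.75, min_bq = 20L,
                             max_masked_frac = 0.5) {
  reads <- as.data.frame(rs$reads)
  basedf <- as.data.frame(rs$bases)
  seqs <- list()
  for (i in seq_len(nrow(reads))) {
    L <- reads$end[i] - reads$start[i]
    pos <- reads$start[i]:(reads$end[i] - 1L)
    s <- ref_base_at(panel, rep(reads$chrom[i], L), pos)
    qv <- rep(30L, L)
    b <- basedf[basedf$read_id == reads$read_id[i], , drop = FALSE]
    if (nrow(b)) {
      idx <- b$pos - reads$start[i] + 1L
      s[idx] <- b$base
      qv[idx] <- b$qual
    }
    m <- qv < min_bq
    s[m] <- NA_character_
    attr(s, "masked_frac") <- mean(m)
    seqs[[i]] <- s
  }
  keep <- vapply(seqs, function(s) attr(s, "masked_frac") <= max_masked_frac,
                 logical(1))
  reads <- reads[keep, , drop = FALSE]
  seqs <- seqs[keep]
  if (!nrow(reads))
    return(list(molecules = character(0), calls = data.frame()))
  mkey <- paste(reads$sample_id, reads$bc_w, reads$bc_c, reads$chrom,
                reads$start, reads$end, sep = "/")
  rows <- list()
  for (mk in unique(mkey)) {
    sel <- which(mkey == mk)
    r1 <- reads[sel[1], ]
    L <- r1$end - r1$start
    cons <- list(W = NULL, C = NULL)
    for (st in c("W", "C")) {
      fi <- sel[reads$strand[sel] == st]
      if (!length(fi)) next
      needed <- max(1L, ceiling(q * length(fi)))
      cc <- rep(NA_character_, L)
      for (j in seq_len(L)) {
        v <- vapply(fi, function(k) seqs[[k]][j], NA_character_)
        v <- v[!is.na(v)]
        if (!length(v)) next
        tb <- table(v)
        w <- which(tb >= needed)
        if (length(w)) cc[j] <- names(tb)[w[which.max(tb[w])]]
      }
      cons[[st]] <- cc
    }
    refv <- ref_base_at(panel, rep(r1$chrom, L), r1$start:(r1$end - 1L))
    for (j in seq_len(L)) {
      w <- if (is.null(cons$W)) NA_character_ else cons$W[j]
      cc <- if (is.null(cons$C)) NA_character_ else cons$C[j]
      status <- if (!is.na(w) && !is.na(cc)) {
        if (w == cc) "duplex_confirmed" else "discordant_no_call"
      } else if (is.na(w) && is.na(cc)) {
        "masked_no_call"
      } else "single_strand_only"
      base <- switch(status,
        duplex_confirmed = w,
        single_strand_only = if (is.na(w)) cc else w,
        NA_character_)
      # implicit positions: duplex/single-strand reference never
      # materializes; all-reference masked positions only materialize if a
      # strand voted (i.e. at least one strand had coverage and failed)
      materialize <- switch(status,
        duplex_confirmed = base != refv[j],
        single_strand_only = base != refv[j],
        discordant_no_call = TRUE,
        masked_no_call = !is.null(cons$W) || !is.null(cons$C))
      if (materialize)
        rows[[length(rows) + 1L]] <- data.frame(
          mol = mk, pos = r1$start + j - 1L, base = base, status = status,
          stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows)
           else data.frame(mol = character(0), pos = integer(0),
                           base = character(0), status = character(0))
  calls <- calls[order(calls$mol, calls$pos, calls$status), , drop = FALSE]
  rownames(calls) <- NULL
  list(molecules = sort(unique(mkey)), calls = calls)
}

# package consensus_set rendered in the oracle's comparison convention
pipeline_calls_for_oracle <- function(cons) {
  m <- as.data.frame(cons$molecules)
  mkey <- paste(m$sample_id, m$bc_w, m$bc_c, m$chrom, m$start, m$end,
                sep = "/")
  cl <- as.data.frame(cons$calls)
  cl$mol <- mkey[match(cl$cons_id, m$cons_id)]
  cl <- cl[, c("mol", "pos", "base", "status")]
  cl <- cl[order(cl$mol, cl$pos, cl$status), , drop = FALSE]
  rownames(cl) <- NULL
  list(molecules = sort(unique(mkey)), calls = cl)
}

# Clopper-Pearson by direct numeric inversion of the binomial tails
oracle_clopper_pearson <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  lower <- if (x == 0) 0 else
    uniroot(function(p) pbinom(x - 1, n, p, lower.tail = FALSE) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (x == n) 1 else
    uniroot(function(p) pbinom(x, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower = lower, upper = upper)
}
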