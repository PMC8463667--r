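# Independent oracles and small fixtures shared across tests.

# Brute-force pileup: per-read, per-base tally written as plain loops,
# independent of build_pileup's vectorized path. Applies the same rules:
# mapq/baseq/flag filters and one count per fragment (higher quality wins).
brute_force_pileup <- function(aln, positions, min_baseq = 20L,
                               min_mapq = 20L) {
  rd <- aln$reads
  seg <- aln$segments
  bases <- c("A", "C", "G", "T")
  qual_recycled <- length(rd$qual) == 1L
  res <- data.frame(position = as.integer(positions),
                    A = 0L, C = 0L, G = 0L, T = 0L,
                    depth = 0L, mean_baseq = NA_real_)
  for (k in seq_along(positions)) {
    p <- positions[k]
    seen <- list()   # qname -> c(base, qual)
    for (j in seq_len(nrow(seg))) {
      if (seg$ref_start[j] > p || seg$ref_end[j] < p) next
      r <- seg$read[j]
      if (bitwAnd(rd$flag[r], 256L + 1024L + 4L) != 0L) next
      if (rd$mapq[r] < min_mapq) next
      i <- seg$offset[j] + (p - seg$ref_start[j]) + 1L
      b <- substr(rd$seq[r], i, i)
      qs <- if (qual_recycled) rd$qual[1L] else rd$qual[r]
      q <- utf8ToInt(substr(qs, i, i)) - 33L
      if (q < min_baseq || !(b %in% bases)) next
      qn <- rd$qname[r]
      prev <- seen[[qn]]
      if (is.null(prev) || q > prev[[2L]]) seen[[qn]] <- list(b, q)
    }
    if (length(seen)) {
      bs <- vapply(seen, `[[`, "", 1L)
      qs <- vapply(seen, function(x) as.numeric(x[[2L]]), 0)
      for (b in bs) res[k, b] <- res[k, b] + 1L
      res$depth[k] <- length(bs)
      res$mean_baseq[k] <- mean(qs)
    }
  }
  res
}

# string-diff oracle: positions where two equal-length sequences differ
seq_diff_positions <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  which(av != bv)
}

# small haplotype fixture used by several files
small_pair <- function(len = 2000L, n_snps = 10L, deletion = NULL,
                       seed = 9L) {
  derive_haplotypes(make_reference(len, seed = 2L), n_snps = n_snps,
                    deletion = deletion, seed = seed)
}
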