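#' Pileup base counts at selected positions
#'
#' Counts A/C/G/T bases covering each requested 1-based reference position,
#' applying the filters a variant-frequency pipeline needs: bases below
#' `min_baseq` and records below `min_mapq` are excluded, as are records
#' flagged secondary, duplicate or unmapped. When the two mates of a
#' fragment (or two alignment records of one read) cover the same position,
#' the fragment is counted once and the higher-quality base wins, so
#' duplicated evidence from overlapping mates is never double-counted.
#' Alignments spanning the circular origin contribute at their wrapped
#' coordinates.
#'
#' @param alignments A `read_sim` object from [simulate_reads()], a
#'   `mito_alignments` object from [read_alignments()], or a SAM/BAM path.
#' @param genome The [circular_genome] reference (used for header checks
#'   when `alignments` is a file path).
#' @param positions Integer vector of 1-based positions to pile up.
#' @param min_baseq Minimum base quality counted (default 20).
#' @param min_mapq Minimum mapping quality counted (default 20).
#' @return A data.frame of class `pileup` with one row per requested
#'   position: `position`, counts `A`, `C`, `G`, `T`, `depth` (sum of the
#'   four counts) and `mean_baseq`.
#' @export
build_pileup <- function(alignments, genome = NULL, positions,
                         min_baseq = 20L, min_mapq = 20L) {
  if (is.character(alignments)) {
    if (is.null(genome))
      stop("genome is required when alignments is a file path")
    alignments <- read_alignments(alignments, genome)
  }
  stopifnot(is.list(alignments), !is.null(alignments$reads),
            !is.null(alignments$segments))
  if (!is.null(genome) && inherits(genome, "circular_genome") &&
      alignments$genome_length != genome$length)
    stop("reference mismatch: alignments are over a ",
         alignments$genome_length, " bp genome, not ", genome$length)

  rd <- alignments$reads
  seg <- alignments$segments
  # record-level filters applied once
  drop_flags <- bitwAnd(rd$flag, 256L + 1024L + 4L) != 0L
  rec_ok <- !drop_flags & rd$mapq >= min_mapq
  keep <- rec_ok[seg$read]
  s_read <- seg$read[keep]
  s_start <- seg$ref_start[keep]
  s_end <- seg$ref_end[keep]
  s_off <- seg$offset[keep]
  qual_recycled <- length(rd$qual) == 1L

  positions <- as.integer(positions)
  bases <- c("A", "C", "G", "T")
  out <- matrix(0L, nrow = length(positions), ncol = 4L,
                dimnames = list(NULL, bases))
  mean_bq <- numeric(length(positions))
  for (k in seq_along(positions)) {
    p <- positions[k]
    hit <- which(s_start <= p & s_end >= p)
    if (length(hit) == 0L) { mean_bq[k] <- NA_real_; next }
    r <- s_read[hit]
    i <- s_off[hit] + (p - s_start[hit]) + 1L
    b <- substr(rd$seq[r], i, i)
    qsrc <- if (qual_recycled) rep.int(1L, length(r)) else r
    qch <- substr(rd$qual[qsrc], i, i)
    q <- utf8ToInt(paste(qch, collapse = "")) - 33L
    ok <- q >= min_baseq & b %in% bases
    if (!any(ok)) { mean_bq[k] <- NA_real_; next }
    r <- r[ok]; b <- b[ok]; q <- q[ok]
    # one count per fragment: keep the higher-quality base per QNAME
    qn <- rd$qname[r]
    o <- order(qn, -q)
    first <- !duplicated(qn[o])
    b <- b[o][first]; q <- q[o][first]
    out[k, ] <- tabulate(match(b, bases), nbins = 4L)
    mean_bq[k] <- mean(q)
  }
  res <- data.frame(position = positions, out,
                    depth = as.integer(rowSums(out)),
                    mean_baseq = mean_bq)
  class(res) <- c("pileup", "data.frame")
  res
}
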