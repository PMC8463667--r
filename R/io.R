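## Writers for simulated read sets (FASTQ / SAM / truth TSV) and a reader
## that normalizes external SAM/BAM alignments into the internal segment
## representation consumed by build_pileup().

#' Write a simulated read set to FASTQ, SAM and truth TSV
#'
#' Produces `<prefix>_R1.fastq` / `<prefix>_R2.fastq` (read sequences in
#' sequencing orientation), `<prefix>.sam` (truth alignments, `@SQ` header
#' with the genome name and length; origin-spanning reads as two records,
#' the second flagged supplementary with hard clips) and
#' `<prefix>_truth.tsv` (one row per read: `read_id`, `origin`, `start`,
#' `strand`).
#'
#' @param sim A `read_sim` object from [simulate_reads()].
#' @param pair The [haplotype_pair] the reads were simulated from.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_read_sim <- function(sim, pair, prefix) {
  rl <- sim$config$read_length
  rd <- sim$reads
  n_pairs <- sim$n_pairs
  n_reads <- 2L * n_pairs

  ## FASTQ (mate 1 / mate 2 files, reverse-strand reads reverse-complemented)
  fq_seq <- rd$seq
  rev_i <- rd$strand == "-"
  fq_seq[rev_i] <- rc_strings(fq_seq[rev_i])
  qual <- strrep("?", rl)
  for (m in 1:2) {
    sel <- which(rd$mate == m)
    sel <- sel[order(rd$qname[sel])]
    lines <- as.vector(rbind(paste0("@", rd$qname[sel], "/", m),
                             fq_seq[sel], "+", qual))
    writeLines(lines, sprintf("%s_R%d.fastq", prefix, m))
  }

  ## SAM: one record per molecule piece (origin wrap splits records)
  seg <- sim$segments
  key <- paste(seg$read, seg$piece)
  first <- !duplicated(key)
  rec <- data.frame(read = seg$read[first], piece = seg$piece[first],
                    pos = seg$ref_start[first], off = seg$offset[first])
  seg_len <- seg$ref_end - seg$ref_start + 1L
  rec$len <- as.integer(tapply(seg_len, factor(key, levels = key[first]),
                               sum))
  # CIGAR: hard clips around the aligned piece; a deletion gap where the
  # piece maps across the deletion junction
  n2 <- as.integer(table(factor(key, levels = key[first])))
  cig_core <- character(nrow(rec))
  one <- n2 == 1L
  cig_core[one] <- paste0(rec$len[one], "M")
  if (any(!one)) {
    second <- duplicated(key)
    len1 <- seg_len[first][!one]
    i2 <- match(key[first][!one], key[second])
    rs2 <- seg$ref_start[second]; re2 <- seg$ref_end[second]
    rs1e <- seg$ref_end[first][!one]
    cig_core[!one] <- paste0(len1, "M", rs2[i2] - rs1e[i2] - 1L, "D",
                             re2[i2] - rs2[i2] + 1L, "M")
  }
  pre <- ifelse(rec$off > 0L, paste0(rec$off, "H"), "")
  post_len <- rl - rec$off - rec$len
  post <- ifelse(post_len > 0L, paste0(post_len, "H"), "")
  cigar <- paste0(pre, cig_core, post)

  flag <- rd$flag[rec$read] + ifelse(rec$piece > 1L, 2048L, 0L)
  mate_read <- ifelse(rec$read <= n_pairs, rec$read + n_pairs,
                      rec$read - n_pairs)
  pnext <- rd$start[mate_read]
  seqs <- substr(rd$seq[rec$read], rec$off + 1L, rec$off + rec$len)
  quals <- strrep("?", rec$len)

  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", sim$genome_name,
                      sim$genome_length))
  body <- paste(rd$qname[rec$read], flag, sim$genome_name, rec$pos,
                rd$mapq[rec$read], cigar, "=", pnext, 0L, seqs, quals,
                sep = "\t")
  writeLines(c(header, body), paste0(prefix, ".sam"))

  utils::write.table(sim$truth, paste0(prefix, "_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read aligned reads from SAM/BAM into pileup-ready form
#'
#' Loads a SAM or BAM file (SAM is converted via [Rsamtools::asBam()]) and
#' walks each record's CIGAR into reference-space aligned segments, the
#' representation [build_pileup()] consumes. The header's reference length
#' must match `genome`.
#'
#' @param path SAM or BAM file path.
#' @param genome The [circular_genome] the reads were aligned to.
#' @return An object of class `mito_alignments` (fields `reads`,
#'   `segments`, `genome_name`, `genome_length`).
#' @export
read_alignments <- function(path, genome) {
  stopifnot(inherits(genome, "circular_genome"))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (length(hdr) != 1L || unname(hdr[1L]) != genome$length)
    stop("reference mismatch: alignment header length ",
         paste(hdr, collapse = ","), " does not match genome length ",
         genome$length)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual"))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  keep <- !is.na(b$pos)
  reads <- list(qname = b$qname[keep],
                seq = as.character(b$seq[keep]),
                qual = as.character(b$qual[keep]),
                mapq = as.integer(b$mapq[keep]),
                flag = as.integer(b$flag[keep]))
  reads$mapq[is.na(reads$mapq)] <- 0L
  segs <- cigar_segments(b$cigar[keep], b$pos[keep])
  structure(list(reads = reads, segments = segs,
                 genome_name = genome$name, genome_length = genome$length),
            class = "mito_alignments")
}

# walk CIGARs into (read, ref_start, ref_end, offset) aligned segments;
# offset is 0-based into the record's stored SEQ
cigar_segments <- function(cigar, pos) {
  parsed <- parse_cigar(cigar)
  out_read <- integer(0); out_rs <- integer(0)
  out_re <- integer(0); out_off <- integer(0)
  for (i in seq_along(parsed)) {
    ref <- pos[i]; off <- 0L
    ops <- parsed[[i]]
    for (j in seq_along(ops$op)) {
      op <- ops$op[j]; len <- ops$len[j]
      if (op %in% c("M", "=", "X")) {
        out_read <- c(out_read, i); out_rs <- c(out_rs, ref)
        out_re <- c(out_re, ref + len - 1L); out_off <- c(out_off, off)
        ref <- ref + len; off <- off + len
      } else if (op %in% c("I", "S")) {
        off <- off + len
      } else if (op %in% c("D", "N")) {
        ref <- ref + len
      }                                        # H, P consume nothing stored
    }
  }
  data.frame(read = out_read, ref_start = out_rs, ref_end = out_re,
             offset = out_off, piece = 1L)
}
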