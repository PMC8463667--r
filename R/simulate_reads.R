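#' Configuration for paired-end mtDNA read simulation
#'
#' Describes a sequencing experiment over a donor/recipient mtDNA mixture:
#' target per-site depth, paired read length, substitution error rate, the
#' amplification mode (near-uniform rolling-circle amplification, or
#' two-amplicon long-range PCR with restricted placement and a configurable
#' per-amplicon depth imbalance), and the true donor molecule fraction.
#'
#' `mixture_fraction` and the recipient deletion's heteroplasmy are
#' molecule-level fractions. Fragments are emitted in proportion to
#' molecule mass (molecule fraction times molecule length), as mass-based
#' sequencing does, so per-molecule per-site depth is equal across molecule
#' species and the donor-allele frequency at sites outside any deletion
#' equals `mixture_fraction`.
#'
#' @param coverage Target mean depth at retained (non-deleted) sites
#'   (default 2500).
#' @param read_length Read length in bases for each mate (default 150).
#' @param error_rate Per-base substitution error probability (default
#'   0.001; must be < 0.25).
#' @param amplification_mode `"rca_uniform"` or `"pcr_two_amplicon"`.
#' @param amplicon_intervals List of two `c(start, end)` reference
#'   intervals (1-based, inclusive; `start > end` wraps the origin) used in
#'   PCR mode. The defaults split the circle into two overlapping halves;
#'   they are placeholders for a long-range two-primer-set design, not real
#'   primer coordinates.
#' @param amplicon_ratio Depth of amplicon 2 relative to amplicon 1 in PCR
#'   mode (default 1, balanced).
#' @param insert_gap Unsequenced bases between mates; fragment length is
#'   `2 * read_length + insert_gap` (default 50, i.e. a 350 bp insert).
#' @param mixture_fraction Fraction in [0, 1] of mtDNA molecules that are
#'   donor-derived — the ground-truth percent exogenous mtDNA / 100.
#' @param seed Integer seed.
#' @return An object of class `read_sim_config`.
#' @export
read_sim_config <- function(coverage = 2500, read_length = 150L,
                            error_rate = 0.001,
                            amplification_mode = c("rca_uniform",
                                                   "pcr_two_amplicon"),
                            amplicon_intervals = NULL,
                            amplicon_ratio = 1,
                            insert_gap = 50L,
                            mixture_fraction = 0,
                            seed = 1L) {
  amplification_mode <- match.arg(amplification_mode)
  if (!is.finite(coverage) || coverage <= 0)
    stop("invalid parameter: coverage must be > 0")
  if (!is.finite(error_rate) || error_rate < 0 || error_rate >= 0.25)
    stop("invalid parameter: error_rate must lie in [0, 0.25)")
  if (!is.finite(mixture_fraction) || mixture_fraction < 0 ||
      mixture_fraction > 1)
    stop("invalid parameter: mixture_fraction must lie in [0, 1]")
  if (amplification_mode == "pcr_two_amplicon" &&
      !is.null(amplicon_intervals) && length(amplicon_intervals) != 2L)
    stop("configuration error: amplicon_intervals must list two intervals")
  structure(list(coverage = coverage,
                 read_length = as.integer(read_length),
                 error_rate = error_rate,
                 amplification_mode = amplification_mode,
                 amplicon_intervals = amplicon_intervals,
                 amplicon_ratio = amplicon_ratio,
                 insert_gap = as.integer(insert_gap),
                 mixture_fraction = mixture_fraction,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

default_amplicons <- function(L) {
  half <- as.integer(ceiling(L / 2))
  list(c(1L, min(L, half + 300L)), c(max(1L, half - 299L), L))
}

rc_strings <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate paired-end reads from a donor/recipient mtDNA mixture
#'
#' Emits 2 x `read_length` bp read pairs from a circular donor/recipient
#' haplotype mixture with truth-correct alignments (no external aligner is
#' involved). Each fragment originates from one of three molecule species —
#' donor, full-length recipient, or deletion-carrying recipient — sampled
#' in proportion to molecule fraction times molecule length. Deleted
#' molecules contribute no bases inside the deletion; reads crossing the
#' deletion junction carry a deletion CIGAR operation, and reads spanning
#' the circular origin are split into two alignment records (the second
#' flagged supplementary). Substitution errors are applied i.i.d. per base;
#' base qualities are fixed at Q30.
#'
#' The number of read pairs is `coverage * effective_length /
#' (2 * read_length)`, where `effective_length` is the mass-weighted mean
#' molecule length (equal to the genome length when no deletion is
#' present), so the realized mean depth at retained sites matches
#' `coverage`.
#'
#' @param pair A [haplotype_pair].
#' @param config A [read_sim_config].
#' @param out_prefix Optional path prefix; when given, writes
#'   `<prefix>_R1.fastq`, `<prefix>_R2.fastq`, `<prefix>.sam` and
#'   `<prefix>_truth.tsv`.
#' @return An object of class `read_sim`: in-memory alignments
#'   (`$reads`, `$segments`), the per-read `$truth` table (columns
#'   `read_id`, `origin`, `start`, `strand`), the reference info and the
#'   config. Feed it directly to [build_pileup()] or [fit_mixture()].
#' @export
simulate_reads <- function(pair, config = read_sim_config(),
                           out_prefix = NULL) {
  stopifnot(inherits(pair, "haplotype_pair"),
            inherits(config, "read_sim_config"))
  L <- pair$recipient$length
  rl <- config$read_length
  frag_len <- 2L * rl + config$insert_gap
  del <- pair$deletion
  h <- if (is.null(del)) 0 else del$heteroplasmy
  d_size <- if (is.null(del)) 0L else deletion_size(del)
  Ld <- L - d_size
  if (Ld < frag_len)
    stop("genome (after deletion) shorter than fragment length")
  f <- config$mixture_fraction

  mol_len <- c(L, L, Ld)                       # donor, recip_full, recip_del
  mol_frac <- c(f, (1 - f) * (1 - h), (1 - f) * h)
  w_class <- mol_frac * mol_len
  eff_len <- sum(w_class)
  n_pairs <- max(1L, as.integer(round(config$coverage * eff_len /
                                        (2 * rl))))

  pcr <- config$amplification_mode == "pcr_two_amplicon"
  amps <- NULL
  if (pcr) {
    amps <- config$amplicon_intervals %||% default_amplicons(L)
    if (length(amps) != 2L)
      stop("configuration error: pcr_two_amplicon needs two amplicon intervals")
    check_amplicon_cover(amps, pair$truth_snps$position, L)
  }

  sim <- with_seed(config$seed, {
    if (!pcr) {
      cls <- sample.int(3L, n_pairs, replace = TRUE, prob = w_class)
      start <- integer(n_pairs)
      for (k in 1:3) {
        i <- cls == k
        if (any(i)) start[i] <- sample.int(mol_len[k], sum(i), replace = TRUE)
      }
    } else {
      # categories: class x amplicon, weights = molecule fraction x
      # molecule-space placement window x per-amplicon depth ratio
      r_amp <- c(1, config$amplicon_ratio)
      win <- expand.grid(cls = 1:3, amp = 1:2)
      win$ms <- NA_integer_; win$me <- NA_integer_
      for (i in seq_len(nrow(win))) {
        mw <- amplicon_window(amps[[win$amp[i]]], L, del,
                              deleted = win$cls[i] == 3L)
        win$ms[i] <- mw[1L]; win$me[i] <- mw[2L]
      }
      win$span <- pmax(0L, win$me - win$ms + 1L - frag_len + 1L)
      win$w <- mol_frac[win$cls] * win$span * r_amp[win$amp]
      if (sum(win$w) <= 0)
        stop("configuration error: no amplicon can hold a fragment")
      cat_idx <- sample.int(nrow(win), n_pairs, replace = TRUE, prob = win$w)
      cls <- win$cls[cat_idx]
      start <- win$ms[cat_idx] +
        floor(stats::runif(n_pairs) * win$span[cat_idx])
      Lm <- mol_len[cls]
      start <- as.integer(((start - 1L) %% Lm) + 1L)
    }
    orient <- sample(c("+", "-"), n_pairs, replace = TRUE)
    list(cls = cls, start = as.integer(start), orient = orient)
  })

  cls <- sim$cls
  Lm <- mol_len[cls]
  # read A is the left, reference-forward mate; read B the right,
  # reference-reverse mate; pair orientation decides which is mate 1
  uA <- wrap1(sim$start, Lm)
  uB <- wrap1(sim$start + frag_len - rl, Lm)

  rec_seq <- pair$recipient$sequence
  mol_seq <- c(pair$donor$sequence, rec_seq,
               if (d_size > 0L)
                 paste0(substr(rec_seq, 1L, del$start - 1L),
                        substr(rec_seq, del$end + 1L, L))
               else rec_seq)
  mol2x <- vapply(mol_seq, function(s) paste0(s, s), "", USE.NAMES = FALSE)

  n_reads <- 2L * n_pairs
  ri_cls <- rep(cls, each = 2L)                 # reads interleaved A,B? no:
  # layout: reads 1..n_pairs are A mates, n_pairs+1..2n are B mates
  ri_cls <- c(cls, cls)
  u <- c(uA, uB)
  seqs <- substring(mol2x[ri_cls], u, u + rl - 1L)

  seqs <- with_seed(derive_seed(config$seed, "seqerr"), {
    apply_substitution_errors(seqs, rl, config$error_rate)
  })

  segs <- read_segments(u, mol_len[ri_cls], ri_cls == 3L, del, rl)

  pair_id <- sprintf("frag%07d", seq_len(n_pairs))
  mate_of <- c(ifelse(sim$orient == "+", 1L, 2L),
               ifelse(sim$orient == "+", 2L, 1L))
  read_id <- paste0(c(pair_id, pair_id), "/", mate_of)
  origin <- c("donor", "recipient_full", "recipient_deleted")[ri_cls]
  strand <- rep(c("+", "-"), c(n_pairs, n_pairs))
  # segs rows are grouped by read; first segment per read gives its POS
  first_idx <- which(!duplicated(segs$read))
  start_ref <- integer(n_reads)
  start_ref[segs$read[first_idx]] <- segs$ref_start[first_idx]

  # read A: paired+proper+mate-reverse (+first/second); read B adds reverse
  flagA <- ifelse(mate_of[seq_len(n_pairs)] == 1L, 99L, 163L)
  flagB <- ifelse(mate_of[n_pairs + seq_len(n_pairs)] == 1L, 83L, 147L)
  reads <- list(qname = c(pair_id, pair_id),
                read_id = read_id,
                mate = mate_of,
                seq = seqs,
                qual = strrep("?", rl),          # Q30, recycled
                mapq = rep(60L, n_reads),
                flag = c(flagA, flagB),
                origin = origin,
                strand = strand,
                start = start_ref)

  truth <- data.frame(read_id = read_id, origin = origin,
                      start = start_ref, strand = strand,
                      stringsAsFactors = FALSE)

  out <- structure(list(reads = reads, segments = segs, truth = truth,
                        genome_name = pair$recipient$name,
                        genome_length = L, n_pairs = n_pairs,
                        config = config),
                   class = "read_sim")
  if (!is.null(out_prefix)) write_read_sim(out, pair, out_prefix)
  out
}

#' @export
print.read_sim <- function(x, ...) {
  cat(sprintf(
    "<read_sim> %d read pairs (2 x %d bp) over %s (%d bp), mode %s\n",
    x$n_pairs, x$config$read_length, x$genome_name, x$genome_length,
    x$config$amplification_mode))
  tab <- table(x$truth$origin) / 2
  cat("  fragments by origin:",
      paste(names(tab), format(as.integer(tab)), collapse = ", "), "\n")
  invisible(x)
}

# i.i.d. substitution errors: binomial count per read, positions sampled
# without replacement, replacement base uniform over the other three
apply_substitution_errors <- function(seqs, rl, error_rate) {
  if (error_rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), rl, error_rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(rl, n_err[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, old), 1L)
    }
  }
  seqs
}

# Map each read (molecule-space start u on a circle of length Lm, length
# rl) to 1-3 reference-space segments. Returns a data.frame grouped by
# read with columns read, ref_start, ref_end, offset (0-based offset of
# ref_start's base within the read sequence) and piece (molecule-space
# piece index; a new piece starts where the read wraps the origin).
read_segments <- function(u, Lm, is_del, del, rl) {
  n <- length(u)
  e <- u + rl - 1L
  # molecule-space pieces (origin wrap)
  p1s <- u; p1e <- pmin(e, Lm)
  has2 <- e > Lm
  p2s <- ifelse(has2, 1L, NA_integer_)
  p2e <- ifelse(has2, e - Lm, NA_integer_)

  map_piece <- function(ps, pe, deleted, off0, piece) {
    # returns candidate segments (possibly split at the deletion junction)
    if (is.null(del)) {
      return(list(list(read = seq_along(ps), rs = ps, re = pe,
                       off = off0, piece = piece)))
    }
    ds <- del$start; dd <- deletion_size(del)
    split <- deleted & ps < ds & pe >= ds
    below <- !deleted | pe < ds
    above <- deleted & ps >= ds & !split
    rs1 <- ifelse(below, ps, ifelse(above, ps + dd, ps))
    re1 <- ifelse(below, pe, ifelse(above, pe + dd, ds - 1L))
    rs2 <- ifelse(split, ds + dd, NA_integer_)
    re2 <- ifelse(split, pe + dd, NA_integer_)
    off2 <- off0 + (ds - ps)
    list(list(read = seq_along(ps), rs = as.integer(rs1),
              re = as.integer(re1), off = off0, piece = piece),
         list(read = seq_along(ps)[split], rs = as.integer(rs2[split]),
              re = as.integer(re2[split]), off = off2[split],
              piece = piece[split]))
  }

  len1 <- p1e - p1s + 1L
  cand <- map_piece(p1s, p1e, is_del, rep(0L, n), rep(1L, n))
  if (any(has2)) {
    i2 <- which(has2)
    c2 <- map_piece(p2s[i2], p2e[i2], is_del[i2], len1[i2], rep(2L, length(i2)))
    c2 <- lapply(c2, function(x) { x$read <- i2[x$read]; x })
    cand <- c(cand, c2)
  }
  cand <- Filter(function(x) length(x$read) > 0L, cand)
  seg <- data.frame(
    read = unlist(lapply(cand, `[[`, "read")),
    ref_start = unlist(lapply(cand, `[[`, "rs")),
    ref_end = unlist(lapply(cand, `[[`, "re")),
    offset = as.integer(unlist(lapply(cand, `[[`, "off"))),
    piece = unlist(lapply(cand, `[[`, "piece"))
  )
  seg <- seg[order(seg$read, seg$offset), , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

# warn unless the amplicon intervals jointly cover every truth SNP
check_amplicon_cover <- function(amps, snp_pos, L) {
  if (length(snp_pos) == 0L) return(invisible(TRUE))
  covered <- rep(FALSE, length(snp_pos))
  for (iv in amps) {
    if (iv[1L] <= iv[2L]) {
      covered <- covered | (snp_pos >= iv[1L] & snp_pos <= iv[2L])
    } else {                                    # wraps the origin
      covered <- covered | snp_pos >= iv[1L] | snp_pos <= iv[2L]
    }
  }
  if (!all(covered))
    warning(sum(!covered),
            " truth SNP position(s) not covered by the amplicon intervals")
  invisible(all(covered))
}

# molecule-space placement window [ms, me] (possibly unwrapped past Lm)
# for a reference-space amplicon interval
amplicon_window <- function(iv, L, del, deleted) {
  a <- iv[1L]; b <- iv[2L]
  wraps <- a > b
  if (!deleted || is.null(del)) {
    Lm <- L
    ms <- a; me <- if (wraps) b + Lm else b
    return(c(ms, me))
  }
  ds <- del$start; de <- del$end; dd <- de - ds + 1L
  Lm <- L - dd
  map_start <- function(x) if (x < ds) x else if (x > de) x - dd else ds
  map_end <- function(x) if (x < ds) x else if (x > de) x - dd else ds - 1L
  ms <- map_start(a); me <- map_end(b)
  if (wraps) me <- me + Lm
  c(ms, me)
}
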