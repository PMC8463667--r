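#' Circular genome objects
#'
#' A `circular_genome` holds a named, uppercase A/C/G/T sequence together
#' with its length. Coordinates on it are 1-based inclusive and wrap modulo
#' the length, matching the convention used for the human mitochondrial
#' reference (rCRS, 16,569 bp).
#'
#' @param sequence Character scalar, uppercase nucleotides (A/C/G/T only).
#' @param name Sequence identifier used in FASTA/SAM headers.
#' @return An object of class `circular_genome` with fields `name`,
#'   `sequence` and `length`.
#' @export
circular_genome <- function(sequence, name = "chrM") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty sequence")
  if (grepl("[^ACGT]", sequence))
    stop("sequence contains bases outside A/C/G/T")
  structure(
    list(name = as.character(name), sequence = sequence,
         length = nchar(sequence)),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d bp (circular)\n", x$name, x$length))
  invisible(x)
}

#' @export
length.circular_genome <- function(x) x$length

#' Generate a random circular reference genome
#'
#' Draws a uniformly random A/C/G/T sequence of the requested length. The
#' default length is the 16,569 bp of the human mitochondrial genome.
#'
#' @param length Genome length in base pairs (>= 100).
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @param name Sequence identifier.
#' @return A [circular_genome].
#' @export
make_reference <- function(length = 16569L, seed = 1L, name = "chrM") {
  length <- as.integer(length)
  if (is.na(length) || length < 100L)
    stop("invalid parameter: length must be at least 100")
  seq <- with_seed(seed, paste(sample(c("A", "C", "G", "T"), length,
                                      replace = TRUE), collapse = ""))
  circular_genome(seq, name = name)
}

#' Specify a large mtDNA deletion
#'
#' Describes a single large-scale deletion carried by a fraction
#' (heteroplasmy) of the recipient's mtDNA molecules. The default interval
#' is the common deletion studied here, nt 8470 to nt 13,447 inclusive.
#'
#' @param start,end 1-based inclusive interval of the deleted bases.
#' @param heteroplasmy Fraction in [0, 1] of recipient molecules carrying
#'   the deletion.
#' @return An object of class `deletion_spec`.
#' @export
deletion_spec <- function(start = 8470L, end = 13447L, heteroplasmy = 0) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start >= end)
    stop("invalid parameter: need 1 <= start < end")
  if (!is.finite(heteroplasmy) || heteroplasmy < 0 || heteroplasmy > 1)
    stop("invalid parameter: heteroplasmy must lie in [0, 1]")
  structure(list(start = start, end = end,
                 heteroplasmy = as.numeric(heteroplasmy)),
            class = "deletion_spec")
}

#' @export
print.deletion_spec <- function(x, ...) {
  cat(sprintf("<deletion_spec> nt %d-%d (%d bp) at heteroplasmy %.1f%%\n",
              x$start, x$end, x$end - x$start + 1L, 100 * x$heteroplasmy))
  invisible(x)
}

deletion_size <- function(del) del$end - del$start + 1L

#' Derive a donor/recipient haplotype pair from a reference
#'
#' Creates two mtDNA haplotypes that differ at exactly `n_snps` positions:
#' the recipient keeps the reference sequence, and the donor carries
#' `n_snps` substitutions at positions sampled without replacement. When the
#' recipient carries a deletion, no substitution is placed inside the
#' deletion interval, so that allele frequencies at informative sites are
#' not distorted by molecule dosage. The true SNP table and the deletion
#' are recorded for downstream parameter-recovery checks.
#'
#' @param ref A [circular_genome] reference.
#' @param n_snps Number of donor/recipient differences to introduce (>= 1).
#' @param deletion Optional [deletion_spec] carried by the recipient.
#' @param seed Integer seed.
#' @return An object of class `haplotype_pair` with fields `donor`,
#'   `recipient` (both [circular_genome]), `truth_snps` (data.frame with
#'   columns `position`, `donor_allele`, `recipient_allele`) and
#'   `deletion` (or `NULL`).
#' @export
derive_haplotypes <- function(ref, n_snps = 30L, deletion = NULL, seed = 1L) {
  stopifnot(inherits(ref, "circular_genome"))
  n_snps <- as.integer(n_snps)
  if (is.na(n_snps) || n_snps < 1L)
    stop("invalid parameter: n_snps must be >= 1")
  avail <- seq_len(ref$length)
  if (!is.null(deletion)) {
    stopifnot(inherits(deletion, "deletion_spec"))
    if (deletion$end > ref$length)
      stop("invalid parameter: deletion interval exceeds genome length")
    avail <- avail[avail < deletion$start | avail > deletion$end]
  }
  if (n_snps > length(avail))
    stop("invalid parameter: n_snps exceeds available positions")
  bases <- c("A", "C", "G", "T")
  res <- with_seed(seed, {
    pos <- sort(sample(avail, n_snps))
    old <- substring(ref$sequence, pos, pos)
    new <- vapply(old, function(b) sample(setdiff(bases, b), 1L), "")
    list(pos = pos, old = old, new = unname(new))
  })
  donor_seq <- ref$sequence
  for (i in seq_len(n_snps)) {
    substr(donor_seq, res$pos[i], res$pos[i]) <- res$new[i]
  }
  structure(
    list(
      donor = circular_genome(donor_seq, name = paste0(ref$name, "_donor")),
      recipient = circular_genome(ref$sequence,
                                  name = paste0(ref$name, "_recipient")),
      truth_snps = data.frame(position = res$pos,
                              donor_allele = res$new,
                              recipient_allele = res$old,
                              stringsAsFactors = FALSE, row.names = NULL),
      deletion = deletion
    ),
    class = "haplotype_pair"
  )
}

#' @export
print.haplotype_pair <- function(x, ...) {
  cat(sprintf("<haplotype_pair> %d bp, %d truth SNPs%s\n",
              x$donor$length, nrow(x$truth_snps),
              if (is.null(x$deletion)) "" else
                sprintf(", recipient deletion nt %d-%d (h = %.3f)",
                        x$deletion$start, x$deletion$end,
                        x$deletion$heteroplasmy)))
  invisible(x)
}

#' Read a single-record FASTA file as a circular genome
#'
#' @param path Path to a FASTA file containing exactly one record of
#'   unambiguous A/C/G/T bases.
#' @return A [circular_genome].
#' @export
load_haplotype <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L)
    stop("format error: expected a single-record FASTA, found ", length(set))
  seq <- toupper(as.character(set[[1L]]))
  if (grepl("[^ACGT]", seq))
    stop("content error: sequence contains N or ambiguity codes")
  circular_genome(seq, name = sub("\\s.*$", "", names(set)[1L]))
}

#' Write a circular genome to FASTA
#'
#' @param genome A [circular_genome].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_haplotype <- function(genome, path) {
  stopifnot(inherits(genome, "circular_genome"))
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
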