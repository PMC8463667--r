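#' Identify informative SNPs between two mtDNA haplotypes
#'
#' An informative SNP is a position at which the donor (exogenous) and
#' recipient (endogenous) haplotypes carry different bases; the set of such
#' positions is what lets a sequencing pileup quantify the mixture of the
#' two mtDNA populations. Both sequences must have equal length (haplotype
#' pairs differing by indels need alignment first and are out of scope).
#'
#' Sites are flagged, and by default excluded from downstream estimation,
#' when they fall
#' \itemize{
#'   \item inside a declared recipient deletion (`in_deletion`): template
#'     dosage differs between haplotypes there;
#'   \item within a homopolymer run of 5 or more identical bases on either
#'     haplotype (`homopolymer`): sequencing error is elevated exactly where
#'     the estimator trusts single-base counts;
#'   \item inside any user-supplied excluded interval (`excluded_region`),
#'     e.g. the hypervariable control-region preset
#'     [hypervariable_regions()].
#' }
#'
#' @param donor,recipient [circular_genome] objects of equal length.
#' @param deletion Optional [deletion_spec] carried by the recipient.
#' @param exclude_regions List of `c(start, end)` 1-based intervals to flag.
#'   Empty by default.
#' @param homopolymer_min Minimum run length flagged as homopolymer
#'   (default 5).
#' @return A data.frame of class `informative_snps` with columns `position`,
#'   `donor_allele`, `recipient_allele`, logical flags `in_deletion`,
#'   `homopolymer`, `excluded_region`, and `pass` (no flag set).
#' @export
find_informative_snps <- function(donor, recipient, deletion = NULL,
                                  exclude_regions = list(),
                                  homopolymer_min = 5L) {
  stopifnot(inherits(donor, "circular_genome"),
            inherits(recipient, "circular_genome"))
  if (donor$length != recipient$length)
    stop("alignment required: haplotypes have unequal lengths (",
         donor$length, " vs ", recipient$length, ")")
  d <- strsplit(donor$sequence, "", fixed = TRUE)[[1L]]
  r <- strsplit(recipient$sequence, "", fixed = TRUE)[[1L]]
  pos <- which(d != r)
  in_del <- if (is.null(deletion)) rep(FALSE, length(pos)) else
    pos >= deletion$start & pos <= deletion$end
  hp <- homopolymer_mask(d, homopolymer_min) |
    homopolymer_mask(r, homopolymer_min)
  excl <- rep(FALSE, length(pos))
  for (iv in exclude_regions) {
    excl <- excl | (pos >= iv[1L] & pos <= iv[2L])
  }
  out <- data.frame(position = pos,
                    donor_allele = d[pos],
                    recipient_allele = r[pos],
                    in_deletion = in_del,
                    homopolymer = hp[pos],
                    excluded_region = excl,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$pass <- !(out$in_deletion | out$homopolymer | out$excluded_region)
  class(out) <- c("informative_snps", "data.frame")
  out
}

# logical mask of positions lying in a homopolymer run of >= min bases,
# treating the sequence as circular (runs may span the origin)
homopolymer_mask <- function(bases, min_run) {
  n <- length(bases)
  runs <- rle(bases)
  mask <- inverse.rle(list(lengths = runs$lengths,
                           values = runs$lengths >= min_run))
  k <- length(runs$lengths)
  if (k > 1L && runs$values[1L] == runs$values[k]) {
    joined <- runs$lengths[1L] + runs$lengths[k]
    if (joined >= min_run) {
      mask[seq_len(runs$lengths[1L])] <- TRUE
      mask[seq.int(n - runs$lengths[k] + 1L, n)] <- TRUE
    }
  }
  mask
}

#' rCRS-style hypervariable control-region intervals
#'
#' Preset exclusion intervals covering the three hypervariable segments of
#' the human mtDNA control region (HV2 57-372, HV3 438-574, HV1
#' 16,024-16,365 in rCRS coordinates). Off by default in
#' [find_informative_snps()]; supply as `exclude_regions` to activate.
#'
#' @return A list of `c(start, end)` intervals.
#' @export
hypervariable_regions <- function() {
  list(c(57L, 372L), c(438L, 574L), c(16024L, 16365L))
}

#' @export
print.informative_snps <- function(x, ...) {
  cat(sprintf("<informative_snps> %d sites (%d pass, %d flagged)\n",
              nrow(x), sum(x$pass), sum(!x$pass)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more sites\n")
  invisible(x)
}

#' Write / read an informative-SNP table as TSV
#'
#' @param snps An `informative_snps` data.frame.
#' @param path TSV path.
#' @return `path` (write) or the table (read).
#' @export
write_snp_table <- function(snps, path) {
  utils::write.table(as.data.frame(snps), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_table
#' @export
read_snp_table <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(out) <- c("informative_snps", "data.frame")
  out
}
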