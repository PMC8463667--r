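#' Digital-PCR partition counts
#'
#' Raw readout of one dPCR chip (or one dye channel of a dual-probe chip):
#' the number of readable partitions and how many were positive, plus the
#' nanograms of template loaded so copy numbers can be normalized per ng.
#'
#' @param n_positive Positive partitions (>= 0, <= `n_valid`).
#' @param n_valid Readable partitions (>= 1; chips have 20,000 nominal).
#' @param ng_loaded Nanograms of template loaded (> 0 for per-ng outputs).
#' @param assay Assay name.
#' @return An object of class `partition_counts`.
#' @export
partition_counts <- function(n_positive, n_valid = 20000L, ng_loaded = NA_real_,
                             assay = "assay") {
  n_positive <- as.integer(n_positive); n_valid <- as.integer(n_valid)
  if (is.na(n_valid) || n_valid < 1L)
    stop("invalid parameter: n_valid must be >= 1")
  if (is.na(n_positive) || n_positive < 0L || n_positive > n_valid)
    stop("invalid parameter: need 0 <= n_positive <= n_valid")
  structure(list(assay = assay, n_valid = n_valid, n_positive = n_positive,
                 ng_loaded = as.numeric(ng_loaded)),
            class = "partition_counts")
}

#' @export
print.partition_counts <- function(x, ...) {
  cat(sprintf("<partition_counts> %s: %d / %d positive (%.3f)%s\n",
              x$assay, x$n_positive, x$n_valid, x$n_positive / x$n_valid,
              if (is.na(x$ng_loaded)) "" else
                sprintf(", %.3g ng loaded", x$ng_loaded)))
  invisible(x)
}

#' Simulate a digital-PCR chip
#'
#' Draws the total number of template molecules as Poisson(copies/ng x ng
#' loaded), assigns each molecule to a readable partition uniformly at
#' random, and counts partitions holding at least one molecule.
#'
#' @param true_copies_per_ng Ground-truth concentration (copies per ng).
#' @param ng_loaded Nanograms loaded (default 2).
#' @param n_partitions Total chip partitions (default 20,000).
#' @param valid_fraction Fraction of partitions readable (default 1).
#' @param seed Integer seed.
#' @param assay Assay name carried into the counts.
#' @return A [partition_counts], with the realized molecule draw recorded
#'   in `$true_molecules` as simulation ground truth.
#' @export
simulate_dpcr <- function(true_copies_per_ng, ng_loaded = 2,
                          n_partitions = 20000L, valid_fraction = 1,
                          seed = 1L, assay = "assay") {
  if (!is.finite(true_copies_per_ng) || true_copies_per_ng < 0)
    stop("invalid parameter: true_copies_per_ng must be >= 0")
  if (!is.finite(ng_loaded) || ng_loaded < 0)
    stop("invalid parameter: ng_loaded must be >= 0")
  n_partitions <- as.integer(n_partitions)
  if (n_partitions < 1L) stop("invalid parameter: n_partitions must be >= 1")
  n_valid <- max(1L, as.integer(round(n_partitions * valid_fraction)))
  drawn <- with_seed(seed, {
    m <- stats::rpois(1L, true_copies_per_ng * ng_loaded)
    n_pos <- if (m == 0L) 0L
    else sum(tabulate(sample.int(n_valid, m, replace = TRUE),
                      nbins = n_valid) > 0L)
    list(m = m, n_pos = n_pos)
  })
  out <- partition_counts(drawn$n_pos, n_valid, ng_loaded, assay)
  out$true_molecules <- drawn$m        # simulation truth, for recovery tests
  out
}

#' Simulate paired full-length / total mtDNA chips
#'
#' Emulates the paired-assay design used for deletion-heteroplasmy
#' determination: a "total" assay targeting a site outside the deletion
#' detects every mtDNA molecule, while a "full-length" assay targeting a
#' site inside the deletion detects only non-deleted molecules, so its
#' effective concentration is `total x (1 - heteroplasmy)`. The two chips
#' are loaded from the same sample (equal ng) but partitioned
#' independently.
#'
#' @param total_copies_per_ng Ground-truth total mtDNA concentration.
#' @param deletion_heteroplasmy Fraction in [0, 1] of molecules carrying
#'   the deletion.
#' @param ng_loaded Nanograms loaded per chip (default 6.55).
#' @param n_partitions,valid_fraction Chip geometry, see [simulate_dpcr()].
#' @param seed Integer seed (the two chips use derived sub-seeds).
#' @return A list with elements `full_length` and `total`, each a
#'   [partition_counts].
#' @export
simulate_dpcr_heteroplasmy <- function(total_copies_per_ng,
                                       deletion_heteroplasmy,
                                       ng_loaded = 6.55,
                                       n_partitions = 20000L,
                                       valid_fraction = 1, seed = 1L) {
  if (!is.finite(deletion_heteroplasmy) || deletion_heteroplasmy < 0 ||
      deletion_heteroplasmy > 1)
    stop("invalid parameter: heteroplasmy must lie in [0, 1]")
  fl <- simulate_dpcr(total_copies_per_ng * (1 - deletion_heteroplasmy),
                      ng_loaded, n_partitions, valid_fraction,
                      seed = derive_seed(seed, "dpcr_fl"),
                      assay = "full_length")
  tot <- simulate_dpcr(total_copies_per_ng, ng_loaded, n_partitions,
                       valid_fraction,
                       seed = derive_seed(seed, "dpcr_total"),
                       assay = "total")
  list(full_length = fl, total = tot)
}

#' Poisson occupancy rate of a dPCR chip
#'
#' The mean number of template copies per partition implied by the
#' fraction of positive partitions under Poisson loading:
#' lambda = -ln(1 - n_positive / n_valid).
#'
#' @param n_positive,n_valid Positive and readable partition counts.
#' @return The occupancy `lambda` (copies per partition).
#' @export
poisson_lambda <- function(n_positive, n_valid) {
  if (n_valid < 1L || n_positive < 0L || n_positive > n_valid)
    stop("invalid parameter: need 0 <= n_positive <= n_valid, n_valid >= 1")
  if (n_positive == n_valid)
    stop("saturation: every partition positive, lambda undefined")
  -log(1 - n_positive / n_valid)
}

#' Absolute copy number from partition counts
#'
#' Converts chip counts into copies per chip (`lambda x n_valid`) and
#' copies per nanogram of template, with a 95% confidence interval from
#' the Wilson binomial interval on the positive fraction propagated
#' through the Poisson occupancy transform and the linear scalings.
#'
#' @param counts A [partition_counts].
#' @return An object of class `copy_number` with fields `lambda`,
#'   `copies_per_chip`, `copies_per_ng`, `ci95` (on copies/ng, or on
#'   copies/chip when `ng_loaded` is missing) and the input counts.
#' @export
copies_per_ng <- function(counts) {
  stopifnot(inherits(counts, "partition_counts"))
  lam <- poisson_lambda(counts$n_positive, counts$n_valid)
  chip <- lam * counts$n_valid
  per_ng <- if (is.na(counts$ng_loaded)) NA_real_ else {
    if (counts$ng_loaded <= 0)
      stop("invalid parameter: ng_loaded must be > 0")
    chip / counts$ng_loaded
  }
  wil <- wilson_interval(counts$n_positive, counts$n_valid)
  ci_lam <- -log(1 - pmin(wil, 1 - 1e-12))
  scale <- counts$n_valid / if (is.na(counts$ng_loaded)) 1 else counts$ng_loaded
  structure(list(lambda = lam, copies_per_chip = chip,
                 copies_per_ng = per_ng,
                 ci95 = ci_lam * scale,
                 ci_method = "Wilson on positive fraction, transformed",
                 counts = counts),
            class = "copy_number")
}

wilson_interval <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, center - half), min(1, center + half))
}

#' @export
print.copy_number <- function(x, digits = 4, ...) {
  cat(sprintf("<copy_number> %s: lambda %.4g, %.4g copies/chip",
              x$counts$assay, x$lambda, x$copies_per_chip))
  if (!is.na(x$copies_per_ng))
    cat(sprintf(", %.4g copies/ng (95%% CI %.4g-%.4g)",
                x$copies_per_ng, x$ci95[1L], x$ci95[2L]))
  cat("\n")
  invisible(x)
}

#' @method coef copy_number
#' @export
coef.copy_number <- function(object, ...) {
  c(lambda = object$lambda, copies_per_chip = object$copies_per_chip,
    copies_per_ng = object$copies_per_ng)
}

#' @method confint copy_number
#' @export
confint.copy_number <- function(object, parm, level = 0.95, ...) {
  if (level != 0.95) {
    wil <- wilson_interval(object$counts$n_positive, object$counts$n_valid,
                           level)
    ci_lam <- -log(1 - pmin(wil, 1 - 1e-12))
    scale <- object$counts$n_valid /
      if (is.na(object$counts$ng_loaded)) 1 else object$counts$ng_loaded
    return(ci_lam * scale)
  }
  object$ci95
}

#' Deletion heteroplasmy from paired full-length / total assays
#'
#' Heteroplasmy percent = 100 x (1 - full-length copies / total copies).
#' When sampling noise makes the full-length assay exceed the total
#' (possible near 0% heteroplasmy), the value is clamped to [0, 100] and
#' flagged with a warning rather than erroring.
#'
#' @param full_length,total `copy_number` results for the full-length and
#'   total assays of one sample (both per-ng normalized, or both per-chip
#'   with equal loads — the ratio makes the two equivalent).
#' @return An object of class `heteroplasmy_result` with fields `percent`,
#'   `full_length_assay`, `total_assay`, `clamped`.
#' @export
deletion_heteroplasmy <- function(full_length, total) {
  stopifnot(inherits(full_length, "copy_number"),
            inherits(total, "copy_number"))
  fl <- if (is.na(full_length$copies_per_ng)) full_length$copies_per_chip
        else full_length$copies_per_ng
  tt <- if (is.na(total$copies_per_ng)) total$copies_per_chip
        else total$copies_per_ng
  if (!is.finite(tt) || tt <= 0)
    stop("undefined heteroplasmy: total copy number is zero")
  pct <- 100 * (1 - fl / tt)
  clamped <- FALSE
  if (pct < 0) {
    warning("full-length exceeds total copies; heteroplasmy clamped to 0")
    pct <- 0; clamped <- TRUE
  } else if (pct > 100) {
    pct <- 100; clamped <- TRUE
  }
  structure(list(percent = pct,
                 full_length_assay = full_length$counts$assay,
                 total_assay = total$counts$assay,
                 clamped = clamped),
            class = "heteroplasmy_result")
}

#' @export
print.heteroplasmy_result <- function(x, ...) {
  cat(sprintf("Deletion heteroplasmy: %.2f%% (%s vs %s)%s\n",
              x$percent, x$full_length_assay, x$total_assay,
              if (x$clamped) " [clamped]" else ""))
  invisible(x)
}

#' Allele fraction from a dual-probe dPCR chip
#'
#' For SNP genotyping chips read in two dye channels (one probe per
#' allele), converts each channel's positive-partition count to copies via
#' Poisson occupancy and returns allele B's share,
#' `copies_b / (copies_a + copies_b)`. Double-positive partitions are
#' counted in both channels (independent-target approximation).
#'
#' @param counts_allele_a,counts_allele_b [partition_counts] for the two
#'   dye channels of one chip.
#' @return Allele-B fraction in [0, 1].
#' @export
dual_probe_fraction <- function(counts_allele_a, counts_allele_b) {
  stopifnot(inherits(counts_allele_a, "partition_counts"),
            inherits(counts_allele_b, "partition_counts"))
  la <- poisson_lambda(counts_allele_a$n_positive, counts_allele_a$n_valid)
  lb <- poisson_lambda(counts_allele_b$n_positive, counts_allele_b$n_valid)
  ca <- la * counts_allele_a$n_valid
  cb <- lb * counts_allele_b$n_valid
  if (ca + cb <= 0)
    stop("undefined fraction: both channels have zero copies")
  cb / (ca + cb)
}

#' Read / write dPCR partition count tables
#'
#' TSV with columns `assay`, `n_valid`, `n_positive`, `ng_loaded` (one row
#' per chip or channel).
#'
#' @param counts_list List of [partition_counts].
#' @param path TSV path.
#' @return `path` (write) or a list of [partition_counts] (read).
#' @export
write_partition_counts <- function(counts_list, path) {
  if (inherits(counts_list, "partition_counts"))
    counts_list <- list(counts_list)
  df <- do.call(rbind, lapply(counts_list, function(x)
    data.frame(assay = x$assay, n_valid = x$n_valid,
               n_positive = x$n_positive, ng_loaded = x$ng_loaded)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition_counts
#' @export
read_partition_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    partition_counts(df$n_positive[i], df$n_valid[i], df$ng_loaded[i],
                     df$assay[i]))
}
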