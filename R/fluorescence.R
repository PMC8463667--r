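#' Simulate a per-cell two-channel fluorescence panel
#'
#' Emulates the readout used to estimate the exogenous share of a cell's
#' mitochondrial content: a total-mitochondria stain (MitoTracker) and an
#' exogenous-mitochondria label (Dendra2 carried by transferred
#' mitochondria). Per cell, the total mitochondrial signal is lognormal
#' (sdlog 0.6 around 1000 a.u., a typical flow-intensity spread); the
#' Dendra2 channel is `exo_fraction x total x gain` and the MitoTracker
#' channel is `total`, each multiplied by independent lognormal noise with
#' the given coefficient of variation (mean 1). Calibration cells — cells
#' whose mitochondria are entirely labeled, e.g. the originally augmented
#' donor cells, flagged `dtomato_positive` — are generated at exogenous
#' fraction 1 and anchor the channel-gain estimate in
#' [exo_mito_fraction()].
#'
#' @param n_cells Number of recipient cells (default 500).
#' @param exo_fraction True fraction in [0, 1] of recipient mitochondrial
#'   content that is exogenous.
#' @param noise_cv Lognormal channel-noise coefficient of variation
#'   (default 0.3).
#' @param n_calibration Number of fully-exogenous control cells
#'   (default 50).
#' @param gain Dendra2 channel gain relative to MitoTracker (default 0.8).
#' @param seed Integer seed.
#' @return A data.frame of class `fluorescence_panel`: `cell_id`,
#'   `dendra2_intensity`, `mitotracker_intensity`, `dtomato_positive`,
#'   `is_calibration`.
#' @export
simulate_fluorescence <- function(n_cells = 500L, exo_fraction = 0.084,
                                  noise_cv = 0.3, n_calibration = 50L,
                                  gain = 0.8, seed = 1L) {
  if (!is.finite(exo_fraction) || exo_fraction < 0 || exo_fraction > 1)
    stop("invalid parameter: exo_fraction must lie in [0, 1]")
  if (!is.finite(noise_cv) || noise_cv < 0)
    stop("invalid parameter: noise_cv must be >= 0")
  n_cells <- as.integer(n_cells); n_calibration <- as.integer(n_calibration)
  if (n_cells < 1L || n_calibration < 0L)
    stop("invalid parameter: need n_cells >= 1 and n_calibration >= 0")
  n <- n_cells + n_calibration
  sdlog <- sqrt(log(1 + noise_cv^2))
  meanlog <- -sdlog^2 / 2                      # noise factors have mean 1
  panel <- with_seed(seed, {
    total <- stats::rlnorm(n, meanlog = log(1000), sdlog = 0.6)
    frac <- c(rep(exo_fraction, n_cells), rep(1, n_calibration))
    noise1 <- if (noise_cv > 0) stats::rlnorm(n, meanlog, sdlog) else rep(1, n)
    noise2 <- if (noise_cv > 0) stats::rlnorm(n, meanlog, sdlog) else rep(1, n)
    data.frame(
      cell_id = sprintf("cell%05d", seq_len(n)),
      dendra2_intensity = frac * total * gain * noise1,
      mitotracker_intensity = total * noise2,
      dtomato_positive = c(rep(FALSE, n_cells), rep(TRUE, n_calibration)),
      is_calibration = c(rep(FALSE, n_cells), rep(TRUE, n_calibration)),
      stringsAsFactors = FALSE)
  })
  class(panel) <- c("fluorescence_panel", "data.frame")
  panel
}

#' Read / write fluorescence panels as TSV
#'
#' @param panel A `fluorescence_panel` data.frame.
#' @param path TSV path.
#' @return `path` (write) or the panel (read).
#' @export
write_fluorescence_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fluorescence_panel
#' @export
read_fluorescence_panel <- function(path) {
  panel <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  class(panel) <- c("fluorescence_panel", "data.frame")
  panel
}
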