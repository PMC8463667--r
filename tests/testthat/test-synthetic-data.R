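test_that("make_reference produces valid, reproducible genomes", {
  g <- make_reference(16569, seed = 1)
  expect_s3_class(g, "circular_genome")
  expect_identical(g$length, 16569L)
  expect_identical(nchar(g$sequence), 16569L)
  expect_false(grepl("[^ACGT]", g$sequence))

  expect_identical(make_reference(100, seed = 7)$sequence,
                   make_reference(100, seed = 7)$sequence)
  expect_false(identical(make_reference(100, seed = 7)$sequence,
                         make_reference(100, seed = 8)$sequence))
  expect_error(make_reference(99), "invalid parameter")

  # uniform draws: each base composition inside a generous binomial band
  comp <- table(strsplit(make_reference(200, seed = 3)$sequence, "")[[1L]])
  expect_true(all(comp / 200 > 0.1 & comp / 200 < 0.5))
})

test_that("derive_haplotypes records exactly the introduced differences", {
  ref <- make_reference(16569, seed = 1)
  pair <- derive_haplotypes(ref, n_snps = 30, seed = 5)
  expect_identical(nrow(pair$truth_snps), 30L)
  # brute-force string diff agrees with the recorded truth
  expect_identical(seq_diff_positions(pair$donor$sequence,
                                      pair$recipient$sequence),
                   pair$truth_snps$position)
  expect_identical(pair$recipient$sequence, ref$sequence)

  one <- derive_haplotypes(ref, n_snps = 1, seed = 3)
  expect_length(seq_diff_positions(one$donor$sequence,
                                   one$recipient$sequence), 1L)

  del <- deletion_spec(8470, 13447, heteroplasmy = 0.835)
  pd <- derive_haplotypes(ref, n_snps = 30, deletion = del, seed = 5)
  expect_false(any(pd$truth_snps$position >= 8470 &
                     pd$truth_snps$position <= 13447))
  expect_identical(pd$deletion$heteroplasmy, 0.835)

  small <- make_reference(100, seed = 1)
  expect_error(derive_haplotypes(small, n_snps = 101), "invalid parameter")
  expect_error(derive_haplotypes(small, n_snps = 50,
                                 deletion = deletion_spec(10, 80),
                                 seed = 1),
               "invalid parameter")
})

test_that("simulated read counts follow the coverage formula", {
  pair <- small_pair(len = 16569L, n_snps = 5L, seed = 4L)
  cfg <- read_sim_config(coverage = 250, mixture_fraction = 0.1, seed = 2)
  pre <- tempfile()
  sim <- simulate_reads(pair, cfg, out_prefix = pre)
  expected <- 250 * 16569 / (2 * 150)
  n_fastq <- length(readLines(paste0(pre, "_R1.fastq"))) / 4
  expect_equal(n_fastq, sim$n_pairs)
  expect_lt(abs(sim$n_pairs - expected) / expected, 0.01)
})

test_that("mixture boundaries and seed determinism hold for reads", {
  pair <- small_pair()
  cfg0 <- read_sim_config(coverage = 60, mixture_fraction = 0, seed = 5)
  sim0 <- simulate_reads(pair, cfg0)
  expect_true(all(grepl("^recipient", sim0$truth$origin)))

  sim0b <- simulate_reads(pair, cfg0)
  expect_identical(sim0$reads$seq, sim0b$reads$seq)
  expect_identical(sim0$truth, sim0b$truth)
  sim1 <- simulate_reads(pair, read_sim_config(coverage = 60,
                                               mixture_fraction = 0,
                                               seed = 6))
  expect_false(identical(sim0$reads$seq, sim1$reads$seq))
})

test_that("donor fraction and depth are conserved in rca mode", {
  pair <- small_pair(len = 5000L, n_snps = 8L)
  f <- 0.3
  cfg <- read_sim_config(coverage = 120, mixture_fraction = f, seed = 13)
  sim <- simulate_reads(pair, cfg)
  n <- nrow(sim$truth)
  obs <- mean(sim$truth$origin == "donor")
  expect_lt(abs(obs - f), 4 * sqrt(f * (1 - f) / (n / 2)))

  # mean pileup depth across scattered positions within 5% of coverage
  pos <- seq(1L, 5000L, by = 97L)
  pu <- build_pileup(sim, pair$recipient, pos)
  expect_lt(abs(mean(pu$depth) - 120) / 120, 0.05)
})

test_that("deleted molecules leave no bases inside the deletion", {
  del <- deletion_spec(800, 1400, heteroplasmy = 1)
  pair <- small_pair(len = 2000L, n_snps = 6L, deletion = del)
  cfg <- read_sim_config(coverage = 80, mixture_fraction = 0, seed = 21)
  sim <- simulate_reads(pair, cfg)
  inside <- build_pileup(sim, pair$recipient, c(800, 1000, 1400))
  expect_true(all(inside$depth == 0L))
  outside <- build_pileup(sim, pair$recipient, c(100, 500, 1700))
  expect_true(all(outside$depth > 0L))
})

test_that("pcr mode restricts placement to amplicons and warns on gaps", {
  pair <- small_pair(len = 4000L, n_snps = 6L, seed = 31L)
  amps <- list(c(1L, 2100L), c(1901L, 4000L))
  cfg <- read_sim_config(coverage = 80, mixture_fraction = 0.2,
                         amplification_mode = "pcr_two_amplicon",
                         amplicon_intervals = amps, seed = 3)
  sim <- simulate_reads(pair, cfg)
  expect_true(all(sim$segments$ref_start >= 1 &
                    sim$segments$ref_end <= 4000))
  # amplicons covering only half the genome: SNPs outside must warn
  narrow <- list(c(1L, 900L), c(901L, 1800L))
  cfg2 <- read_sim_config(coverage = 40, mixture_fraction = 0.2,
                          amplification_mode = "pcr_two_amplicon",
                          amplicon_intervals = narrow, seed = 3)
  expect_warning(simulate_reads(pair, cfg2), "not covered")
  expect_error(read_sim_config(amplification_mode = "pcr_two_amplicon",
                               amplicon_intervals = list(c(1, 10))),
               "configuration error")
})

test_that("dpcr chip simulation follows Poisson occupancy", {
  expect_identical(simulate_dpcr(0, seed = 1)$n_positive, 0L)
  c1 <- simulate_dpcr(500, ng_loaded = 2, n_partitions = 2000, seed = 4)
  c2 <- simulate_dpcr(500, ng_loaded = 2, n_partitions = 2000, seed = 4)
  expect_identical(c1$n_positive, c2$n_positive)

  # expected occupancy 1 - e^-1 at lambda = 1, averaged over 100 chips
  occ <- vapply(1:100, function(s) {
    ch <- simulate_dpcr(1000, ng_loaded = 2, n_partitions = 2000, seed = s)
    ch$n_positive / ch$n_valid
  }, numeric(1))
  expect_lt(abs(mean(occ) - (1 - exp(-1))), 0.01)
})

test_that("paired heteroplasmy chips scale the full-length assay", {
  pr <- simulate_dpcr_heteroplasmy(1500, 1, seed = 2)
  expect_identical(pr$full_length$n_positive, 0L)

  pos <- vapply(1:20, function(s) {
    p <- simulate_dpcr_heteroplasmy(1500, 0, seed = s)
    c(p$full_length$n_positive, p$total$n_positive)
  }, numeric(2))
  expect_lt(abs(mean(pos[1, ]) / mean(pos[2, ]) - 1), 0.05)
  expect_error(simulate_dpcr_heteroplasmy(1500, 1.2), "invalid parameter")
})

test_that("fluorescence panels honor boundaries and determinism", {
  p0 <- simulate_fluorescence(n_cells = 50, exo_fraction = 0,
                              noise_cv = 0.2, seed = 3)
  expect_true(all(p0$dendra2_intensity[!p0$is_calibration] == 0))
  expect_true(all(p0$dendra2_intensity[p0$is_calibration] > 0))

  p1 <- simulate_fluorescence(n_cells = 50, exo_fraction = 1,
                              noise_cv = 0, seed = 3)
  expect_equal(exo_mito_fraction(p1)$percent, 100)

  pa <- simulate_fluorescence(n_cells = 30, exo_fraction = 0.2, seed = 11)
  pb <- simulate_fluorescence(n_cells = 30, exo_fraction = 0.2, seed = 11)
  expect_identical(pa, pb)
  expect_error(simulate_fluorescence(exo_fraction = 1.5),
               "invalid parameter")
})
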